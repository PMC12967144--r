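#' @keywords internal
"_PACKAGE"

## Shared conventions -------------------------------------------------------
##
## Arrays are indexed (z, y, x); voxel_size is (sz, sy, sx) in nm per axis.
## Physical coordinate of the centre of voxel (k, j, i) (1-based array index)
## is ((i - 0.5) * sx, (j - 0.5) * sy, (k - 0.5) * sz), i.e. the origin sits
## at the corner of the first voxel. All internal quantities are nm / nm^2 /
## nm^3; conversion to micrometres happens exactly once, at reporting
## boundaries.

#' Mitotic phase labels in biological order
#'
#' The ordered factor levels used for phase annotations, from interphase
#' (`non_dividing`) through the prophase sub-stages to `cytokinesis`.
#'
#' @format Character vector of length 8.
#' @export
PHASE_LEVELS <- c(
  "non_dividing", "prophase_I", "prophase_II", "prophase_III",
  "metaphase", "anaphase", "telophase", "cytokinesis"
)

#' Object classes recognised in label volumes
#' @format Character vector.
#' @export
OBJECT_CLASSES <- c("cell", "nucleus", "chromosome", "mitochondrion", "ER", "vesicle")

NM_PER_UM <- 1e3

nm_to_um  <- function(x) x / NM_PER_UM
nm2_to_um2 <- function(x) x / NM_PER_UM^2
nm3_to_um3 <- function(x) x / NM_PER_UM^3
um3_to_nm3 <- function(x) x * NM_PER_UM^3

check_voxel_size <- function(voxel_size) {
  if (is.null(voxel_size) || length(voxel_size) != 3 ||
      !is.numeric(voxel_size) || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel size required: supply voxel_size = c(sz, sy, sx) in nm, all > 0",
         call. = FALSE)
  }
  as.numeric(voxel_size)
}

#' Grayscale intensity volume
#'
#' A 3D grayscale array indexed `(z, y, x)` together with its physical voxel
#' size in nanometres per axis.
#'
#' @param data 3D numeric array indexed `(z, y, x)`.
#' @param voxel_size Numeric length-3, `(sz, sy, sx)` in nm; all positive.
#' @return An object of class `voxel_grid` with elements `data` and
#'   `voxel_size`.
#' @export
voxel_grid <- function(data, voxel_size) {
  voxel_size <- check_voxel_size(voxel_size)
  if (!is.array(data) || length(dim(data)) != 3)
    stop("data must be a 3D array indexed (z, y, x)", call. = FALSE)
  if (any(dim(data) < 1)) stop("all dimensions must be >= 1", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, voxel %s nm (z,y,x)\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$voxel_size, collapse = "x")))
  invisible(x)
}

#' Integer label volume with object index
#'
#' A 3D array of non-negative integer object IDs (0 = background), voxel-size
#' metadata and a per-object index giving each object's class, parent cell and
#' truncation flag (objects touching the stack boundary are flagged, not
#' dropped).
#'
#' @param labels 3D array of non-negative integers indexed `(z, y, x)`.
#' @param voxel_size Numeric length-3, `(sz, sy, sx)` in nm.
#' @param object_index Data frame with columns `object_id`, `class`
#'   (one of [OBJECT_CLASSES]), `parent_cell_id` (NA for cells or unparented
#'   objects) and `truncated` (logical). Every nonzero label must appear.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, object_index = NULL) {
  voxel_size <- check_voxel_size(voxel_size)
  if (!is.array(labels) || length(dim(labels)) != 3)
    stop("labels must be a 3D array indexed (z, y, x)", call. = FALSE)
  if (is.double(labels)) {
    if (any(labels != round(labels)) || any(labels < 0))
      stop("labels must be non-negative integers", call. = FALSE)
    storage.mode(labels) <- "integer"
  }
  if (any(labels < 0)) stop("labels must be non-negative integers", call. = FALSE)
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0L]
  if (is.null(object_index)) {
    object_index <- data.frame(
      object_id = ids,
      class = rep(NA_character_, length(ids)),
      parent_cell_id = rep(NA_integer_, length(ids)),
      truncated = rep(FALSE, length(ids))
    )
  } else {
    object_index <- as.data.frame(object_index)
    req <- c("object_id", "class")
    if (!all(req %in% names(object_index)))
      stop("object_index needs columns object_id and class", call. = FALSE)
    if (!"parent_cell_id" %in% names(object_index))
      object_index$parent_cell_id <- NA_integer_
    if (!"truncated" %in% names(object_index))
      object_index$truncated <- FALSE
    missing_ids <- setdiff(ids, object_index$object_id)
    if (length(missing_ids))
      stop("labels present but absent from object_index: ",
           paste(utils::head(missing_ids, 10), collapse = ", "), call. = FALSE)
    bad <- !is.na(object_index$class) & !(object_index$class %in% OBJECT_CLASSES)
    if (any(bad))
      stop("unknown object class: ",
           paste(unique(object_index$class[bad]), collapse = ", "), call. = FALSE)
    cell_ids <- object_index$object_id[!is.na(object_index$class) &
                                         object_index$class == "cell"]
    par <- object_index$parent_cell_id
    orphan <- !is.na(par) & !(par %in% cell_ids)
    if (any(orphan))
      stop("parent_cell_id refers to a non-cell or absent object: ",
           paste(unique(par[orphan]), collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, voxel_size = voxel_size,
                 object_index = object_index),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, voxel %s nm, %d objects\n",
              paste(dim(x$labels), collapse = "x"),
              paste(x$voxel_size, collapse = "x"),
              nrow(x$object_index)))
  invisible(x)
}

#' Phase annotation for analysed cells
#'
#' @param cell_id Integer vector of cell IDs.
#' @param phase Character vector of phases, one of [PHASE_LEVELS]; exactly one
#'   phase per cell.
#' @return Data frame with columns `cell_id` and `phase` (ordered factor).
#' @export
phase_annotation <- function(cell_id, phase) {
  if (length(cell_id) != length(phase))
    stop("cell_id and phase must have the same length", call. = FALSE)
  if (anyDuplicated(cell_id))
    stop("every analysed cell has exactly one phase; duplicated cell_id",
         call. = FALSE)
  bad <- !(phase %in% PHASE_LEVELS)
  if (any(bad))
    stop("unknown phase label: ", paste(unique(phase[bad]), collapse = ", "),
         call. = FALSE)
  data.frame(cell_id = as.integer(cell_id),
             phase = factor(phase, levels = PHASE_LEVELS))
}

## Volume I/O ----------------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume to multipage TIFF with a JSON sidecar
#'
#' The grayscale or label array is stored as a multipage TIFF (one page per z
#' slice); voxel size and, for label volumes, the object index are stored in a
#' JSON sidecar `<path>.json`. Label values must fit in 16 bits. The
#' round trip through [read_volume()] preserves every voxel value and the
#' voxel size exactly.
#'
#' @param vol A [voxel_grid()] or [label_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "label_volume")) {
    arr <- vol$labels
    if (max(arr) > 65535L)
      stop("label IDs above 65535 cannot be stored in 16-bit TIFF", call. = FALSE)
    kind <- "labels"
  } else if (inherits(vol, "voxel_grid")) {
    arr <- vol$data
    if (min(arr) < 0 || max(arr) > 65535)
      stop("intensity values must lie in [0, 65535]", call. = FALSE)
    kind <- "intensity"
  } else stop("vol must be a voxel_grid or label_volume", call. = FALSE)
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(k) arr[k, , , drop = TRUE] / 65535)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16)
  if (!isTRUE(ok) && !identical(ok, length(pages)))
    stop("failed to write TIFF: ", path, call. = FALSE)
  meta <- list(kind = kind, voxel_size_nm = vol$voxel_size,
               dim = dim(arr))
  if (kind == "labels") meta$object_index <- vol$object_index
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' Voxel size must be available, either from the JSON sidecar or from the
#' `voxel_size` argument; reading without one is an error (1 nm is never
#' silently assumed). When `as` is `"labels"` the data must be integral.
#'
#' @param path TIFF path.
#' @param as `"auto"` (use the sidecar's kind), `"labels"` or `"intensity"`.
#' @param voxel_size Optional override, `(sz, sy, sx)` nm.
#' @return A [voxel_grid()] or [label_volume()].
#' @export
read_volume <- function(path, as = c("auto", "labels", "intensity"),
                        voxel_size = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (is.null(voxel_size)) voxel_size <- meta$voxel_size_nm
  voxel_size <- check_voxel_size(voxel_size)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0, d)
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]] * 65535
  arr <- round(arr)
  kind <- if (as == "auto") {
    if (!is.null(meta$kind)) meta$kind else "intensity"
  } else as
  if (kind == "labels") {
    if (any(arr != round(arr)))
      stop("non-integer data cannot be read as labels", call. = FALSE)
    storage.mode(arr) <- "integer"
    oi <- if (!is.null(meta$object_index)) as.data.frame(meta$object_index)
    label_volume(arr, voxel_size, object_index = oi)
  } else {
    voxel_grid(arr, voxel_size)
  }
}

## Result tables -------------------------------------------------------------

#' Write a result table as locale-independent CSV
#'
#' Rows are sorted by `cell_id` then `object_id` when those columns exist so
#' output is deterministic; numeric fields use the dot decimal separator
#' regardless of locale. An empty record set yields a header-only file.
#'
#' @param records Data frame (possibly zero rows) with a common schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  ord <- intersect(c("cell_id", "object_id"), names(records))
  if (length(ord) && nrow(records))
    records <- records[do.call(order, records[ord]), , drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write table to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path CSV path.
#' @return Data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
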