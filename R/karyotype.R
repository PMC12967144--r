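## Ultrastructure-based 3D karyotyping of segmented metaphase chromatids.
##
## The ovine diploid complement is 2n = 54: 26 autosome pairs (chromosomes
## 1-3 metacentric, 4-26 acrocentric) plus a large submetacentric X and a
## small acrocentric Y. Volume is the primary identification criterion,
## centromere position the secondary one, spatial proximity a supporting one.

KARYOTYPE_GROUPS <- c("metacentric", "acro_I", "acro_II", "acro_III", "X", "Y")

## 26-neighbourhood offsets and their physical step lengths
neighbour_offsets <- function(voxel_size) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  g$len <- sqrt((g$dz * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 +
                  (g$dx * voxel_size[3])^2)
  g
}

## geodesic distance (chamfer metric on the 26-neighbourhood) from a set of
## seed voxels, computed by iterative relaxation on the cropped mask
geodesic_distance <- function(mask, seeds_lin, voxel_size) {
  d <- dim(mask)
  dist <- array(Inf, d)
  dist[seeds_lin] <- 0
  dist[!mask] <- NA
  offs <- neighbour_offsets(voxel_size)
  shift_arr <- function(a, dz, dy, dx, fill = Inf) {
    out <- array(fill, d)
    zi <- seq_len(d[1]); yi <- seq_len(d[2]); xi <- seq_len(d[3])
    z_src <- zi - dz; y_src <- yi - dy; x_src <- xi - dx
    zok <- z_src >= 1 & z_src <= d[1]
    yok <- y_src >= 1 & y_src <= d[2]
    xok <- x_src >= 1 & x_src <= d[3]
    out[zi[zok], yi[yok], xi[xok]] <- a[z_src[zok], y_src[yok], x_src[xok]]
    out
  }
  repeat {
    new <- dist
    for (r in seq_len(nrow(offs))) {
      cand <- shift_arr(dist, offs$dz[r], offs$dy[r], offs$dx[r]) + offs$len[r]
      upd <- !is.na(new) & !is.na(cand) & cand < new
      new[upd] <- cand[upd]
    }
    if (isTRUE(all.equal(new, dist)) ||
        max(abs(new - dist), na.rm = TRUE) < 1e-9) break
    dist <- new
  }
  dist
}

#' Locate the centromere of a chromatid mask
#'
#' Traces the chromatid's medial axis by geodesic arclength profiling: the
#' geodesic diameter endpoints define the arclength coordinate, the
#' cross-sectional width profile (slice voxel count along arclength) is
#' smoothed, and the centromere is the minimal-width point within the central
#' 90% of arclength. The arm ratio is the longer over the shorter arclength
#' about that point. Non-elongated or fragmented masks return class
#' `"unresolved"` rather than an error.
#'
#' @param mask Logical/0-1 3D array of one chromatid.
#' @param voxel_size `(sz, sy, sx)` nm.
#' @return List: `skeleton_length_um`, `arm_ratio`, `centromere_class`,
#'   `centromere_arc_fraction`.
#' @export
centromere_detect <- function(mask, voxel_size) {
  voxel_size <- check_voxel_size(voxel_size)
  mask <- mask != 0
  n <- sum(mask)
  if (n == 0) stop("empty mask", call. = FALSE)
  unresolved <- list(skeleton_length_um = NA_real_, arm_ratio = NA_real_,
                     centromere_class = "unresolved",
                     centromere_arc_fraction = NA_real_)
  first <- which(mask)[1]
  d0 <- geodesic_distance(mask, first, voxel_size)
  if (any(is.infinite(d0[mask]))) return(unresolved)   # fragmented
  a_end <- which(d0 == max(d0[mask]))[1]
  dA <- geodesic_distance(mask, a_end, voxel_size)
  b_end <- which(dA == max(dA[mask]))[1]
  dB <- geodesic_distance(mask, b_end, voxel_size)
  L <- dA[b_end]
  mean_step <- mean(voxel_size)
  if (L < 4 * mean_step) return(unresolved)
  ## elongation: geodesic diameter vs volume-equivalent sphere diameter
  d_eq <- 2 * (3 * n * prod(voxel_size) / (4 * pi))^(1 / 3)
  if (L < 1.6 * d_eq) return(unresolved)
  ## arclength coordinate of every voxel, in [0, L]
  t_arc <- (dA[mask] - dB[mask] + L) / 2
  nbins <- max(8L, ceiling(L / mean_step))
  bin <- pmin(pmax(ceiling(t_arc / L * nbins), 1L), nbins)
  prof <- tabulate(bin, nbins)
  ## 3-bin running mean
  prof_s <- (c(prof[1], prof[-nbins]) + prof + c(prof[-1], prof[nbins])) / 3
  centres <- (seq_len(nbins) - 0.5) / nbins
  central <- which(centres >= 0.05 & centres <= 0.95)
  waist <- central[which.min(prof_s[central])]
  f <- centres[waist]
  arm_ratio <- max(f, 1 - f) / min(f, 1 - f)
  list(skeleton_length_um = nm_to_um(L),
       arm_ratio = arm_ratio,
       centromere_class = classify_centromere(arm_ratio),
       centromere_arc_fraction = f)
}

#' Classify centromere position from the arm ratio
#'
#' Levan convention: metacentric for ratio <= 1.7, submetacentric for
#' 1.7 < ratio <= 3, acrocentric above 3.
#'
#' @param arm_ratio Long-arm / short-arm length, >= 1.
#' @return `"metacentric"`, `"submetacentric"` or `"acrocentric"`.
#' @export
classify_centromere <- function(arm_ratio) {
  if (any(!is.finite(arm_ratio)) || any(arm_ratio < 1))
    stop("arm_ratio must be >= 1", call. = FALSE)
  ifelse(arm_ratio <= 1.7, "metacentric",
         ifelse(arm_ratio <= 3.0, "submetacentric", "acrocentric"))
}

## pairing cost between two chromatids; Inf when the hard volume constraint
## is violated. Weights encode the priority order volume >> morphology >>
## proximity.
pair_cost <- function(v1, v2, cls1, cls2, comdist, cell_diameter,
                      max_vol_frac = 0.35) {
  vm <- (v1 + v2) / 2
  dv <- abs(v1 - v2) / vm
  if (dv > max_vol_frac) return(Inf)
  cls_term <- as.numeric(!is.na(cls1) && !is.na(cls2) && cls1 != cls2)
  prox <- if (is.finite(comdist) && is.finite(cell_diameter) && cell_diameter > 0)
    comdist / cell_diameter else 0
  0.7 * dv + 0.2 * cls_term + 0.1 * prox
}

#' Pair homologous chromatids of one cell
#'
#' Greedy global minimum-cost pairing with 2-opt refinement on the cost
#' `0.7 |V1 - V2| / mean(V) + 0.2 [centromere classes differ] +
#' 0.1 (COM distance / cell diameter)`; pairs whose volumes differ by more
#' than 35% of their mean are forbidden, so chromatids without a
#' volume-compatible partner stay unpaired. Deterministic under input
#' permutation (internal ordering by object id).
#'
#' @param chromatids Data frame with columns `object_id`, `volume_um3`,
#'   optional `centromere_class`, optional `com_x_nm`/`com_y_nm`/`com_z_nm`.
#' @param cell_diameter_nm Optional scale for the proximity term.
#' @return List: `pairs` (data frame `pair_id`, `object_a`, `object_b`,
#'   `mean_volume_um3`), `unpaired` (object ids), `assignment` (named vector
#'   object_id -> pair_id or NA).
#' @export
pair_homologs <- function(chromatids, cell_diameter_nm = NULL) {
  ch <- as.data.frame(chromatids)
  if (nrow(ch) < 2) stop("need at least two chromatids", call. = FALSE)
  ch <- ch[order(ch$object_id), ]
  n <- nrow(ch)
  if (is.null(cell_diameter_nm)) {
    if (all(c("com_x_nm", "com_y_nm", "com_z_nm") %in% names(ch))) {
      spread <- sqrt(sum(apply(ch[, c("com_x_nm", "com_y_nm", "com_z_nm")], 2,
                               function(v) diff(range(v)))^2))
      cell_diameter_nm <- max(spread, 1)
    } else cell_diameter_nm <- NA_real_
  }
  has_com <- all(c("com_x_nm", "com_y_nm", "com_z_nm") %in% names(ch))
  cls <- if ("centromere_class" %in% names(ch)) ch$centromere_class else
    rep(NA_character_, n)
  C <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cd <- if (has_com)
      sqrt((ch$com_x_nm[i] - ch$com_x_nm[j])^2 +
             (ch$com_y_nm[i] - ch$com_y_nm[j])^2 +
             (ch$com_z_nm[i] - ch$com_z_nm[j])^2) else NA_real_
    C[i, j] <- C[j, i] <- pair_cost(ch$volume_um3[i], ch$volume_um3[j],
                                    cls[i], cls[j], cd, cell_diameter_nm)
  }
  ## greedy: repeatedly take the globally cheapest admissible pair
  mate <- rep(NA_integer_, n)
  free <- rep(TRUE, n)
  Cw <- C
  repeat {
    if (all(!is.finite(Cw[free, free, drop = FALSE]))) break
    sub <- which(outer(free, free, "&") & is.finite(Cw), arr.ind = TRUE)
    if (!nrow(sub)) break
    costs <- Cw[sub]
    best <- sub[order(costs, sub[, 1], sub[, 2])[1], ]
    i <- best[1]; j <- best[2]
    mate[i] <- j; mate[j] <- i
    free[i] <- free[j] <- FALSE
  }
  ## 2-opt: swap partners between two pairs when it lowers total cost
  repeat {
    improved <- FALSE
    paired_i <- which(!is.na(mate) & seq_len(n) < mate)
    if (length(paired_i) >= 2) {
      for (a in seq_along(paired_i)) {
        for (b in seq_along(paired_i)) {
          if (a >= b) next
          i1 <- paired_i[a]; j1 <- mate[i1]
          i2 <- paired_i[b]; j2 <- mate[i2]
          cur <- C[i1, j1] + C[i2, j2]
          alt1 <- C[i1, i2] + C[j1, j2]
          alt2 <- C[i1, j2] + C[j1, i2]
          if (is.finite(alt1) && alt1 < cur - 1e-12 && alt1 <= alt2) {
            mate[i1] <- i2; mate[i2] <- i1; mate[j1] <- j2; mate[j2] <- j1
            improved <- TRUE
          } else if (is.finite(alt2) && alt2 < cur - 1e-12) {
            mate[i1] <- j2; mate[j2] <- i1; mate[j1] <- i2; mate[i2] <- j1
            improved <- TRUE
          }
          if (improved) break
        }
        if (improved) break
      }
    }
    if (!improved) break
  }
  first_of_pair <- which(!is.na(mate) & seq_len(n) < mate)
  pairs <- data.frame(
    pair_id = seq_along(first_of_pair),
    object_a = ch$object_id[first_of_pair],
    object_b = ch$object_id[mate[first_of_pair]],
    mean_volume_um3 = (ch$volume_um3[first_of_pair] +
                         ch$volume_um3[mate[first_of_pair]]) / 2
  )
  assignment <- rep(NA_integer_, n)
  assignment[first_of_pair] <- pairs$pair_id
  assignment[mate[first_of_pair]] <- pairs$pair_id
  names(assignment) <- ch$object_id
  list(pairs = pairs,
       unpaired = ch$object_id[is.na(mate)],
       assignment = assignment)
}

#' Identify the sex chromosomes among unpaired chromatids
#'
#' X is the largest-volume submetacentric candidate; Y the smallest-volume
#' acrocentric candidate. Ties break by larger surface area, then lower
#' object id. Either may be absent (`NA`).
#'
#' @param chromatids Data frame with `object_id`, `volume_um3`, optional
#'   `surface_area_um2` and `centromere_class`.
#' @param unpaired Object ids left unpaired by [pair_homologs()].
#' @return List `list(X = id or NA, Y = id or NA)`.
#' @export
identify_sex_chromosomes <- function(chromatids, unpaired) {
  ch <- as.data.frame(chromatids)
  cand <- ch[ch$object_id %in% unpaired, , drop = FALSE]
  pick <- function(df, decreasing_vol) {
    if (!nrow(df)) return(NA_integer_)
    sa <- if ("surface_area_um2" %in% names(df)) df$surface_area_um2 else
      rep(0, nrow(df))
    ord <- order(if (decreasing_vol) -df$volume_um3 else df$volume_um3,
                 -sa, df$object_id)
    df$object_id[ord[1]]
  }
  cls <- if ("centromere_class" %in% names(cand)) cand$centromere_class else
    rep(NA_character_, nrow(cand))
  x_id <- pick(cand[!is.na(cls) & cls == "submetacentric", , drop = FALSE], TRUE)
  y_sel <- !is.na(cls) & cls == "acrocentric"
  if (!is.na(x_id)) y_sel <- y_sel & cand$object_id != x_id
  y_id <- pick(cand[y_sel, , drop = FALSE], FALSE)
  list(X = x_id, Y = y_id)
}

#' Assign the karyotype group of a chromosome pair
#'
#' Sex label overrides; metacentric autosomes form the metacentric group;
#' acrocentric autosomes split by pair mean volume: above 3 um^3 acro I
#' (strict), 2-3 um^3 inclusive acro II, below 2 um^3 acro III. A
#' submetacentric autosome is unresolved (with a warning): only X is expected
#' to be submetacentric in sheep.
#'
#' @param mean_volume_um3 Pair mean volume, > 0.
#' @param centromere_class One of metacentric/submetacentric/acrocentric or NA.
#' @param sex_label `"X"`, `"Y"` or `NA`.
#' @return One of `r paste(KARYOTYPE_GROUPS, collapse=", ")` or "unresolved".
#' @export
assign_karyotype_group <- function(mean_volume_um3, centromere_class = NA,
                                   sex_label = NA) {
  if (!is.finite(mean_volume_um3) || mean_volume_um3 <= 0)
    stop("volume must be positive", call. = FALSE)
  if (!is.na(sex_label) && sex_label %in% c("X", "Y")) return(sex_label)
  if (!is.na(centromere_class) && centromere_class == "metacentric")
    return("metacentric")
  if (!is.na(centromere_class) && centromere_class == "submetacentric") {
    warning("submetacentric autosome: unresolved karyotype group")
    return("unresolved")
  }
  if (mean_volume_um3 > 3) "acro_I"
  else if (mean_volume_um3 >= 2) "acro_II"
  else "acro_III"
}

#' Build the ordered karyotype table of one metaphase cell
#'
#' Runs homolog pairing and sex-chromosome identification, numbers autosome
#' pairs 1..26 by descending mean volume (ties by descending surface area then
#' object id) and assigns karyotype groups. A chromatid count different from
#' the expected diploid count still yields a table, with `count_mismatch` set.
#'
#' @param chromatids Data frame as for [pair_homologs()]; a
#'   `surface_area_um2` column improves tie-breaking.
#' @param expected_diploid Expected chromatid count (ovine default 54).
#' @return List of class `karyotype_table`: `table` (one row per chromosome:
#'   `chromosome`, `karyotype_group`, `mean_volume_um3`, `mean_surface_um2`,
#'   `object_a`, `object_b`), `n_chromatids`, `count_mismatch`, `unassigned`.
#' @export
build_karyotype <- function(chromatids, expected_diploid = 54L) {
  ch <- as.data.frame(chromatids)
  ch <- ch[order(ch$object_id), ]
  pr <- pair_homologs(ch)
  sex <- identify_sex_chromosomes(ch, pr$unpaired)
  getv <- function(id, col) if (col %in% names(ch))
    ch[[col]][match(id, ch$object_id)] else NA_real_
  pairs <- pr$pairs
  if (nrow(pairs)) {
    pairs$mean_surface_um2 <- (getv(pairs$object_a, "surface_area_um2") +
                                 getv(pairs$object_b, "surface_area_um2")) / 2
    cls_a <- if ("centromere_class" %in% names(ch))
      ch$centromere_class[match(pairs$object_a, ch$object_id)] else NA
    ord <- order(-pairs$mean_volume_um3,
                 -ifelse(is.na(pairs$mean_surface_um2), 0, pairs$mean_surface_um2),
                 pairs$object_a)
    pairs <- pairs[ord, ]
    cls_a <- cls_a[ord]
    grp <- vapply(seq_len(nrow(pairs)), function(i)
      assign_karyotype_group(pairs$mean_volume_um3[i], cls_a[i]),
      character(1))
    tab <- data.frame(
      chromosome = as.character(seq_len(nrow(pairs))),
      karyotype_group = grp,
      mean_volume_um3 = pairs$mean_volume_um3,
      mean_surface_um2 = pairs$mean_surface_um2,
      object_a = pairs$object_a,
      object_b = pairs$object_b
    )
  } else {
    tab <- data.frame(chromosome = character(), karyotype_group = character(),
                      mean_volume_um3 = numeric(), mean_surface_um2 = numeric(),
                      object_a = integer(), object_b = integer())
  }
  for (s in c("X", "Y")) {
    id <- sex[[s]]
    if (!is.na(id)) {
      tab <- rbind(tab, data.frame(
        chromosome = s, karyotype_group = s,
        mean_volume_um3 = getv(id, "volume_um3"),
        mean_surface_um2 = getv(id, "surface_area_um2"),
        object_a = id, object_b = NA_integer_))
    }
  }
  rownames(tab) <- NULL
  assigned <- c(tab$object_a, tab$object_b)
  structure(list(
    table = tab,
    n_chromatids = nrow(ch),
    count_mismatch = nrow(ch) != expected_diploid,
    unassigned = setdiff(ch$object_id, assigned[!is.na(assigned)])
  ), class = "karyotype_table")
}

#' @export
print.karyotype_table <- function(x, ...) {
  cat(sprintf("<karyotype_table> %d chromatids%s\n", x$n_chromatids,
              if (x$count_mismatch) " (count mismatch)" else ""))
  grp <- table(x$table$karyotype_group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
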