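## Synthetic phantom generator: label + intensity volumes with known ground
## truth, emulating the statistical structure of segmented SBF-SEM stacks of
## dividing cells. Object geometry is simple (ellipsoidal cell and nucleus,
## convex chromatid solids, ellipsoidal organelle fragments) but the
## population structure is the one the downstream analysis assumes:
## a diploid ovine chromosome complement, phase-dependent organelle
## counts/volumes, phase-dependent chromosomal displacement from the cell
## centre, and a stain model where denser chromatin yields higher grayscale
## values plus Gaussian noise.

STAIN_DEFAULTS <- c(background = 30, cytoplasm = 100, nucleus = 140,
                    ER = 150, vesicle = 160, mitochondrion = 170,
                    chromosome = 200)

#' Default ovine metaphase chromosome template
#'
#' Fifty-four chromatids: 26 autosome pairs (pairs 1-3 metacentric, the
#' remaining 23 acrocentric) plus a submetacentric X and a small acrocentric
#' Y. Pair volumes are fixed template defaults chosen to respect the
#' published group ranges (acro I > 3 um^3, acro II 2-3 um^3,
#' acro III < 2 um^3), not measurements.
#'
#' @return Data frame with one row per chromatid: `chromatid_id`,
#'   `pair_label` (`"1"`..`"26"`, `"X"`, `"Y"`), `volume_um3`,
#'   `centromere_class`, `arm_ratio`.
#' @export
default_ovine_template <- function() {
  pair_vol <- c(9.0, 8.2, 7.5,                                  # 1-3 metacentric
                4.8, 4.5, 4.1, 3.8, 3.5, 3.2,                   # 4-9  acro I
                2.9, 2.8, 2.7, 2.5, 2.4, 2.3, 2.2, 2.1,         # 10-17 acro II
                1.9, 1.8, 1.6, 1.5, 1.4, 1.2, 1.1, 1.0, 0.8)    # 18-26 acro III
  pair_cls <- c(rep("metacentric", 3), rep("acrocentric", 23))
  pair_ratio <- c(rep(1.2, 3), rep(4.5, 23))
  lab <- as.character(seq_len(26))
  df <- data.frame(
    pair_label = c(rep(lab, each = 2), "X", "Y"),
    volume_um3 = c(rep(pair_vol, each = 2), 4.2, 0.5),
    centromere_class = c(rep(pair_cls, each = 2), "submetacentric",
                         "acrocentric"),
    arm_ratio = c(rep(pair_ratio, each = 2), 2.2, 4.5)
  )
  df <- cbind(chromatid_id = seq_len(nrow(df)), df)
  df
}

#' Phantom specification
#'
#' Collects every knob of the generator with defaults matching the emulated
#' acquisition: 30x30x30 nm voxels, a 15 x 15 x 12 um ellipsoidal cell, the
#' ovine chromosome template, and phase-typical organelle populations. For
#' fast tests the same physical scene is typically generated at 90 nm voxels
#' (the stacks' bin-by-three resolution).
#'
#' @param seed Integer RNG seed.
#' @param voxel_size `(sz, sy, sx)` nm.
#' @param phase One of [PHASE_LEVELS].
#' @param cell_semi_axes_um Ellipsoid semi-axes `(x, y, z)` in um.
#' @param chromosome_template Data frame as [default_ovine_template()];
#'   `NULL` for the default (ignored in `non_dividing` phase).
#' @param organelles Named list per class (`mitochondrion`, `ER`, `vesicle`):
#'   `count`, `mean_volume_um3`, `pattern` (`"uniform"`, `"central_hotspot"`,
#'   `"cortical"`, `"clustered"`), optional `k` for clustered.
#' @param stain Named numeric of class mean grayscales (uint8 scale).
#' @param noise_sd Gaussian stain noise s.d.
#' @param displacement_frac Chromosome COM target radius as a fraction of the
#'   available placement radius.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1729,
                         voxel_size = c(30, 30, 30),
                         phase = "metaphase",
                         cell_semi_axes_um = c(7.5, 7.5, 6.0),
                         chromosome_template = NULL,
                         organelles = list(
                           mitochondrion = list(count = 20, mean_volume_um3 = 0.25,
                                                pattern = "uniform"),
                           ER = list(count = 30, mean_volume_um3 = 0.12,
                                     pattern = "uniform"),
                           vesicle = list(count = 25, mean_volume_um3 = 0.06,
                                          pattern = "uniform")),
                         stain = STAIN_DEFAULTS,
                         noise_sd = 8,
                         displacement_frac = 0.33) {
  voxel_size <- check_voxel_size(voxel_size)
  stopifnot(phase %in% PHASE_LEVELS)
  if (is.null(chromosome_template)) chromosome_template <- default_ovine_template()
  for (cl in names(organelles)) {
    o <- organelles[[cl]]
    if (o$count < 0) stop("organelle counts must be >= 0", call. = FALSE)
    if (o$mean_volume_um3 <= 0) stop("organelle volumes must be > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(seed = seed, voxel_size = voxel_size, phase = phase,
                 cell_semi_axes_um = cell_semi_axes_um,
                 chromosome_template = chromosome_template,
                 organelles = organelles, stain = stain, noise_sd = noise_sd,
                 displacement_frac = displacement_frac),
            class = "phantom_spec")
}

## random rotation matrix from the current RNG stream
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## voxel offsets (arr.ind, relative to centre) of a rotated ellipsoid with
## semi-axes ax_nm = (a, b, c) nm; voxel_size (sz,sy,sx)
ellipsoid_offsets <- function(ax_nm, rot, voxel_size, centre_frac = c(0, 0, 0)) {
  sz <- voxel_size[1]; sy <- voxel_size[2]; sx <- voxel_size[3]
  half <- max(ax_nm)
  hz <- ceiling(half / sz) + 1L; hy <- ceiling(half / sy) + 1L
  hx <- ceiling(half / sx) + 1L
  g <- expand.grid(dz = -hz:hz, dy = -hy:hy, dx = -hx:hx)
  ## sub-voxel centre shift decouples the realised voxel count from lattice
  ## quantisation, so small solids can be volume-calibrated smoothly
  P <- cbind((g$dx - centre_frac[1]) * sx, (g$dy - centre_frac[2]) * sy,
             (g$dz - centre_frac[3]) * sz)
  Q <- P %*% rot                       # world -> body frame (rot columns)
  inside <- (Q[, 1] / ax_nm[1])^2 + (Q[, 2] / ax_nm[2])^2 +
    (Q[, 3] / ax_nm[3])^2 <= 1
  cbind(dz = g$dz[inside], dy = g$dy[inside], dx = g$dx[inside])
}

## semi-axes (nm) of an ellipsoid of volume v_um3 with shape factors f
ellipsoid_axes <- function(v_um3, f = c(2.2, 1.1, 0.85)) {
  u <- (um3_to_nm3(v_um3) * 3 / (4 * pi * prod(f)))^(1 / 3)
  f * u
}

## voxelise an ellipsoid and rescale its axes until the realised voxel count
## is within 3% of the target volume
calibrated_ellipsoid_offsets <- function(v_um3, shape, rot, voxel_size) {
  target <- um3_to_nm3(v_um3) / prod(voxel_size)
  ax <- ellipsoid_axes(v_um3, shape)
  best <- NULL; best_err <- Inf
  for (it in 1:8) {
    cf <- stats::runif(3)
    offs <- ellipsoid_offsets(ax, rot, voxel_size, centre_frac = cf)
    got <- nrow(offs)
    err <- abs(got - target) / target
    if (got >= 1 && err < best_err) { best <- offs; best_err <- err }
    if (best_err <= 0.02) break
    ax <- ax * (target / max(got, 1))^(1 / 3)
  }
  best
}

#' Generate a single chromatid mask: a bent rod with a centromeric waist
#'
#' A solid tube around a quadratic Bezier curve whose radius dips by 45% at
#' the arclength fraction implied by the arm ratio, voxelised at the given
#' resolution and calibrated so the realised voxel volume is within 5% of the
#' target. Deterministic for a fixed seed.
#'
#' @param volume_um3 Target volume; must be at least 50 voxels at this
#'   resolution.
#' @param arm_ratio Long/short arm ratio >= 1 (waist at fraction
#'   `1/(1+arm_ratio)` of the arclength).
#' @param voxel_size `(sz, sy, sx)` nm.
#' @param seed RNG seed (bend direction jitter).
#' @param bend Fractional sagitta of the curve (0 = straight rod).
#' @return List: `mask` (3D logical array), `voxel_size`, `arm_fraction`,
#'   `target_volume_um3`, `realized_volume_um3`.
#' @export
generate_chromatid <- function(volume_um3, arm_ratio, voxel_size = c(90, 90, 90),
                               seed = 1729, bend = 0.18) {
  voxel_size <- check_voxel_size(voxel_size)
  voxvol <- prod(voxel_size)
  target_vox <- um3_to_nm3(volume_um3) / voxvol
  if (target_vox < 50)
    stop("target volume below resolution (needs >= 50 voxels)", call. = FALSE)
  if (arm_ratio < 1) stop("arm_ratio must be >= 1", call. = FALSE)
  set.seed(seed)
  f <- 1 / (1 + arm_ratio)             # waist fraction of tip-to-tip extent
  V <- um3_to_nm3(volume_um3)
  r0 <- (V / (9 * pi * 0.9))^(1 / 3)   # tube radius for aspect L = 9 r
  L <- 9 * r0
  ## arm lengths are measured tip to tip; the hemispherical end caps add r0
  ## at each end, so shift the waist on the curve axis accordingly
  f_axis <- min(max((f * (L + 2 * r0) - r0) / L, 0.02), 0.5)
  ## quadratic Bezier in a local (u, v) plane, bend jittered by the seed
  sag <- L * bend * stats::runif(1, 0.8, 1.2)
  p0 <- c(0, 0, 0); p2 <- c(L, 0, 0); p1 <- c(L / 2, sag * 2, 0)
  ts <- seq(0, 1, length.out = 200)
  curve <- outer((1 - ts)^2, p0) + outer(2 * ts * (1 - ts), p1) +
    outer(ts^2, p2)
  arc <- c(0, cumsum(sqrt(rowSums(diff(curve)^2))))
  u <- arc / max(arc)
  rad_profile <- function(uu, r) r * (1 - 0.45 * exp(-(uu - f_axis)^2 / (2 * 0.05^2)))
  sz <- voxel_size[1]; sy <- voxel_size[2]; sx <- voxel_size[3]
  for (it in 1:8) {
    rmax <- r0
    lo <- apply(curve, 2, min) - rmax - max(voxel_size)
    hi <- apply(curve, 2, max) + rmax + max(voxel_size)
    nx <- ceiling((hi[1] - lo[1]) / sx); ny <- ceiling((hi[2] - lo[2]) / sy)
    nz <- ceiling((hi[3] - lo[3]) / sz)
    xs <- lo[1] + (seq_len(nx) - 0.5) * sx
    ys <- lo[2] + (seq_len(ny) - 0.5) * sy
    zs <- lo[3] + (seq_len(nz) - 0.5) * sz
    g <- expand.grid(z = zs, y = ys, x = xs)
    ## nearest curve sample per voxel (chunked distance computation)
    npt <- nrow(g)
    best_d <- rep(Inf, npt); best_u <- rep(0, npt)
    chunk <- 40L
    for (s0 in seq(1, length(ts), by = chunk)) {
      sidx <- s0:min(s0 + chunk - 1L, length(ts))
      dx <- outer(g$x, curve[sidx, 1], "-")
      dy <- outer(g$y, curve[sidx, 2], "-")
      dz <- outer(g$z, curve[sidx, 3], "-")
      dd <- dx * dx + dy * dy + dz * dz
      mi <- max.col(-dd, ties.method = "first")
      mv <- dd[cbind(seq_len(npt), mi)]
      upd <- mv < best_d
      best_d[upd] <- mv[upd]
      best_u[upd] <- u[sidx][mi[upd]]
    }
    inside <- sqrt(best_d) <= rad_profile(best_u, r0)
    got <- sum(inside)
    if (abs(got - target_vox) / target_vox <= 0.04 || it == 8) {
      mask <- array(FALSE, c(nz, ny, nx))
      mask[which(inside)] <- TRUE
      return(list(mask = mask, voxel_size = voxel_size, arm_fraction = f,
                  target_volume_um3 = volume_um3,
                  realized_volume_um3 = nm3_to_um3(got * voxvol)))
    }
    r0 <- r0 * sqrt(target_vox / max(got, 1))
    ## keep the curve fixed; only the tube radius is recalibrated
  }
}

## place `offs` (relative arr.ind offsets) at integer centre (cz,cy,cx) if all
## voxels fall in region & are unoccupied; returns linear indices or NULL
try_place <- function(offs, centre, region, occupied, d) {
  z <- offs[, 1] + centre[1]; y <- offs[, 2] + centre[2]; x <- offs[, 3] + centre[3]
  if (min(z) < 1 || min(y) < 1 || min(x) < 1 ||
      max(z) > d[1] || max(y) > d[2] || max(x) > d[3]) return(NULL)
  lin <- z + (y - 1L) * d[1] + (x - 1L) * d[1] * d[2]
  if (!all(region[lin]) || any(occupied[lin])) return(NULL)
  lin
}

#' Generate a phantom cell: label volume, intensity volume, ground truth
#'
#' Builds one ellipsoidal cell at the requested phase. Cells up to late
#' prophase contain a nucleus enclosing the chromosomes; from metaphase
#' onwards chromosomes sit free in the cytoplasm at a phase-dependent radial
#' displacement. Organelle fragments are packed without overlap following
#' their spatial pattern. The intensity volume applies the per-class stain
#' means plus Gaussian noise. Identical seeds give identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom_cell`: `labels` ([label_volume()]),
#'   `intensity` ([voxel_grid()]), `truth` (per-object data frame with
#'   realised voxel counts, volumes, COMs and placement targets), `phase`.
#' @export
generate_phantom_cell <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  vs <- spec$voxel_size
  sz <- vs[1]; sy <- vs[2]; sx <- vs[3]
  ax_nm <- spec$cell_semi_axes_um * NM_PER_UM   # (x, y, z)
  d <- c(ceiling(2 * ax_nm[3] / sz) + 4L,
         ceiling(2 * ax_nm[2] / sy) + 4L,
         ceiling(2 * ax_nm[1] / sx) + 4L)
  centre <- (d + 1) / 2
  zc <- (seq_len(d[1]) - centre[1]) * sz
  yc <- (seq_len(d[2]) - centre[2]) * sy
  xc <- (seq_len(d[3]) - centre[3]) * sx
  ## cell ellipsoid mask
  zz <- array(zc, d)
  yy <- aperm(array(yc, d[c(2, 1, 3)]), c(2, 1, 3))
  xx <- aperm(array(xc, d[c(3, 2, 1)]), c(3, 2, 1))
  cell <- (xx / ax_nm[1])^2 + (yy / ax_nm[2])^2 + (zz / ax_nm[3])^2 <= 1
  has_nucleus <- spec$phase %in% c("non_dividing", "prophase_I",
                                   "prophase_II", "prophase_III")
  nucleus <- NULL
  if (has_nucleus) {
    nx_nm <- ax_nm * 0.74
    nucleus <- (xx / nx_nm[1])^2 + (yy / nx_nm[2])^2 + (zz / nx_nm[3])^2 <= 1
  }
  rm(zz, yy, xx)
  labels <- array(0L, d)
  occupied <- array(FALSE, d)
  labels[cell] <- 1L                   # cell (cytoplasm carved below)
  if (has_nucleus) labels[nucleus] <- 2L
  next_id <- if (has_nucleus) 3L else 2L
  oi <- data.frame(object_id = 1L, class = "cell",
                   parent_cell_id = NA_integer_, truncated = FALSE)
  truth <- data.frame(
    object_id = 1L, class = "cell", parent_cell_id = NA_integer_,
    pair_label = NA_character_, pattern = NA_character_,
    target_volume_um3 = nm3_to_um3(4 / 3 * pi * prod(ax_nm)),
    displacement_target_frac = NA_real_, carved = TRUE
  )
  if (has_nucleus) {
    oi <- rbind(oi, data.frame(object_id = 2L, class = "nucleus",
                               parent_cell_id = 1L, truncated = FALSE))
    truth <- rbind(truth, data.frame(
      object_id = 2L, class = "nucleus", parent_cell_id = 1L,
      pair_label = NA_character_, pattern = NA_character_,
      target_volume_um3 = nm3_to_um3(4 / 3 * pi * prod(ax_nm * 0.74)),
      displacement_target_frac = NA_real_, carved = TRUE
    ))
  }
  ## placement helper: bias the object COM to radius frac * available radius
  place_object <- function(offs, region, frac, pattern = "radial",
                           cluster_centres = NULL, what = "object",
                           max_attempts = 600, make_offs = NULL,
                           region_ax = ax_nm) {
    half_nm <- c(max(abs(offs[, 3])) * sx, max(abs(offs[, 2])) * sy,
                 max(abs(offs[, 1])) * sz)
    draw_target <- function() {
      if (pattern == "clustered" && !is.null(cluster_centres)) {
        cc <- cluster_centres[[sample.int(length(cluster_centres), 1)]]
        return(cc + stats::rnorm(3, 0, 0.06 * max(region_ax)))
      }
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      rmax_dir <- 1 / sqrt(sum((dir / region_ax)^2))   # region radius along dir
      rmax_eff <- max(rmax_dir - max(half_nm) - 2 * max(vs), 0)
      rtarget <- switch(pattern,
        uniform = rmax_eff * stats::runif(1)^(1 / 3),
        central_hotspot = abs(stats::rnorm(1, 0, 0.22 * rmax_eff)),
        cortical = rmax_eff * stats::runif(1, 0.78, 0.97),
        ## radial: full-support Beta law with mean frac * rmax, so a
        ## monotone frac plants a monotone mean without a hard shell
        radial = rmax_eff * stats::qbeta(stats::runif(1), frac * 8, (1 - frac) * 8)
      )
      dir * min(rtarget, rmax_eff)
    }
    ## spiral-out search: Gaussian offsets of growing scale around the target,
    ## with periodic re-orientation of the object
    target <- draw_target()
    for (attempt in seq_len(max_attempts)) {
      if (pattern != "radial" && attempt %% 25 == 0) target <- draw_target()
      if (!is.null(make_offs) && attempt %% 80 == 0) offs <- make_offs()
      sig <- 0.02 * max(ax_nm) * (1 + attempt / 25)
      pos_nm <- target +
        (if (attempt == 1) c(0, 0, 0) else stats::rnorm(3, 0, sig))
      cz_ <- round(centre[1] + pos_nm[3] / sz)
      cy_ <- round(centre[2] + pos_nm[2] / sy)
      cx_ <- round(centre[3] + pos_nm[1] / sx)
      lin <- try_place(offs, c(cz_, cy_, cx_), region, occupied, d)
      if (!is.null(lin)) return(lin)
    }
    stop(sprintf("packing failed for %s (%d voxels) after %d attempts; %d%% of region occupied",
                 what, nrow(offs), max_attempts,
                 round(100 * sum(occupied[region]) / max(sum(region), 1))),
         call. = FALSE)
  }
  ## chromosomes ------------------------------------------------------------
  chrom_region <- if (has_nucleus && spec$phase != "non_dividing") nucleus else cell
  if (spec$phase != "non_dividing") {
    tpl <- spec$chromosome_template
    tpl <- tpl[order(-tpl$volume_um3), ]
    ## nuclear (prophase) chromatin is packed tighter: use a more compact
    ## solid so the full complement fits inside the envelope
    chrom_shape <- if (has_nucleus) c(1.7, 1.1, 0.92) else c(2.2, 1.1, 0.85)
    for (r in seq_len(nrow(tpl))) {
      v_r <- tpl$volume_um3[r]
      mk <- function() calibrated_ellipsoid_offsets(v_r, chrom_shape,
                                                    random_rotation(), vs)
      offs <- mk()
      lin <- place_object(offs, chrom_region, spec$displacement_frac,
                          what = sprintf("chromatid %s", tpl$pair_label[r]),
                          max_attempts = 2000, make_offs = mk,
                          region_ax = if (has_nucleus) ax_nm * 0.74 else ax_nm)
      labels[lin] <- next_id
      occupied[lin] <- TRUE
      oi <- rbind(oi, data.frame(object_id = next_id, class = "chromosome",
                                 parent_cell_id = 1L, truncated = FALSE))
      truth <- rbind(truth, data.frame(
        object_id = next_id, class = "chromosome", parent_cell_id = 1L,
        pair_label = tpl$pair_label[r], pattern = "radial",
        target_volume_um3 = tpl$volume_um3[r],
        displacement_target_frac = spec$displacement_frac, carved = FALSE))
      next_id <- next_id + 1L
    }
  }
  ## organelles (cytoplasm only) -------------------------------------------
  cyto <- cell
  if (has_nucleus) cyto <- cyto & !nucleus
  for (cl in names(spec$organelles)) {
    o <- spec$organelles[[cl]]
    if (o$count == 0) next
    cluster_centres <- NULL
    if (identical(o$pattern, "clustered")) {
      k <- if (!is.null(o$k)) o$k else 3
      cluster_centres <- lapply(seq_len(k), function(i) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        dir * 0.55 * min(ax_nm) * stats::runif(1)^(1 / 3)
      })
    }
    shape <- switch(cl, mitochondrion = c(2.4, 1.0, 0.9),
                    ER = c(2.8, 1.4, 0.6), vesicle = c(1, 1, 1))
    for (i in seq_len(o$count)) {
      v <- o$mean_volume_um3 * exp(stats::rnorm(1, 0, 0.25))
      v <- max(v, nm3_to_um3(20 * prod(vs)))   # keep fragments resolvable
      offs <- calibrated_ellipsoid_offsets(v, shape, random_rotation(), vs)
      lin <- place_object(offs, cyto, NA, pattern = o$pattern,
                          cluster_centres = cluster_centres,
                          what = sprintf("%s %d", cl, i))
      labels[lin] <- next_id
      occupied[lin] <- TRUE
      oi <- rbind(oi, data.frame(object_id = next_id, class = cl,
                                 parent_cell_id = 1L, truncated = FALSE))
      truth <- rbind(truth, data.frame(
        object_id = next_id, class = cl, parent_cell_id = 1L,
        pair_label = NA_character_, pattern = o$pattern,
        target_volume_um3 = v, displacement_target_frac = NA_real_,
        carved = FALSE))
      next_id <- next_id + 1L
    }
  }
  ## realised morphometry of every object (single pass)
  nz_lin <- which(labels != 0L)
  by_id <- split(nz_lin, labels[nz_lin])
  voxvol <- prod(vs)
  truth$voxel_count <- 0L
  truth$volume_um3 <- NA_real_
  truth$com_x_nm <- NA_real_; truth$com_y_nm <- NA_real_; truth$com_z_nm <- NA_real_
  for (idc in names(by_id)) {
    lin <- by_id[[idc]]
    i1 <- (lin - 1L) %% d[1] + 1L
    i2 <- ((lin - 1L) %/% d[1]) %% d[2] + 1L
    i3 <- (lin - 1L) %/% (d[1] * d[2]) + 1L
    row <- match(as.integer(idc), truth$object_id)
    truth$voxel_count[row] <- length(lin)
    truth$volume_um3[row] <- nm3_to_um3(length(lin) * voxvol)
    truth$com_x_nm[row] <- mean(i3 - 0.5) * sx
    truth$com_y_nm[row] <- mean(i2 - 0.5) * sy
    truth$com_z_nm[row] <- mean(i1 - 0.5) * sz
  }
  cell_com <- c(centre[3] * sx - 0.5 * sx, centre[2] * sy - 0.5 * sy,
                centre[1] * sz - 0.5 * sz)
  ## displacement in um of every non-cell object from the geometric centre
  truth$displacement_um <- nm_to_um(sqrt(
    (truth$com_x_nm - (centre[3] - 0.5) * sx)^2 +
      (truth$com_y_nm - (centre[2] - 0.5) * sy)^2 +
      (truth$com_z_nm - (centre[1] - 0.5) * sz)^2))
  truth$phase <- spec$phase
  ## intensity volume --------------------------------------------------------
  stain <- spec$stain
  intens <- array(stain["background"], d)
  intens[labels == 1L] <- stain["cytoplasm"]
  if (has_nucleus) intens[labels == 2L] <- stain["nucleus"]
  cls_of <- truth$class[match(labels[nz_lin], truth$object_id)]
  for (cl in c("chromosome", "mitochondrion", "ER", "vesicle")) {
    sel <- nz_lin[cls_of == cl]
    if (length(sel)) intens[sel] <- stain[cl]
  }
  if (spec$noise_sd > 0)
    intens <- intens + stats::rnorm(length(intens), 0, spec$noise_sd)
  intens <- round(pmin(pmax(intens, 0), 255))
  structure(list(
    labels = label_volume(labels, vs, object_index = oi),
    intensity = voxel_grid(intens, vs),
    truth = truth, phase = spec$phase
  ), class = "phantom_cell")
}

#' Default per-phase effect table
#'
#' Multipliers applied to the base organelle populations, the chromosome
#' volumes and the chromosome displacement fraction per phase. The defaults
#' plant the qualitative trends the analysis is designed to detect:
#' chromosomal displacement rising steadily from prophase to cytokinesis
#' (prophase chromosome volumes are scaled 0.55/0.75/0.90 to emulate
#' progressive condensation), mitochondrial volume building to a telophase
#' peak with a central hotspot, vesicle count/volume peaking at metaphase,
#' ER volume expanding at anaphase with fragment counts dipping early and
#' rising late, and non-dividing cells ~7% smaller in linear scale.
#'
#' @return Data frame, one row per phase.
#' @export
phase_effect_table <- function() {
  data.frame(
    phase = PHASE_LEVELS,
    cell_scale = c(0.93, rep(1, 7)),
    displacement_frac = c(NA, 0.45, 0.55, 0.65, 0.48, 0.68, 0.80, 0.92),
    chrom_vol_mult = c(NA, 0.55, 0.75, 0.90, 1, 1, 1, 1),
    mito_count_mult = c(1, 1, 1.05, 1.1, 1.15, 1.2, 1.25, 1.2),
    mito_vol_mult  = c(1, 1.05, 1.1, 1.15, 1.25, 1.3, 1.4, 1.3),
    er_count_mult  = c(1, 0.9, 0.85, 0.8, 0.8, 1.1, 1.3, 1.4),
    er_vol_mult    = c(1, 1.05, 1.1, 1.15, 1.25, 1.6, 1.5, 1.4),
    ves_count_mult = c(1, 1.1, 1.2, 1.3, 1.6, 1.3, 1.1, 1),
    ves_vol_mult   = c(1, 1.05, 1.1, 1.2, 1.5, 1.2, 1.1, 1),
    mito_pattern = c("uniform", "uniform", "uniform", "uniform", "uniform",
                     "uniform", "central_hotspot", "uniform")
  )
}

#' Generate a series of phantom cells across mitotic phases
#'
#' One cell per requested phase, with organelle counts/volumes and chromosome
#' displacement scaled by the effect table, so the planted monotone and
#' peaked trends are recoverable by the downstream statistics.
#'
#' @param base_spec A [phantom_spec()] used as the template for every cell.
#' @param effects Effect table as [phase_effect_table()].
#' @param phases Phases to generate (default: all rows of `effects`).
#' @param seed Base seed; cell i uses `seed + i`.
#' @return List of `phantom_cell` objects, one per phase, named by phase.
#' @export
generate_phase_series <- function(base_spec = phantom_spec(),
                                  effects = phase_effect_table(),
                                  phases = effects$phase,
                                  seed = base_spec$seed) {
  out <- list()
  for (i in seq_along(phases)) {
    ph <- phases[i]
    e <- effects[effects$phase == ph, ]
    if (!nrow(e)) stop("phase absent from effect table: ", ph, call. = FALSE)
    org <- base_spec$organelles
    org$mitochondrion$count <- round(org$mitochondrion$count * e$mito_count_mult)
    org$mitochondrion$mean_volume_um3 <- org$mitochondrion$mean_volume_um3 * e$mito_vol_mult
    org$mitochondrion$pattern <- e$mito_pattern
    org$ER$count <- round(org$ER$count * e$er_count_mult)
    org$ER$mean_volume_um3 <- org$ER$mean_volume_um3 * e$er_vol_mult
    org$vesicle$count <- round(org$vesicle$count * e$ves_count_mult)
    org$vesicle$mean_volume_um3 <- org$vesicle$mean_volume_um3 * e$ves_vol_mult
    tpl <- base_spec$chromosome_template
    if (!is.na(e$chrom_vol_mult))
      tpl$volume_um3 <- tpl$volume_um3 * e$chrom_vol_mult
    sp <- phantom_spec(
      seed = seed + i,
      voxel_size = base_spec$voxel_size,
      phase = ph,
      cell_semi_axes_um = base_spec$cell_semi_axes_um * e$cell_scale,
      chromosome_template = tpl,
      organelles = org,
      stain = base_spec$stain,
      noise_sd = base_spec$noise_sd,
      displacement_frac = if (is.na(e$displacement_frac))
        base_spec$displacement_frac else e$displacement_frac)
    out[[ph]] <- generate_phantom_cell(sp)
  }
  out
}

#' Numeric-level phase table for power and type-I simulations
#'
#' Samples per-cell summary metrics directly (no voxelisation): cellular and
#' nuclear volumes for non-dividing and dividing cells with a planted effect
#' expressed in pooled standard deviations. With `effect_sd = 0` the groups
#' share one distribution (the type-I null).
#'
#' @param seed RNG seed.
#' @param n_nondividing,n_dividing Cells per group (defaults 8 and 9).
#' @param effect_sd Dividing-cell volume effect in units of the pooled s.d.
#' @param base_mean_um3,base_sd_um3 Non-dividing cellular volume distribution.
#' @return Data frame: `cell_id`, `phase`, `dividing`, `cell_volume_um3`,
#'   `nuclear_volume_um3`.
#' @export
generate_phase_table <- function(seed = 1729, n_nondividing = 8,
                                 n_dividing = 9, effect_sd = 3.1,
                                 base_mean_um3 = 1150, base_sd_um3 = 85) {
  set.seed(seed)
  div_phases <- rep(setdiff(PHASE_LEVELS, "non_dividing"),
                    length.out = n_dividing)
  phase <- c(rep("non_dividing", n_nondividing), div_phases)
  dividing <- phase != "non_dividing"
  mu <- ifelse(dividing, base_mean_um3 + effect_sd * base_sd_um3, base_mean_um3)
  vol <- stats::rnorm(length(mu), mu, base_sd_um3)
  data.frame(
    cell_id = seq_along(mu),
    phase = phase,
    dividing = dividing,
    cell_volume_um3 = vol,
    nuclear_volume_um3 = vol * stats::runif(length(mu), 0.26, 0.30)
  )
}
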