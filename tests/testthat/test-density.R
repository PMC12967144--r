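vs <- c(30, 30, 30)

## ellipsoid mask with semi-axes (in voxels) a > b > c along x, y, z
aligned_ellipsoid <- function(a = 25, b = 15, c0 = 10) digital_ellipsoid(a, b, c0)

test_that("alignment orders variances and is orthonormal", {
  m <- aligned_ellipsoid()
  tr <- align_to_major_axes(m, vs)
  expect_false(tr$degenerate)
  expect_true(all(diff(tr$axis_variance) <= 0))
  expect_equal(tr$rotation %*% t(tr$rotation), diag(3), tolerance = 1e-9)
  ## the aligned-frame variances must be descending after transform
  idx <- which(m, arr.ind = TRUE)
  P <- cbind((idx[, 3] - 0.5) * 30, (idx[, 2] - 0.5) * 30, (idx[, 1] - 0.5) * 30)
  A <- apply_alignment(tr, P)
  v <- apply(A, 2, var)
  expect_true(v[1] >= v[2] && v[2] >= v[3])
})

test_that("an axis-aligned ellipsoid aligns to the identity up to sign", {
  tr <- align_to_major_axes(aligned_ellipsoid(), vs)
  expect_equal(abs(tr$rotation), diag(3), tolerance = 1e-6)
})

test_that("a ball is degenerate and gets the identity", {
  tr <- align_to_major_axes(digital_ball(10), vs)
  expect_true(tr$degenerate)
  expect_equal(tr$rotation, diag(3))
})

test_that("alignment is idempotent", {
  m <- aligned_ellipsoid()
  tr <- align_to_major_axes(m, vs)
  ## already axis-aligned: applying the (sign-canonical) transform again
  ## must stay within numerical noise of the identity
  expect_equal(abs(tr$rotation %*% tr$rotation), diag(3), tolerance = 1e-6)
})

test_that("3x3 density grid counts conserve and match brute-force binning", {
  m <- aligned_ellipsoid()
  tr <- align_to_major_axes(m, vs)
  set.seed(20)
  ## centroids sampled from inside the mask, jittered off the voxel lattice
  ## (the binning rule is compared away from region boundaries)
  idx <- which(m, arr.ind = TRUE)
  pick <- idx[sample(nrow(idx), 40), ]
  cen <- cbind((pick[, 3] - 0.5) * 30, (pick[, 2] - 0.5) * 30,
               (pick[, 1] - 0.5) * 30) + matrix(runif(120, -9, 9), 40, 3)
  g <- regional_density_3x3(cen, m, vs, tr)
  expect_equal(sum(g$counts), 40)
  expect_equal(g$n_outside, 0)
  ## brute-force binning oracle in the aligned frame
  ap <- apply_alignment(tr, cen)
  brute <- matrix(0L, 3, 3)
  for (r in seq_len(nrow(ap))) {
    ci <- min(max(ceiling((ap[r, 1] - g$bbox$x[1]) / diff(g$bbox$x) * 3), 1), 3)
    cj <- min(max(ceiling((ap[r, 2] - g$bbox$y[1]) / diff(g$bbox$y) * 3), 1), 3)
    brute[cj, ci] <- brute[cj, ci] + 1L
  }
  expect_equal(g$counts, brute)
  expect_true(all(g$density_per_um2 >= 0, na.rm = TRUE))
})

test_that("a central point cluster makes the centre region the argmax", {
  m <- aligned_ellipsoid()
  com <- compute_com(m, vs)
  cen <- matrix(rep(com, each = 12), 12, 3) +
    matrix(rnorm(36, sd = 60), 12, 3)
  g <- regional_density_3x3(cen, m, vs)
  expect_equal(which.max(g$density_per_um2), 5L)   # (2,2) of the 3x3
})

test_that("density grid is invariant to rigid rotation of the scene", {
  m <- aligned_ellipsoid(20, 12, 8)
  set.seed(21)
  idx <- which(m, arr.ind = TRUE)
  pick <- idx[sample(nrow(idx), 25), ]
  ## sub-voxel jitter keeps centroids off region-boundary lattice lines
  cen <- cbind((pick[, 3] - 0.5) * 30 + 7.3, (pick[, 2] - 0.5) * 30 - 3.1,
               (pick[, 1] - 0.5) * 30 + 5.9)
  g1 <- regional_density_3x3(cen, m, vs)
  ## rotate the whole scene 90 degrees about z: (x, y) -> (-y, x)
  m2 <- aperm(m, c(1, 3, 2))[, , dim(m)[2]:1]
  cen2 <- cbind((dim(m)[2] * 30) - cen[, 2], cen[, 1], cen[, 3])
  g2 <- regional_density_3x3(cen2, m2, vs)
  expect_equal(sort(as.vector(g1$counts)), sort(as.vector(g2$counts)))
  expect_equal(sort(round(as.vector(g1$density_per_um2), 6)),
               sort(round(as.vector(g2$density_per_um2), 6)))
})

test_that("hotspot map is unimodal for one centroid and integrates to n", {
  m <- aligned_ellipsoid()
  com <- compute_com(m, vs)
  hm1 <- hotspot_map(matrix(com + c(200, -150, 0), 1, 3), m, vs,
                     bandwidth_nm = 300)
  peak <- which(hm1$z == max(hm1$z), arr.ind = TRUE)
  ## the cell is axis-aligned, so the aligned frame is centred on the COM
  ## (sign convention may mirror an axis)
  expect_lt(abs(abs(hm1$x[peak[1]]) - 200), 100)
  expect_lt(abs(abs(hm1$y[peak[2]]) - 150), 100)
  ## integral ~ centroid count when kernels lie inside the window
  set.seed(22)
  cen <- matrix(rep(com, each = 30), 30, 3) + matrix(rnorm(90, sd = 100), 30, 3)
  hm <- hotspot_map(cen, m, vs, bandwidth_nm = 150)
  integral <- sum(hm$z) * diff(hm$x[1:2]) * diff(hm$y[1:2])
  expect_lt(abs(integral / 30 - 1), 0.02)
  expect_error(hotspot_map(matrix(numeric(0), 0, 3), m, vs), "at least one")
})

test_that("two distant equal clusters give two near-equal maxima", {
  m <- aligned_ellipsoid()
  com <- compute_com(m, vs)
  off <- c(450, 0, 0)
  set.seed(23)
  cen <- rbind(matrix(rep(com + off, each = 20), 20, 3),
               matrix(rep(com - off, each = 20), 20, 3)) +
    matrix(rnorm(120, sd = 40), 40, 3)
  hm <- hotspot_map(cen, m, vs, bandwidth_nm = 100)
  ## the field restricted to each aligned-frame half has its own maximum
  half <- hm$x < 0
  m1 <- max(hm$z[!half, ]); m2 <- max(hm$z[half, ])
  expect_lt(abs(m1 / m2 - 1), 0.05)
})

test_that("phase stacking averages grids and rejects mixed classes", {
  m <- aligned_ellipsoid(15, 10, 7)
  set.seed(24)
  idx <- which(m, arr.ind = TRUE)
  mkgrid <- function(n) {
    pick <- idx[sample(nrow(idx), n), ]
    cen <- cbind((pick[, 3] - 0.5) * 30, (pick[, 2] - 0.5) * 30,
                 (pick[, 1] - 0.5) * 30)
    regional_density_3x3(cen, m, vs)
  }
  g1 <- mkgrid(10)
  s1 <- stack_phase_heatmaps(list(g1))
  expect_equal(s1$density_per_um2, g1$density_per_um2)
  s2 <- stack_phase_heatmaps(list(g1, g1))
  expect_equal(s2$density_per_um2, g1$density_per_um2)
  g2 <- mkgrid(15)
  s3 <- stack_phase_heatmaps(list(g1, g2))
  expect_equal(s3$density_per_um2, (g1$density_per_um2 + g2$density_per_um2) / 2)
  expect_error(stack_phase_heatmaps(list(g1, g2), classes = c("ER", "vesicle")),
               "mixed")
})
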