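## Digital test solids built in code.

digital_ball <- function(r, extra = 3) {
  n <- 2 * (r + extra) + 1
  c0 <- r + extra + 1
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2, c(n, n, n))
}

digital_cube <- function(n, extra = 2) {
  N <- n + 2 * extra
  a <- array(FALSE, c(N, N, N))
  idx <- (extra + 1):(extra + n)
  a[idx, idx, idx] <- TRUE
  a
}

digital_ellipsoid <- function(a, b, c0, extra = 3) {
  nx <- 2 * (a + extra) + 1; ny <- 2 * (b + extra) + 1; nz <- 2 * (c0 + extra) + 1
  cx <- a + extra + 1; cy <- b + extra + 1; cz <- c0 + extra + 1
  g <- expand.grid(z = 1:nz, y = 1:ny, x = 1:nx)
  array(((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 + ((g$z - cz) / c0)^2 <= 1,
        c(nz, ny, nx))
}

random_blob <- function(seed, n = 12, p = 0.4) {
  set.seed(seed)
  a <- array(stats::runif(n^3) < p, c(n, n, n))
  a[1, , ] <- a[n, , ] <- FALSE
  a
}

## small deterministic chromatid table from the ovine template with optional
## multiplicative volume noise
noisy_template <- function(seed = 1, vol_noise = 0) {
  tpl <- default_ovine_template()
  set.seed(seed)
  if (vol_noise > 0)
    tpl$volume_um3 <- tpl$volume_um3 * (1 + stats::rnorm(nrow(tpl), 0, vol_noise))
  data.frame(object_id = tpl$chromatid_id,
             pair_label = tpl$pair_label,
             volume_um3 = tpl$volume_um3,
             centromere_class = tpl$centromere_class)
}
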