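## Well-separated Gaussian blob generator for cluster-recovery tests.
gaussian_blobs <- function(k, n_per, sep_sd, noise_sd = 1, seed = 1) {
  set.seed(seed)
  repeat {
    ctr <- matrix(stats::rnorm(3 * k, sd = sep_sd), k, 3)
    if (k == 1 || min(stats::dist(ctr)) >= 10 * noise_sd) break
  }
  pts <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(stats::rnorm(3 * n_per, sd = noise_sd), n_per, 3), 2,
          ctr[i, ], "+")))
  list(points = pts, labels = rep(seq_len(k), each = n_per))
}

## purity of a clustering against planted labels
label_purity <- function(found, planted) {
  tab <- table(found, planted)
  sum(apply(tab, 1, max)) / length(found)
}
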