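test_that("centromere class thresholds follow the Levan convention", {
  expect_equal(classify_centromere(1.0), "metacentric")
  expect_equal(classify_centromere(1.7), "metacentric")
  expect_equal(classify_centromere(2.0), "submetacentric")
  expect_equal(classify_centromere(3.0), "submetacentric")
  expect_equal(classify_centromere(5.0), "acrocentric")
  expect_error(classify_centromere(0.5), ">= 1")
})

test_that("centromere detection recovers planted arm ratios", {
  vs <- c(90, 90, 90)
  rod1 <- generate_chromatid(3.5, 1, vs, seed = 6)
  cd1 <- centromere_detect(rod1$mask, vs)
  expect_gte(cd1$arm_ratio, 1)
  expect_lte(cd1$arm_ratio, 1.3)
  expect_equal(cd1$centromere_class, "metacentric")
  ## waist at 20% of length -> arm ratio ~ 4
  rod4 <- generate_chromatid(3.5, 4, vs, seed = 5)
  cd4 <- centromere_detect(rod4$mask, vs)
  expect_lt(abs(cd4$arm_ratio / 4 - 1), 0.25)
  rod5 <- generate_chromatid(3.0, 5, vs, seed = 8)
  expect_equal(centromere_detect(rod5$mask, vs)$centromere_class, "acrocentric")
  ## a ball has no elongation: unresolved, not an error
  expect_equal(centromere_detect(digital_ball(8), c(30, 30, 30))$centromere_class,
               "unresolved")
  ## fragmented mask: unresolved
  frag <- array(FALSE, c(4, 4, 12)); frag[2, 2, 1:4] <- TRUE; frag[2, 2, 9:12] <- TRUE
  expect_equal(centromere_detect(frag, vs)$centromere_class, "unresolved")
})

test_that("exact duplicate volumes pair trivially", {
  ch <- data.frame(object_id = 1:6,
                   volume_um3 = c(9, 5, 2, 9, 5, 2),
                   centromere_class = rep("acrocentric", 6))
  pr <- pair_homologs(ch)
  expect_equal(nrow(pr$pairs), 3)
  expect_equal(length(pr$unpaired), 0)
  vols <- lapply(seq_len(3), function(i)
    ch$volume_um3[ch$object_id %in% unlist(pr$pairs[i, c("object_a", "object_b")])])
  for (v in vols) expect_equal(v[1], v[2])
})

test_that("ovine template pairing with 1% volume noise recovers every true pair", {
  ## the ovine template's acro II pairs differ by only ~4% in volume, so the
  ## within-pair noise must stay well below the between-pair gaps
  for (seed in 1:3) {
    tp <- noisy_template(seed, vol_noise = 0.01)
    pr <- pair_homologs(tp)
    expect_equal(nrow(pr$pairs), 26)
    expect_setequal(pr$unpaired, c(53, 54))            # X and Y stay unpaired
    ok <- mapply(function(a, b) (a %% 2 == 1) && (b == a + 1),
                 pr$pairs$object_a, pr$pairs$object_b)
    expect_true(all(ok))
  }
})

test_that("2% noise pairs perfectly when between-pair volumes are distinct", {
  pv <- 9 * 0.88^(0:25)                  # 12% gaps between adjacent pairs
  for (seed in 1:3) {
    tp <- data.frame(object_id = 1:52,
                     volume_um3 = rep(pv, each = 2),
                     centromere_class = rep(c(rep("metacentric", 3),
                                              rep("acrocentric", 23)), each = 2))
    set.seed(seed + 500)
    tp$volume_um3 <- tp$volume_um3 * (1 + rnorm(52, 0, 0.02))
    pr <- pair_homologs(tp)
    expect_equal(nrow(pr$pairs), 26)
    ok <- mapply(function(a, b) (a %% 2 == 1) && (b == a + 1),
                 pr$pairs$object_a, pr$pairs$object_b)
    expect_true(all(ok))
  }
})

test_that("pairing is invariant under input permutation", {
  tp <- noisy_template(7, vol_noise = 0.01)
  pr1 <- pair_homologs(tp)
  set.seed(1)
  pr2 <- pair_homologs(tp[sample(nrow(tp)), ])
  expect_equal(pr1$pairs, pr2$pairs)
})

test_that("sex chromosomes are the largest submetacentric / smallest acrocentric", {
  tp <- noisy_template(2, vol_noise = 0.01)
  pr <- pair_homologs(tp)
  sex <- identify_sex_chromosomes(tp, pr$unpaired)
  expect_equal(sex$X, 53L)
  expect_equal(sex$Y, 54L)
  ## all paired -> both null
  sex0 <- identify_sex_chromosomes(tp, integer(0))
  expect_true(is.na(sex0$X) && is.na(sex0$Y))
  ## X volume perturbed +-10% is still recovered
  for (f in c(0.9, 1.1)) {
    tp2 <- noisy_template(3, vol_noise = 0.01)
    tp2$volume_um3[53] <- 4.2 * f
    pr2 <- pair_homologs(tp2)
    expect_equal(identify_sex_chromosomes(tp2, pr2$unpaired)$X, 53L)
  }
})

test_that("volume-group boundaries follow the stated partition", {
  expect_equal(assign_karyotype_group(3.5, "acrocentric", NA), "acro_I")
  expect_equal(assign_karyotype_group(2.5, "acrocentric", NA), "acro_II")
  expect_equal(assign_karyotype_group(3.0, "acrocentric", NA), "acro_II")  # boundary
  expect_equal(assign_karyotype_group(2.0, "acrocentric", NA), "acro_II")  # inclusive
  expect_equal(assign_karyotype_group(1.9, "acrocentric", NA), "acro_III")
  expect_equal(assign_karyotype_group(8.0, "metacentric", NA), "metacentric")
  expect_equal(assign_karyotype_group(4.2, "submetacentric", "X"), "X")
  expect_warning(g <- assign_karyotype_group(4.2, "submetacentric", NA))
  expect_equal(g, "unresolved")
  expect_error(assign_karyotype_group(0), "positive")
})

test_that("the default ovine template builds the full 3/6/8/9 + X + Y karyotype", {
  tp <- noisy_template(1, vol_noise = 0)
  kt <- build_karyotype(tp)
  expect_equal(kt$n_chromatids, 54)
  expect_false(kt$count_mismatch)
  grp <- table(kt$table$karyotype_group)
  expect_equal(unname(grp["metacentric"]), 3L)
  expect_equal(unname(grp["acro_I"]), 6L)
  expect_equal(unname(grp["acro_II"]), 8L)
  expect_equal(unname(grp["acro_III"]), 9L)
  expect_equal(unname(grp["X"]), 1L)
  expect_equal(unname(grp["Y"]), 1L)
  ## autosome numbering is a strict weak order on mean volume
  auto <- kt$table[!(kt$table$chromosome %in% c("X", "Y")), ]
  expect_equal(auto$chromosome, as.character(1:26))
  expect_true(all(diff(auto$mean_volume_um3) <= 0))
  ## every chromatid lands in exactly one group
  assigned <- c(kt$table$object_a, kt$table$object_b)
  expect_setequal(assigned[!is.na(assigned)], tp$object_id)
  expect_length(kt$unassigned, 0)
})

test_that("karyotype is stable under shuffling and flags missing chromatids", {
  tp <- noisy_template(5, vol_noise = 0.01)
  kt1 <- build_karyotype(tp)
  set.seed(2)
  kt2 <- build_karyotype(tp[sample(nrow(tp)), ])
  expect_equal(kt1$table, kt2$table)
  kt3 <- build_karyotype(tp[-10, ])
  expect_true(kt3$count_mismatch)
  expect_equal(kt3$n_chromatids, 53)
})

test_that("group assignment is perfect when no pair straddles a threshold", {
  ## property: templates built away from the 2 / 3 um^3 boundaries keep their
  ## planted groups under <= 5% volume noise
  for (seed in 1:5) {
    set.seed(seed)
    tp <- noisy_template(seed + 100, vol_noise = 0.02)
    ## drop pairs whose noisy mean is within 6% of a boundary
    kt <- build_karyotype(tp)
    auto <- kt$table[!(kt$table$chromosome %in% c("X", "Y")), ]
    safe <- abs(auto$mean_volume_um3 - 3) / 3 > 0.06 &
      abs(auto$mean_volume_um3 - 2) / 2 > 0.06
    planted <- ifelse(auto$mean_volume_um3 > 3,
                      ifelse(auto$karyotype_group == "metacentric",
                             "metacentric", "acro_I"),
               ifelse(auto$mean_volume_um3 >= 2, "acro_II", "acro_III"))
    expect_equal(auto$karyotype_group[safe], planted[safe])
  }
})
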