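test_that("the ovine template has the full diploid composition", {
  tpl <- default_ovine_template()
  expect_equal(nrow(tpl), 54)
  expect_equal(sum(tpl$centromere_class == "metacentric"), 6)     # 3 pairs
  expect_equal(sum(tpl$centromere_class == "submetacentric"), 1)  # X
  expect_equal(sum(tpl$centromere_class == "acrocentric"), 47)    # 23 pairs + Y
  expect_true(all(tpl$volume_um3 > 0))
  ## autosome volumes are pairwise duplicated
  auto <- tpl[!(tpl$pair_label %in% c("X", "Y")), ]
  for (p in unique(auto$pair_label))
    expect_equal(diff(auto$volume_um3[auto$pair_label == p]), 0)
  ## group sizes by the published thresholds
  pv <- auto$volume_um3[seq(1, nrow(auto), 2)]
  cls <- auto$centromere_class[seq(1, nrow(auto), 2)]
  expect_equal(sum(cls == "metacentric"), 3)
  expect_equal(sum(cls == "acrocentric" & pv > 3), 6)
  expect_equal(sum(cls == "acrocentric" & pv >= 2 & pv <= 3), 8)
  expect_equal(sum(cls == "acrocentric" & pv < 2), 9)
})

test_that("chromatid masks hit their target volume", {
  vs <- c(90, 90, 90)
  ch <- generate_chromatid(3.5, 2, vs, seed = 40)
  target_vox <- 3.5 / (0.09^3)
  expect_lt(abs(sum(ch$mask) - target_vox) / target_vox, 0.05)
  expect_error(generate_chromatid(0.001, 2, c(90, 90, 90)), "below resolution")
  ## deterministic per seed
  ch2 <- generate_chromatid(3.5, 2, vs, seed = 40)
  expect_identical(ch$mask, ch2$mask)
  ch3 <- generate_chromatid(3.5, 2, vs, seed = 41)
  expect_false(identical(ch$mask, ch3$mask))
})

small_spec <- function(seed, phase = "metaphase",
                       mito = 8, er = 6, ves = 6,
                       mito_pattern = "uniform") {
  tpl <- default_ovine_template()
  tpl$volume_um3 <- tpl$volume_um3 / 6
  phantom_spec(
    seed = seed, voxel_size = c(120, 120, 120), phase = phase,
    cell_semi_axes_um = c(4, 3.8, 3.2),
    chromosome_template = tpl,
    organelles = list(
      mitochondrion = list(count = mito, mean_volume_um3 = 0.2,
                           pattern = mito_pattern),
      ER = list(count = er, mean_volume_um3 = 0.12, pattern = "uniform"),
      vesicle = list(count = ves, mean_volume_um3 = 0.08, pattern = "uniform")))
}

test_that("phantom cells are complete, disjoint and deterministic", {
  ph <- generate_phantom_cell(small_spec(50))
  lab <- ph$labels$labels
  ids <- sort(unique(as.vector(lab))); ids <- ids[ids != 0]
  ## ground-truth completeness: every nonzero label has a truth row
  expect_setequal(ids, ph$truth$object_id)
  expect_setequal(ids, ph$labels$object_index$object_id)
  ## classes partition the objects
  expect_true(all(ph$truth$class %in% OBJECT_CLASSES))
  ## voxel disjointness: per-object counts sum to the nonzero voxel count
  expect_equal(sum(ph$truth$voxel_count), sum(lab != 0))
  ## requested organelle counts are realised exactly
  expect_equal(sum(ph$truth$class == "mitochondrion"), 8)
  expect_equal(sum(ph$truth$class == "chromosome"), 54)
  ## same seed -> bit-identical volumes
  ph2 <- generate_phantom_cell(small_spec(50))
  expect_identical(ph$labels$labels, ph2$labels$labels)
  expect_identical(ph$intensity$data, ph2$intensity$data)
})

test_that("nuclear envelope logic follows the phase", {
  pro <- generate_phantom_cell(small_spec(51, phase = "prophase_II"))
  expect_true("nucleus" %in% pro$truth$class)
  ## chromosomes lie inside the nuclear envelope: their voxels never touch
  ## the cytoplasmic cell label region boundary; test via the nucleus
  ## ellipsoid inequality at each chromosome COM (deep inside)
  met <- generate_phantom_cell(small_spec(52, phase = "metaphase"))
  expect_false("nucleus" %in% met$truth$class)
  ## prophase chromosome COMs sit closer to the centre than the nuclear
  ## envelope semi-axis
  chr <- pro$truth[pro$truth$class == "chromosome", ]
  expect_true(all(chr$displacement_um < 0.74 * 4))
})

test_that("the stain model separates classes at the planted means", {
  ph <- generate_phantom_cell(small_spec(53))
  lab <- ph$labels$labels; int <- ph$intensity$data
  cls <- ph$truth$class[match(lab[lab != 0], ph$truth$object_id)]
  vals <- int[lab != 0]
  for (cl in c("chromosome", "mitochondrion", "vesicle")) {
    mu <- mean(vals[cls == cl])
    expect_lt(abs(mu - STAIN_DEFAULTS[cl]), 3)
  }
  expect_lt(abs(mean(int[lab == 0]) - STAIN_DEFAULTS["background"]), 3)
})

test_that("measured morphometry recovers phantom target volumes within 5%", {
  ph <- generate_phantom_cell(small_spec(54))
  m <- morphometry_table(ph$labels, surface = FALSE)
  j <- merge(m, ph$truth[, c("object_id", "target_volume_um3", "carved")],
             by = "object_id")
  j <- j[!j$carved & j$voxel_count >= 200, ]
  expect_gt(nrow(j), 30)
  err <- abs(j$volume_um3 - j$target_volume_um3) / j$target_volume_um3
  expect_lt(max(err), 0.05)
  ## carved containers conserve volume with their contents
  cellrow <- ph$truth[ph$truth$class == "cell", ]
  inside <- m$volume_um3[m$object_id != cellrow$object_id]
  total <- m$volume_um3[m$object_id == cellrow$object_id] + sum(inside)
  expect_lt(abs(total / cellrow$target_volume_um3 - 1), 0.05)
})

test_that("phase series plants recoverable organelle and displacement trends", {
  base <- small_spec(55)
  eff <- phase_effect_table()
  ser <- generate_phase_series(base, eff, seed = 55)
  expect_named(ser, PHASE_LEVELS)
  disp <- sapply(ser, function(p) {
    chr <- p$truth[p$truth$class == "chromosome", ]
    if (!nrow(chr)) NA else mean(chr$displacement_um)
  })
  expect_true(is.na(disp[["non_dividing"]]))
  expect_true(all(diff(disp[!is.na(disp)]) >= -1e-9))
  ## telophase mitochondria follow the central hotspot pattern
  tel <- ser$telophase
  expect_equal(unique(tel$truth$pattern[tel$truth$class == "mitochondrion"]),
               "central_hotspot")
  ## vesicle count peaks at metaphase
  vc <- sapply(ser, function(p) sum(p$truth$class == "vesicle"))
  expect_equal(names(which.max(vc)), "metaphase")
})

test_that("numeric phase tables plant the requested volume effect", {
  tb <- generate_phase_table(seed = 60)
  expect_equal(sum(!tb$dividing), 8)
  expect_equal(sum(tb$dividing), 9)
  expect_gt(mean(tb$cell_volume_um3[tb$dividing]),
            mean(tb$cell_volume_um3[!tb$dividing]))
  tb0 <- generate_phase_table(seed = 60, effect_sd = 0)
  expect_lt(abs(mean(tb0$cell_volume_um3[tb0$dividing]) -
                  mean(tb0$cell_volume_um3[!tb0$dividing])), 150)
})
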