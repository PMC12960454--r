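mk_barcode <- function(lifetimes, essential_policy = "kill_at_min") {
  cossr:::.barcode(cbind(lifetimes, 0), essential_policy)
}

test_that("barcode norms and ratio statistic match hand values", {
  expect_equal(barcode_norm(mk_barcode(c(3, 4)), p = 2), 5)
  expect_equal(barcode_norm(mk_barcode(c(2, 1)), p = Inf), 2)
  expect_equal(barcode_norm(mk_barcode(numeric(0))), 0)
  expect_equal(barcode_norm(mk_barcode(c(2, 2)), p = 1), 4)
  expect_error(barcode_norm(mk_barcode(c(1, 2)), p = 0.5), "p must be")

  expect_equal(ratio_statistic(mk_barcode(5)), 5)
  expect_equal(ratio_statistic(mk_barcode(c(2, 2, 1))), 2 / 3)
  expect_equal(ratio_statistic(mk_barcode(c(0, 0))), 0)
  expect_equal(ratio_statistic(mk_barcode(c(2, 2, 1)), l0 = "l1"), 2 / 5)
  # L^p monotone nonincreasing in p on a fixed barcode
  bc <- mk_barcode(c(0.5, 1, 2, 3))
  ps <- c(1, 1.5, 2, 3, 6, Inf)
  norms <- vapply(ps, function(p) barcode_norm(bc, p), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("coss pipeline: uniform is zero, scaling is invisible, zero
           features are flagged not dropped", {
  s <- hex_fixture(12, 12, list(
    unif = pattern_uniform(4),
    hot = pattern_hotspot(rbind(c(0.25, 0.25), c(0.75, 0.75)), 60, 0.08),
    dead = pattern_uniform(4)))
  s$matrix["dead", ] <- 0
  expect_message(tab <- coss(s, m = 0.1), "all-zero")
  expect_s3_class(tab, "coss_table")
  expect_equal(tab$coss[tab$feature_id == "unif"], 0)
  expect_gt(tab$coss[tab$feature_id == "hot"], 0)
  expect_equal(tab$n_bars[tab$feature_id == "hot"], 2)
  expect_true(is.na(tab$coss[tab$feature_id == "dead"]))
  expect_equal(tab$flag[tab$feature_id == "dead"], "all_zero")
  # positive rescaling of counts leaves the score untouched
  s2 <- s
  s2$matrix["hot", ] <- s2$matrix["hot", ] * 431.7
  tab2 <- suppressMessages(coss(s2, m = 0.1))
  expect_equal(tab2$coss[tab2$feature_id == "hot"],
               tab$coss[tab$feature_id == "hot"])
  expect_error(coss(s, m = 2), "in \\(0, 1\\)")
})

test_that("coss is invariant under well relabeling and rigid motion", {
  s <- hex_fixture(12, 12, list(
    hot = pattern_hotspot(rbind(c(0.3, 0.4), c(0.7, 0.6)), 50, 0.1)),
    noise = "poisson", seed = 6)
  ref <- coss(s, m = 0.1)$coss
  # relabel wells: permute columns and realign from permuted coordinates
  set.seed(2)
  perm <- sample(n_wells(s$lattice))
  lat_p <- align_to_lattice(s$lattice$coords[perm, ])
  expect_equal(coss(lat_p, s$matrix[, perm, drop = FALSE], m = 0.1)$coss, ref)
  # rigid motion: rotate by 23 degrees and translate, then realign
  th <- 23 * pi / 180
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  lat_r <- align_to_lattice(s$lattice$coords %*% t(Rm) + 1000)
  expect_equal(coss(lat_r, s$matrix, m = 0.1)$coss, ref, tolerance = 1e-9)
})

test_that("spiked mass yields one dominant bar and a large ratio", {
  feats <- list(spike = pattern_single_well_spike(100),
                hot = pattern_hotspot(rbind(c(0.25, 0.25), c(0.7, 0.7),
                                            c(0.25, 0.75)), 60, 0.07))
  s <- hex_fixture(16, 16, feats, seed = 9)
  tab <- coss(s, m = 0.05)
  spike <- tab[tab$feature_id == "spike", ]
  hot <- tab[tab$feature_id == "hot", ]
  expect_equal(spike$n_bars, 1)
  expect_gt(spike$ratio, 3 * hot$ratio)
  # optional artifact flag
  tab2 <- coss(s, m = 0.05, ratio_flag = spike$ratio * 0.9)
  expect_equal(tab2$flag[tab2$feature_id == "spike"], "high_ratio")
  expect_equal(tab2$flag[tab2$feature_id == "hot"], "")
})

test_that("a structured pattern beats its own spatial-permutation null", {
  s <- hex_fixture(14, 14, list(
    hot = pattern_hotspot(rbind(c(0.3, 0.3), c(0.7, 0.7)), 50, 0.08)),
    noise = "nb", seed = 21)
  ctx <- dtm_context(s$lattice)
  orig <- coss(s, m = 0.1, context = ctx)$coss
  nulls <- vapply(1:60, function(b) {
    sp <- spatial_permutation(s, "hot", seed = b)
    coss(sp$lattice, sp$matrix, m = 0.1, context = ctx)$coss
  }, numeric(1))
  expect_gt(orig, quantile(nulls, 0.95))
})
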