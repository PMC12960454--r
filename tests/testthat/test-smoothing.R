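test_that("normalize_weights rescales and rejects empty features", {
  expect_equal(normalize_weights(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(normalize_weights(c(0, 0, 7)), c(0, 0, 1))
  expect_error(normalize_weights(c(0, 0, 0), "geneX"), "geneX")
  expect_error(normalize_weights(c(1, -1, 3)), "negative")
  expect_error(normalize_weights(c(1, NA)), "non-finite")
})

test_that("dtm closed forms hold on a complete hex lattice", {
  s <- hex_fixture(10, 10, list(u = pattern_uniform(5)))
  lat <- s$lattice
  w <- rep(1 / 100, 100)
  f <- weighted_dtm(lat, w, m = 0.07)
  expect_s3_class(f, "scalar_field")
  expect_equal(f$stage, "dtm")
  # k = 7 everywhere: (0 + 6 * spacing^2) / 7
  expect_equal(f$values, rep(6 / 7 * lat$spacing^2, 100), tolerance = 1e-12)
  # any well whose own weight >= m has dtm 0 (d_1 = 0)
  w2 <- normalize_weights(c(50, rep(1, 99)))
  f2 <- weighted_dtm(lat, w2, m = 0.2)
  expect_equal(f2$values[1], 0)
  expect_error(weighted_dtm(lat, w, m = 1.5), "in \\(0, 1\\)")
  expect_error(weighted_dtm(lat, w, m = 0), "in \\(0, 1\\)")
})

test_that("dtm agrees with the naive per-well oracle", {
  set.seed(5)
  s <- hex_fixture(8, 9, list(a = pattern_hotspot(c(0.3, 0.6), 40, 0.15),
                              b = pattern_uniform(3)),
                   noise = "poisson", jitter_sd = 0.5, seed = 8)
  lat <- s$lattice
  for (fid in rownames(s$matrix)) {
    w <- normalize_weights(s$matrix[fid, ] + 0.01)
    for (m in c(0.05, 0.1, 0.3)) {
      expect_equal(weighted_dtm(lat, w, m)$values, naive_dtm(lat, w, m),
                   tolerance = 1e-12, info = paste(fid, m))
    }
  }
  # single massive well: dtm at another well = mean of first r ideal d^2,
  # r = rank of the massive well in its distance order
  w <- c(1, rep(0, n_wells(lat) - 1))
  f <- weighted_dtm(lat, w, m = 0.5)
  expect_equal(f$values[1], 0)
  expect_equal(f$values, naive_dtm(lat, w, 0.5), tolerance = 1e-12)
})

test_that("dtm is scale invariant and monotone in m", {
  s <- hex_fixture(9, 9, list(h = pattern_hotspot(c(0.5, 0.5), 30, 0.2)),
                   noise = "nb", seed = 4)
  raw <- s$matrix[1, ] + 1
  lat <- s$lattice
  expect_equal(weighted_dtm(lat, normalize_weights(17.3 * raw), 0.1)$values,
               weighted_dtm(lat, normalize_weights(raw), 0.1)$values)
  ms <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8)
  vals <- sapply(ms, function(m) {
    weighted_dtm(lat, normalize_weights(raw), m)$values
  })
  expect_true(all(diff(t(vals)) >= -1e-12))
})

test_that("network dtm is unchanged when distant zero-weight wells vanish", {
  # pattern mass confined to the center (baseline 0); the masked sample is
  # the SAME sample with a frame of zero-weight boundary wells removed.
  # dtm must be identical at every well whose mass radius (distance to its
  # k-th nearest well in the full lattice) does not reach a removed well.
  full <- hex_fixture(15, 15, list(h = pattern_hotspot(c(0.5, 0.5), 50,
                                                       0.1, baseline = 0)))
  full$matrix[1, full$matrix[1, ] < 0.5] <- 0    # clip the Gaussian tail
  ic <- full$lattice$ideal_coords
  lo <- apply(ic, 2, min)
  rel <- sweep(sweep(ic, 2, lo), 2, apply(ic, 2, max) - lo, "/")
  keep <- rel[, 1] > 0.15 & rel[, 1] < 0.85 & rel[, 2] > 0.15 &
    rel[, 2] < 0.85
  expect_true(all(full$matrix[1, !keep] == 0))   # frame carries no weight
  cut <- sample_data(well_lattice(full$lattice$axial_index[keep, ],
                                  "hexagonal", full$lattice$spacing),
                     full$matrix[, keep, drop = FALSE])
  w_full <- normalize_weights(full$matrix[1, ])
  f_full <- weighted_dtm(full$lattice, w_full, m = 0.1)
  f_cut <- weighted_dtm(cut$lattice, normalize_weights(cut$matrix[1, ]),
                        m = 0.1)
  # per-well mass radius in the full lattice
  n <- n_wells(full$lattice)
  removed <- which(!keep)
  kept <- which(keep)
  safe <- vapply(kept, function(p) {
    d2 <- (ic[, 1] - ic[p, 1])^2 + (ic[, 2] - ic[p, 2])^2
    o <- order(d2, seq_len(n))
    k <- which(cumsum(w_full[o]) >= 0.1 - 1e-12)[1]
    # one-shell margin so the condition is robust to tie handling at k
    min(d2[removed]) > d2[o[min(k + 7, n)]] + 1e-9
  }, logical(1))
  expect_gt(sum(safe), 20)
  expect_equal(f_cut$values[match(kept[safe], kept)],
               f_full$values[kept[safe]], tolerance = 1e-12)
})

test_that("network dtm equals Euclidean dtm for interior wells of a
           complete lattice with uniform weights", {
  s <- hex_fixture(14, 14, list(u = pattern_uniform(5)))
  lat <- s$lattice
  n <- n_wells(lat)
  w <- rep(1 / n, n)
  net <- weighted_dtm(lat, w, m = 0.05)$values
  euc <- weighted_dtm(lat, w, m = 0.05, distances = "euclidean")$values
  # interior: wells at least 3 rings from the boundary (mass radius ~2)
  ctr <- colMeans(lat$ideal_coords)
  d2c <- rowSums(sweep(lat$ideal_coords, 2, ctr)^2)
  interior <- which(d2c <= (3 * lat$spacing)^2)
  expect_gt(length(interior), 5)
  expect_equal(net[interior], euc[interior], tolerance = 1e-9)
})

test_that("invert_field flips about the maximum", {
  f <- scalar_field(c(0.2, 0.5, 0.5), "dtm")
  expect_equal(invert_field(f)$values, c(0.3, 0, 0))
  expect_equal(invert_field(scalar_field(rep(2, 5), "dtm"))$values, rep(0, 5))
  g <- scalar_field(c(0.2, 0.5, 0.5) + 3.7, "dtm")
  expect_equal(invert_field(g)$values, invert_field(f)$values)
  expect_error(invert_field(invert_field(f)), "stage")
  expect_error(invert_field(c(1, 2, 3)), "stage")
})
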