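path3 <- function(z) filtered_complex(z, rbind(c(1, 2), c(2, 3)))

test_that("build_filtration applies the upper-star min rule", {
  s <- hex_fixture(6, 6, list(u = pattern_uniform(3)))
  f <- invert_field(weighted_dtm(s$lattice,
                                 normalize_weights(s$matrix[1, ] + seq_len(36)),
                                 0.1))
  fc <- build_filtration(s$lattice, f)
  expect_equal(fc$edge_value,
               pmin(fc$z[fc$edges[, 1]], fc$z[fc$edges[, 2]]))
  expect_true(all(fc$edge_value <= fc$z[fc$edges[, 1]]))
  expect_error(build_filtration(s$lattice, weighted_dtm(
    s$lattice, rep(1 / 36, 36), 0.1)), "inverted")
  fc3 <- path3(c(3, 1, 2))
  expect_equal(fc3$edge_value, c(1, 1))
})

test_that("hand-checkable barcodes are exact", {
  bc <- superlevel_persistence(path3(c(3, 1, 2)))
  expect_equal(bars_multiset(bc), rbind(c(2, 1), c(3, 1)),
               ignore_attr = TRUE)
  expect_equal(sort(lifetimes(bc)), c(1, 2))
  bc2 <- superlevel_persistence(path3(c(2, 0, 2)))
  expect_equal(bars_multiset(bc2), rbind(c(2, 0), c(2, 0)),
               ignore_attr = TRUE)
  # constant field: one zero-lifetime essential bar
  cf <- filtered_complex(rep(4, 10), cbind(1:9, 2:10))
  expect_equal(bars_multiset(superlevel_persistence(cf)),
               rbind(c(4, 4)), ignore_attr = TRUE)
  # single vertex
  one <- filtered_complex(2.5, matrix(integer(0), ncol = 2))
  expect_equal(bars_multiset(superlevel_persistence(one)),
               rbind(c(2.5, 2.5)), ignore_attr = TRUE)
  # drop policy removes the essential bars
  expect_equal(nrow(superlevel_persistence(path3(c(3, 1, 2)), "drop")), 1)
  expect_equal(nrow(superlevel_persistence(cf, "drop")), 0)
})

test_that("sweep and brute-force oracle agree on random graphs", {
  for (trial in 1:120) {
    g <- random_connected_graph(
      n = sample(2:40, 1),
      extra = sample(0:20, 1),
      tie_values = if (trial %% 2) NULL else 0:4,
      seed = trial)
    for (policy in c("kill_at_min", "drop")) {
      fc <- filtered_complex(g$z, g$edges)
      expect_equal(bars_multiset(superlevel_persistence(fc, policy)),
                   bars_multiset(brute_force_persistence(fc, policy)),
                   ignore_attr = TRUE,
                   info = paste("trial", trial, policy))
    }
  }
})

test_that("bar count equals the number of upper local maxima (generic z)", {
  for (seed in 1:10) {
    g <- random_connected_graph(30, 15, seed = seed)  # distinct z a.s.
    fc <- filtered_complex(g$z, g$edges)
    adj <- lapply(seq_along(g$z), function(v) {
      unique(c(g$edges[g$edges[, 1] == v, 2], g$edges[g$edges[, 2] == v, 1]))
    })
    n_max <- sum(vapply(seq_along(g$z), function(v) {
      all(g$z[v] > g$z[adj[[v]]])
    }, logical(1)))
    expect_equal(nrow(superlevel_persistence(fc)), n_max, info = seed)
  }
})

test_that("barcodes shift and scale with the field", {
  g <- random_connected_graph(25, 10, seed = 99)
  fc <- filtered_complex(g$z, g$edges)
  base <- bars_multiset(superlevel_persistence(fc))
  shifted <- bars_multiset(superlevel_persistence(
    filtered_complex(g$z + 3.25, g$edges)))
  expect_equal(shifted, base + 3.25, ignore_attr = TRUE)
  scaled <- bars_multiset(superlevel_persistence(
    filtered_complex(2.5 * g$z, g$edges)))
  expect_equal(scaled, 2.5 * base, ignore_attr = TRUE)
})

test_that("disconnected graphs: every piece gets an essential bar killed at
           the global minimum", {
  z <- c(5, 1, 4, 2)                     # comp A: wells 1-2, comp B: 3-4
  fc <- filtered_complex(z, rbind(c(1, 2), c(3, 4)))
  bc <- superlevel_persistence(fc)
  expect_equal(bars_multiset(bc), rbind(c(4, 1), c(5, 1)),
               ignore_attr = TRUE)
  expect_equal(bars_multiset(brute_force_persistence(fc)), bars_multiset(bc),
               ignore_attr = TRUE)
  expect_equal(nrow(superlevel_persistence(fc, "drop")), 0)
})
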