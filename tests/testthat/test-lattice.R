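test_that("neighbor_distances matches hand-checkable shells", {
  expect_equal(neighbor_distances("hexagonal", 1, 7), c(0, rep(1, 6)))
  d13 <- neighbor_distances("hexagonal", 1, 13)
  expect_equal(d13[8:13], rep(sqrt(3), 6))
  expect_equal(neighbor_distances("square", 2, 9),
               c(0, rep(2, 4), rep(2 * sqrt(2), 4)))
  expect_error(neighbor_distances("triangular", 1, 5))
})

test_that("neighbor_distances agrees with brute-force enumeration to 200", {
  for (lt in c("hexagonal", "square")) {
    for (s in c(1, 2.5)) {
      expect_equal(neighbor_distances(lt, s, 200),
                   enumerate_shell_distances(lt, s, 200),
                   tolerance = 1e-12, info = paste(lt, s))
    }
  }
  # linear scaling in spacing
  expect_equal(neighbor_distances("hexagonal", 7, 50),
               7 * neighbor_distances("hexagonal", 1, 50))
})

test_that("exact square grid aligns with unit spacing and 4-adjacency", {
  lat <- align_to_lattice(as.matrix(expand.grid(x = 0:4, y = 0:4)))
  expect_s3_class(lat, "well_lattice")
  expect_equal(lat$lattice_type, "square")
  expect_equal(lat$spacing, 1, tolerance = 1e-9)
  deg <- lengths(lat$adjacency)
  expect_equal(max(deg), 4)
  expect_equal(sum(deg == 4), 9)  # 3x3 interior
  expect_true(all(vapply(seq_along(lat$adjacency), function(i) {
    all(vapply(lat$adjacency[[i]], function(j) i %in% lat$adjacency[[j]],
               logical(1)))
  }, logical(1))))
})

test_that("jittered hex lattice aligns to generator ground truth", {
  s <- hex_fixture(20, 20, list(u = pattern_uniform(5)), jitter_sd = 1,
                   seed = 3)
  lat <- align_to_lattice(s$lattice$coords)
  expect_equal(lat$lattice_type, "hexagonal")
  expect_lt(abs(lat$spacing - 100) / 100, 0.01)
  deg <- lengths(lat$adjacency)
  expect_equal(max(deg), 6)
  expect_equal(sum(deg == 6), 18 * 18)  # interior wells
  # idempotency: re-aligning the reconstructed ideal coordinates
  lat2 <- align_to_lattice(lat$ideal_coords)
  expect_identical(lat2$axial_index, lat$axial_index)
  # adjacency from axial indices == adjacency by distance threshold on the
  # ideal coordinates
  thr <- 1.25 * lat$spacing
  pw <- as.matrix(dist(lat$ideal_coords))
  for (i in sample(n_wells(lat), 25)) {
    expect_equal(lat$adjacency[[i]],
                 sort(setdiff(which(pw[i, ] <= thr), i)))
  }
})

test_that("degenerate and corrupt inputs are rejected", {
  expect_error(align_to_lattice(cbind(0:2, 0:2)), "collinear")
  expect_error(align_to_lattice(cbind(0:1, c(0, 0))), "at least 3")
  expect_error(align_to_lattice(rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1))),
               "duplicate")
  # two wells snapping to one site
  g <- as.matrix(expand.grid(0:4, 0:4))
  g[1, ] <- g[2, ] + c(0.05, 0.05)
  expect_error(align_to_lattice(g), "same lattice site")
  # gross jitter: too many wells off-lattice, worst offenders named
  set.seed(1)
  bad <- as.matrix(expand.grid(0:9, 0:9)) +
    matrix(runif(200, -0.45, 0.45), ncol = 2)
  expect_error(align_to_lattice(bad, lattice_type = "square",
                                snap_tolerance = 0.1), "snap tolerance")
})

test_that("well_lattice builds Visium-style hex adjacency from axial", {
  ax <- as.matrix(expand.grid(a = 0:3, b = 0:3))
  lat <- well_lattice(ax, "hexagonal", spacing = 2)
  expect_equal(max(lengths(lat$adjacency)), 6)
  expect_equal(nrow(lat$edges), sum(lengths(lat$adjacency)) / 2)
  expect_error(well_lattice(rbind(ax, ax[1, ]), "hexagonal"),
               "same lattice site")
})
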