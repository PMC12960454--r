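# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own code paths.

# Neighbor-distance oracle: build the lattice row by row (offset-row
# geometry, not the axial-basis formula the package uses), measure from a
# central site, sort.
enumerate_shell_distances <- function(lattice_type, spacing, count) {
  R <- 40L
  rows <- -R:R
  cols <- -R:R
  pts <- if (lattice_type == "hexagonal") {
    do.call(rbind, lapply(rows, function(r) {
      cbind(x = (cols + 0.5 * (abs(r) %% 2)) * spacing,
            y = r * sqrt(3) / 2 * spacing)
    }))
  } else {
    as.matrix(expand.grid(x = cols * spacing, y = rows * spacing))
  }
  d <- sort(sqrt(pts[, 1]^2 + pts[, 2]^2))
  stopifnot(length(d) >= count)
  d[seq_len(count)]
}

# Naive per-well network dtm, straight from the definition: order wells by
# actual distance (equal-distance shells accumulated in ascending weight
# order), accumulate to mass m, average the idealized squared distances.
naive_dtm <- function(lattice, w, m) {
  n <- length(w)
  xy <- lattice$coords
  eps2 <- 1e-6 * lattice$spacing^2
  d_ideal <- neighbor_distances(lattice$lattice_type, lattice$spacing, n)
  vapply(seq_len(n), function(p) {
    d2 <- (xy[, 1] - xy[p, 1])^2 + (xy[, 2] - xy[p, 2])^2
    o <- order(d2, seq_len(n))
    shell <- cumsum(c(TRUE, diff(d2[o]) > eps2))
    ws <- unlist(lapply(split(w[o], shell), sort), use.names = FALSE)
    k <- which(cumsum(ws) >= m - 1e-12)[1]
    if (is.na(k)) k <- n
    mean(d_ideal[seq_len(k)]^2)
  }, numeric(1))
}

# Random connected graph: random spanning tree plus extra random edges.
random_connected_graph <- function(n, extra = n %/% 2, tie_values = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  edges <- if (n > 1) {
    cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L), 0L))
  } else {
    matrix(integer(0), ncol = 2)
  }
  if (extra > 0 && n > 2) {
    more <- t(replicate(extra, sample.int(n, 2L)))
    edges <- unique(rbind(edges, more))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  }
  z <- if (is.null(tie_values)) {
    stats::rnorm(n)
  } else {
    sample(tie_values, n, replace = TRUE)  # ties on purpose
  }
  list(z = z, edges = edges)
}

# Canonical form of a barcode for multiset comparison.
bars_multiset <- function(bc, digits = 9) {
  b <- round(unclass(bc), digits)
  b[order(b[, 1], b[, 2]), , drop = FALSE]
}

# Brute-force maximum-curvature rank on the normalized discrete curve
# (central second differences) — the knee oracle.
max_curvature_rank <- function(scores) {
  n <- length(scores)
  y <- (scores - min(scores)) / (max(scores) - min(scores))
  x <- (seq_len(n) - 1) / (n - 1)
  h <- x[2] - x[1]
  i <- 2:(n - 1)
  d1 <- (y[i + 1] - y[i - 1]) / (2 * h)
  d2 <- (y[i + 1] - 2 * y[i] + y[i - 1]) / h^2
  kappa <- abs(d2) / (1 + d1^2)^1.5
  i[which.max(kappa)]
}

# Small hex/square samples used throughout.
hex_fixture <- function(n_rows = 16, n_cols = 16, features, noise = "none",
                        seed = 1, spacing = 100, mask = NULL,
                        jitter_sd = 0) {
  simulate_sample(synthetic_spec(
    lattice_type = "hexagonal", n_rows = n_rows, n_cols = n_cols,
    spacing = spacing, features = features, noise = noise, mask = mask,
    jitter_sd = jitter_sd, seed = seed))
}
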