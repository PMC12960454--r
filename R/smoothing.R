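#' Normalize a feature's counts to unit-mass weights
#'
#' The distance-to-measure smoother consumes masses comparable with the mass
#' fraction `m`, so each feature's nonnegative counts are rescaled to sum to
#' one before smoothing.
#'
#' @param raw nonnegative, finite values, one per well, at least one > 0.
#' @param feature_id identifier used in error messages.
#' @return numeric vector summing to 1.
#' @export
normalize_weights <- function(raw, feature_id = "feature") {
  if (!is.numeric(raw) || anyNA(raw) || any(!is.finite(raw))) {
    stop("non-finite weights for ", feature_id)
  }
  if (any(raw < 0)) stop("negative weights for ", feature_id)
  s <- sum(raw)
  if (s <= 0) stop("all-zero weights for ", feature_id)
  raw / s
}

#' Precompute per-well distance orderings and idealized squared distances
#'
#' The actual-distance ordering of wells around each well and the cumulative
#' sums of squared idealized network distances are shared across all features
#' of a sample; computing them once makes per-feature smoothing cheap.
#' Ordering uses the raw coordinates. Equal-distance ties (whole shells, on
#' an exact lattice) are tracked as groups: the mass threshold is only
#' tested at group boundaries, so smoothing does not depend on well labels
#' or on the coordinate frame.
#'
#' @param lattice a `well_lattice`.
#' @return list with the n x n ordering matrix, the tie-group-end indicator
#'   matrix, and the cumulative idealized d_i^2 vector.
#' @export
dtm_context <- function(lattice) {
  stopifnot(is.well_lattice(lattice))
  n <- n_wells(lattice)
  og <- cpp_distance_order(lattice$coords[, 1L], lattice$coords[, 2L],
                           1e-6 * lattice$spacing^2)
  d <- neighbor_distances(lattice$lattice_type, lattice$spacing, n)
  list(order = og$order, group_end = og$group_end, cumd2 = cumsum(d^2))
}

#' Weighted distance-to-measure with idealized network distances
#'
#' For each well p, wells are ordered by actual Euclidean distance to p
#' (p itself first) and their weights accumulated until the running sum first
#' reaches the mass fraction `m`, giving k; the smoothed value is the mean of
#' the first k squared idealized lattice distances. Because the idealized
#' distances stand in for the raw ones, wells at tissue edges or next to
#' holes are smoothed as if they sat in the bulk of the grid. Wells at equal
#' distance from p (whole shells, on an exact lattice) are accumulated as a
#' group, so the value is independent of well labels and coordinate frame.
#'
#' @param lattice a `well_lattice`.
#' @param weights unit-mass weight vector (one feature) or a features x wells
#'   matrix of unit-mass rows; see [normalize_weights()].
#' @param m mass fraction in (0, 1). Default 0.1; a useful heuristic is the
#'   fraction of the tissue the smallest spatial feature of interest should
#'   occupy (0.01 suits high-resolution mass spectrometry imaging).
#' @param context optional precomputed [dtm_context()].
#' @param distances `"network"` (default: idealized lattice distances, the
#'   edge-robust estimator) or `"euclidean"` (raw distances, the unmodified
#'   point-cloud estimator; kept for comparison — it inflates values at
#'   tissue edges and holes, which is precisely what the network variant
#'   fixes).
#' @return a `scalar_field` (stage `"dtm"`) for a vector input, or a
#'   features x wells matrix of dtm values for a matrix input.
#' @export
weighted_dtm <- function(lattice, weights, m = 0.1, context = NULL,
                         distances = c("network", "euclidean")) {
  distances <- match.arg(distances)
  stopifnot(is.well_lattice(lattice))
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0 || m >= 1) {
    stop("m must be a single number in (0, 1), got ", format(m))
  }
  if (is.null(context)) context <- dtm_context(lattice)
  n <- n_wells(lattice)
  single <- is.null(dim(weights))
  W <- if (single) matrix(weights, nrow = 1L) else as.matrix(weights)
  if (ncol(W) != n) stop("weights length does not match well count")
  tot <- rowSums(W)
  if (any(abs(tot - 1) > 1e-9)) {
    stop("weights must be normalized to total mass 1 (see normalize_weights)")
  }
  vals <- if (distances == "network") {
    cpp_dtm_matrix(context$order, context$group_end, W, context$cumd2, m)
  } else {
    .euclid_dtm(lattice, W, context, m)
  }
  if (single) scalar_field(as.numeric(vals), "dtm") else vals
}

# unmodified weighted distance-to-measure on raw coordinates (reference /
# contrast implementation; quadratic, R-level); same ascending-within-tie
# accumulation rule as the network kernel
.euclid_dtm <- function(lattice, W, context, m) {
  n <- ncol(W)
  xy <- lattice$coords
  out <- matrix(0, nrow(W), n)
  for (p in seq_len(n)) {
    o <- context$order[p, ]
    d2 <- (xy[o, 1L] - xy[p, 1L])^2 + (xy[o, 2L] - xy[p, 2L])^2
    cum <- cumsum(d2)
    gid <- cumsum(c(TRUE, context$group_end[p, -n]))  # tie-group ids
    for (f in seq_len(nrow(W))) {
      w <- W[f, o]
      w <- unlist(lapply(split(w, gid), sort), use.names = FALSE)
      k <- which(cumsum(w) >= m - 1e-12)[1L]
      if (is.na(k)) k <- n
      out[f, p] <- cum[k] / k
    }
  }
  out
}

#' Scalar field over wells
#'
#' Light container for per-well values: stage `"dtm"` for raw smoothed
#' values, `"inverted"` for the expression landscape (see [invert_field()]).
#'
#' @param values numeric vector, one value per well.
#' @param stage `"dtm"` or `"inverted"`.
#' @export
scalar_field <- function(values, stage = c("dtm", "inverted")) {
  stage <- match.arg(stage)
  stopifnot(is.numeric(values), all(is.finite(values)), all(values >= 0))
  structure(list(values = as.numeric(values), stage = stage),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar_field (%s): %d wells, range [%.4g, %.4g]\n",
              x$stage, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Invert a smoothed field into the expression landscape
#'
#' The distance-to-measure is low where expression is high; inversion
#' `z_i = max_j dtm_j - dtm_i` flips the surface so the landscape is high
#' over expression hotspots, with minimum exactly 0.
#'
#' @param field a `scalar_field` with stage `"dtm"`.
#' @return a `scalar_field` with stage `"inverted"`.
#' @export
invert_field <- function(field) {
  if (!inherits(field, "scalar_field") || field$stage != "dtm") {
    stop("invert_field expects a scalar_field at stage 'dtm'")
  }
  scalar_field(max(field$values) - field$values, "inverted")
}
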