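#' Sample container: lattice plus feature matrix
#'
#' @param lattice a `well_lattice`.
#' @param matrix features x wells nonnegative matrix, rownames = feature ids.
#' @param normalization `"raw"` or `"cpm"`.
#' @export
sample_data <- function(lattice, matrix, normalization = c("raw", "cpm")) {
  normalization <- match.arg(normalization)
  matrix <- as.matrix(matrix)
  stopifnot(is.well_lattice(lattice), ncol(matrix) == n_wells(lattice),
            all(is.finite(matrix)), all(matrix >= 0))
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- paste0("feature_", seq_len(nrow(matrix)))
  }
  if (anyDuplicated(rownames(matrix))) stop("duplicate feature ids")
  structure(list(lattice = lattice, matrix = matrix,
                 feature_ids = rownames(matrix),
                 normalization = normalization),
            class = "sample_data")
}

#' @export
print.sample_data <- function(x, ...) {
  cat(sprintf("sample_data: %d features x %d wells (%s, %s counts)\n",
              nrow(x$matrix), ncol(x$matrix), x$lattice$lattice_type,
              x$normalization))
  invisible(x)
}

# ---- pattern constructors -------------------------------------------------
# Geometry is expressed in relative coordinates of the lattice bounding box
# (centers in [0,1]^2, widths as fractions of the box diagonal), so the same
# pattern spec works across lattice sizes and spacings.

#' Spatial expression patterns for the synthetic generator
#'
#' Constructors for the ground-truth pattern classes the score is meant to
#' detect or ignore: `pattern_hotspot` (one or more Gaussian bumps, the
#' "multiple distinct regions of high expression" case), `pattern_ring` (an
#' annulus of high expression), `pattern_gradient` (a linear ramp, a shape
#' with structure but no sharp boundary), `pattern_void` (uniform expression
#' with a depleted disc: voids also count as structure), `pattern_uniform`
#' (flat null), `pattern_single_well_spike` (all mass in one well, the
#' canonical artifact shape), and `pattern_low_depth` (expression detected
#' in only `k` random wells).
#'
#' @param centers matrix/vector of relative (x, y) centers in `[0, 1]^2`.
#' @param amplitude peak added intensity (counts scale).
#' @param width relative width (fraction of the bounding-box diagonal).
#' @param baseline uniform background intensity.
#' @name patterns
NULL

#' @rdname patterns
#' @export
pattern_hotspot <- function(centers = c(0.5, 0.5), amplitude = 50,
                            width = 0.08, baseline = 1) {
  centers <- matrix(unlist(centers), ncol = 2L, byrow = !is.matrix(centers))
  list(class = "hotspot", centers = centers, amplitude = amplitude,
       width = width, baseline = baseline)
}

#' @rdname patterns
#' @param radius relative ring radius.
#' @export
pattern_ring <- function(centers = c(0.5, 0.5), radius = 0.25,
                         width = 0.05, amplitude = 50, baseline = 1) {
  list(class = "ring", centers = matrix(centers, ncol = 2L),
       radius = radius, width = width, amplitude = amplitude,
       baseline = baseline)
}

#' @rdname patterns
#' @param direction relative (dx, dy) of the ramp.
#' @export
pattern_gradient <- function(direction = c(1, 0), amplitude = 50,
                             baseline = 1) {
  list(class = "gradient", direction = direction, amplitude = amplitude,
       baseline = baseline)
}

#' @rdname patterns
#' @export
pattern_void <- function(centers = c(0.5, 0.5), radius = 0.15,
                         amplitude = 50, baseline = NULL) {
  list(class = "void", centers = matrix(centers, ncol = 2L),
       radius = radius, amplitude = amplitude)
}

#' @rdname patterns
#' @export
pattern_uniform <- function(amplitude = 20) {
  list(class = "uniform", amplitude = amplitude)
}

#' @rdname patterns
#' @export
pattern_single_well_spike <- function(amplitude = 200) {
  list(class = "single_well_spike", amplitude = amplitude)
}

#' @rdname patterns
#' @param k number of wells with detected expression.
#' @export
pattern_low_depth <- function(k = 2, amplitude = 10) {
  list(class = "low_depth", k = k, amplitude = amplitude)
}

# deterministic intensity surface of a pattern over the wells (no noise)
.pattern_intensity <- function(pat, coords) {
  lo <- apply(coords, 2L, min)
  hi <- apply(coords, 2L, max)
  span <- pmax(hi - lo, .Machine$double.eps)
  rel <- sweep(sweep(coords, 2L, lo), 2L, span, "/")
  diag_len <- 1  # relative units
  switch(pat$class,
    hotspot = {
      v <- rep(pat$baseline, nrow(rel))
      for (k in seq_len(nrow(pat$centers))) {
        d2 <- (rel[, 1L] - pat$centers[k, 1L])^2 +
          (rel[, 2L] - pat$centers[k, 2L])^2
        v <- v + pat$amplitude * exp(-d2 / (2 * (pat$width * diag_len)^2))
      }
      v
    },
    ring = {
      d <- sqrt((rel[, 1L] - pat$centers[1L, 1L])^2 +
                  (rel[, 2L] - pat$centers[1L, 2L])^2)
      pat$baseline + pat$amplitude *
        exp(-(d - pat$radius)^2 / (2 * (pat$width * diag_len)^2))
    },
    gradient = {
      dir <- pat$direction / sqrt(sum(pat$direction^2))
      proj <- rel[, 1L] * dir[1L] + rel[, 2L] * dir[2L]
      pat$baseline + pat$amplitude *
        (proj - min(proj)) / max(max(proj) - min(proj),
                                 .Machine$double.eps)
    },
    void = {
      d <- sqrt((rel[, 1L] - pat$centers[1L, 1L])^2 +
                  (rel[, 2L] - pat$centers[1L, 2L])^2)
      ifelse(d < pat$radius, 0.02 * pat$amplitude, pat$amplitude)
    },
    uniform = rep(pat$amplitude, nrow(rel)),
    stop("unknown pattern class: ", pat$class)
  )
}

#' Specification of a synthetic spatial omics sample
#'
#' @param lattice_type `"hexagonal"` (default) or `"square"`.
#' @param n_rows,n_cols grid dimensions before masking.
#' @param spacing center-to-center distance (default 100, a Visium-like
#'   length scale in micrometers).
#' @param features named list of pattern specs (see [patterns]).
#' @param noise `"nb"` (negative binomial, dispersion 0.5 by default --
#'   overdispersed counts typical of spatial transcriptomics), `"poisson"`,
#'   or `"none"` (deterministic intensities).
#' @param dispersion negative binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param jitter_sd Gaussian jitter added to the ideal coordinates
#'   (default 0).
#' @param mask optional `function(x, y)` on relative `[0,1]^2` coordinates
#'   returning `TRUE` for wells to keep (irregular boundaries, holes,
#'   disconnected pieces).
#' @param seed RNG seed; identical spec + seed reproduce the sample exactly.
#' @export
synthetic_spec <- function(lattice_type = c("hexagonal", "square"),
                           n_rows = 32, n_cols = 32, spacing = 100,
                           features = list(uniform = pattern_uniform()),
                           noise = c("nb", "poisson", "none"),
                           dispersion = 0.5, jitter_sd = 0, mask = NULL,
                           seed = 1L) {
  structure(list(lattice_type = match.arg(lattice_type),
                 n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 features = features, noise = match.arg(noise),
                 dispersion = dispersion, jitter_sd = jitter_sd,
                 mask = mask, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic sample with ground truth
#'
#' Builds the ideal lattice, applies the mask, evaluates every pattern's
#' intensity surface, and draws counts from the noise model. The returned
#' `sample_data` carries a `ground_truth` attribute: a data frame with each
#' feature's pattern class and parameters.
#'
#' @param spec a [synthetic_spec()].
#' @return `sample_data` with attribute `ground_truth`.
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  rows <- seq_len(spec$n_rows) - 1L
  cols <- seq_len(spec$n_cols) - 1L
  grid <- expand.grid(c = cols, r = rows)
  axial <- if (spec$lattice_type == "hexagonal") {
    cbind(a = grid$c - grid$r %/% 2L, b = grid$r)
  } else {
    cbind(a = grid$c, b = grid$r)
  }
  basis <- .lattice_basis(spec$lattice_type, spec$spacing)
  ideal <- axial %*% t(basis)
  keep <- rep(TRUE, nrow(ideal))
  if (!is.null(spec$mask)) {
    lo <- apply(ideal, 2L, min)
    span <- pmax(apply(ideal, 2L, max) - lo, .Machine$double.eps)
    rel <- sweep(sweep(ideal, 2L, lo), 2L, span, "/")
    keep <- as.logical(spec$mask(rel[, 1L], rel[, 2L]))
    if (!any(keep)) stop("mask removed all wells")
  }
  axial <- axial[keep, , drop = FALSE]
  coords <- ideal[keep, , drop = FALSE]
  if (spec$jitter_sd > 0) {
    coords <- coords + matrix(stats::rnorm(length(coords), 0, spec$jitter_sd),
                              ncol = 2L)
  }
  lat <- well_lattice(axial, spec$lattice_type, spec$spacing, coords = coords)
  n <- n_wells(lat)
  ids <- names(spec$features)
  if (is.null(ids)) ids <- paste0("feature_", seq_along(spec$features))
  M <- matrix(0, length(spec$features), n, dimnames = list(ids, NULL))
  gt <- data.frame(feature_id = ids,
                   pattern_class = vapply(spec$features, `[[`, "", "class"),
                   parameters = vapply(spec$features, function(p) {
                     paste(names(p)[-1L],
                           vapply(p[-1L], function(v) {
                             paste(format(unlist(v)), collapse = ",")
                           }, ""),
                           sep = "=", collapse = ";")
                   }, ""),
                   stringsAsFactors = FALSE)
  for (k in seq_along(spec$features)) {
    pat <- spec$features[[k]]
    mu <- if (pat$class == "single_well_spike") {
      v <- numeric(n)
      v[sample.int(n, 1L)] <- pat$amplitude
      v
    } else if (pat$class == "low_depth") {
      v <- numeric(n)
      v[sample.int(n, pat$k)] <- pat$amplitude
      v
    } else {
      .pattern_intensity(pat, lat$ideal_coords)
    }
    M[k, ] <- switch(spec$noise,
      none = mu,
      poisson = stats::rpois(n, mu),
      nb = ifelse(mu > 0,
                  stats::rnbinom(n, mu = mu, size = 1 / spec$dispersion), 0))
  }
  out <- sample_data(lat, M, "raw")
  attr(out, "ground_truth") <- gt
  out
}

#' Spatially permute one feature
#'
#' Null model preserving a feature's value distribution while destroying its
#' spatial arrangement: the feature's values are permuted uniformly over
#' wells.
#'
#' @param sample a `sample_data`.
#' @param feature_id which feature to permute.
#' @param seed RNG seed.
#' @return the `sample_data` with that feature's row permuted.
#' @export
spatial_permutation <- function(sample, feature_id, seed = 1L) {
  stopifnot(inherits(sample, "sample_data"))
  i <- match(feature_id, rownames(sample$matrix))
  if (is.na(i)) stop("unknown feature: ", feature_id)
  set.seed(seed)
  sample$matrix[i, ] <- sample$matrix[i, sample.int(ncol(sample$matrix))]
  sample
}
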