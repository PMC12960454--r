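#' Idealized neighbor distance sequence of an infinite lattice
#'
#' Distances from a site of the infinite ideal lattice to its `count` nearest
#' sites, the site itself included first, so `d[1] = 0`. These idealized
#' network distances replace raw well-to-well distances inside the
#' distance-to-measure smoother: every well is treated as if it sat in the
#' bulk of a regular grid, which is what makes the smoother robust to tissue
#' edges and holes. Only the multiset matters downstream (squared distances
#' are summed), so ties within a shell are in arbitrary order.
#'
#' @param lattice_type `"hexagonal"` or `"square"`.
#' @param spacing center-to-center distance between adjacent wells (> 0).
#' @param count number of sites wanted (>= 1).
#' @return nondecreasing numeric vector of length `count`, starting at 0.
#' @examples
#' neighbor_distances("hexagonal", 1, 7)   # 0 then the 6-site first shell
#' neighbor_distances("square", 2, 9)      # shells at 2 and 2 * sqrt(2)
#' @export
neighbor_distances <- function(lattice_type, spacing, count) {
  lattice_type <- match.arg(lattice_type, c("hexagonal", "square"))
  stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0,
            count >= 1)
  count <- as.integer(count)
  R <- max(4L, ceiling(sqrt(count)) + 2L)
  repeat {
    ab <- expand.grid(a = -R:R, b = -R:R)
    d <- if (lattice_type == "hexagonal") {
      sqrt(ab$a^2 + ab$a * ab$b + ab$b^2)
    } else {
      sqrt(ab$a^2 + ab$b^2)
    }
    d <- sort(d)
    # every site within this radius is guaranteed inside the window
    covered <- if (lattice_type == "hexagonal") sqrt(3) * R / 2 else R
    if (length(d) >= count && d[count] <= covered) {
      return(d[seq_len(count)] * spacing)
    }
    R <- R * 2L
  }
}

# axial neighbor offsets; square adjacency is 4-connected by design
.lattice_offsets <- function(lattice_type) {
  if (lattice_type == "hexagonal") {
    cbind(a = c(1L, 0L, -1L, -1L, 0L, 1L), b = c(0L, 1L, 1L, 0L, -1L, -1L))
  } else {
    cbind(a = c(1L, -1L, 0L, 0L), b = c(0L, 0L, 1L, -1L))
  }
}

.lattice_basis <- function(lattice_type, spacing, theta = 0) {
  ang2 <- theta + if (lattice_type == "hexagonal") pi / 3 else pi / 2
  spacing * cbind(u = c(cos(theta), sin(theta)), v = c(cos(ang2), sin(ang2)))
}

# adjacency lists + unique edge pairs from integer axial coordinates
.axial_adjacency <- function(axial, lattice_type) {
  key <- paste(axial[, 1L], axial[, 2L])
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("wells snapped to the same lattice site (corrupt input?): wells ",
         paste(utils::head(dup, 8L), collapse = ", "))
  }
  off <- .lattice_offsets(lattice_type)
  n <- nrow(axial)
  nb <- matrix(NA_integer_, n, nrow(off))
  for (k in seq_len(nrow(off))) {
    nb[, k] <- match(paste(axial[, 1L] + off[k, 1L], axial[, 2L] + off[k, 2L]),
                     key)
  }
  adjacency <- lapply(seq_len(n), function(i) {
    v <- nb[i, ]
    sort(v[!is.na(v)])
  })
  ii <- rep(seq_len(n), each = nrow(off))
  jj <- as.integer(t(nb))
  keep <- !is.na(jj) & ii < jj
  list(adjacency = adjacency,
       edges = cbind(i = ii[keep], j = jj[keep]))
}

#' Construct a well lattice from known integer lattice coordinates
#'
#' Used when lattice indices are trusted as given (Visium array coordinates,
#' synthetic data). For raw, possibly jittered coordinates use
#' [align_to_lattice()].
#'
#' @param axial integer matrix (n x 2) of lattice coordinates: multiples of
#'   the two basis vectors (hexagonal basis at 0 and 60 degrees, square basis
#'   at 0 and 90 degrees).
#' @param lattice_type `"hexagonal"` or `"square"`.
#' @param spacing center-to-center distance (> 0), default 1.
#' @param well_ids optional identifiers, default `well_1 ... well_n`.
#' @param coords optional raw coordinates to carry along (default: the ideal
#'   positions reconstructed from `axial`).
#' @return a `well_lattice` object.
#' @export
well_lattice <- function(axial, lattice_type = c("hexagonal", "square"),
                         spacing = 1, well_ids = NULL, coords = NULL) {
  lattice_type <- match.arg(lattice_type)
  axial <- as.matrix(axial)
  storage.mode(axial) <- "integer"
  stopifnot(ncol(axial) == 2L, nrow(axial) >= 1L, spacing > 0)
  n <- nrow(axial)
  basis <- .lattice_basis(lattice_type, spacing)
  ideal <- axial %*% t(basis)
  if (is.null(coords)) coords <- ideal
  coords <- as.matrix(coords)
  if (is.null(well_ids)) well_ids <- paste0("well_", seq_len(n))
  adj <- .axial_adjacency(axial, lattice_type)
  structure(
    list(well_ids = as.character(well_ids), coords = coords,
         lattice_type = lattice_type, spacing = spacing,
         axial_index = axial, adjacency = adj$adjacency, edges = adj$edges,
         ideal_coords = ideal, basis = basis, origin = c(0, 0)),
    class = "well_lattice")
}

#' @export
print.well_lattice <- function(x, ...) {
  cat(sprintf("well_lattice: %d wells on a %s grid, spacing %.4g\n",
              length(x$well_ids), x$lattice_type, x$spacing))
  cat(sprintf("  edges: %d; mean degree %.2f\n", nrow(x$edges),
              mean(lengths(x$adjacency))))
  invisible(x)
}

#' Align raw well coordinates to an ideal hexagonal or square lattice
#'
#' Estimates the grid spacing from nearest-neighbour distances, infers the
#' lattice type from the angular symmetry of nearest-neighbour bearings
#' (6-fold vs 4-fold), fits the lattice basis by iterated least squares, and
#' snaps every well to an integer lattice site. Wells failing the snap
#' tolerance beyond a small allowed fraction abort the alignment with the
#' worst offenders named; two wells snapping to the same site are an error,
#' never merged. Disconnected tissue pieces are kept in one lattice.
#'
#' @param coords numeric matrix (n x 2) of raw well positions, n >= 3,
#'   pairwise distinct and not all collinear.
#' @param lattice_type `"hexagonal"`, `"square"`, or `NULL` to infer.
#' @param snap_tolerance maximal allowed distance between a well and its
#'   snapped ideal position, as a fraction of the spacing (default 0.25).
#' @param max_fail_frac maximal fraction of wells allowed to violate
#'   `snap_tolerance` before alignment errors out (default 0.05).
#' @param well_ids optional well identifiers.
#' @return a `well_lattice` object whose `axial_index`, `adjacency` and
#'   `spacing` describe the snapped ideal grid; `coords` keeps the raw input.
#' @examples
#' g <- expand.grid(x = 0:4, y = 0:4)
#' lat <- align_to_lattice(as.matrix(g))
#' lat$lattice_type  # "square"
#' @export
align_to_lattice <- function(coords, lattice_type = NULL,
                             snap_tolerance = 0.25, max_fail_frac = 0.05,
                             well_ids = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L || anyNA(coords)) {
    stop("coords must be a numeric n x 2 matrix without missing values")
  }
  n <- nrow(coords)
  if (n < 3L) stop("alignment needs at least 3 wells, got ", n)
  sv <- svd(scale(coords, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate geometry: wells are collinear")
  }
  nn <- cpp_nn(coords[, 1L], coords[, 2L])
  if (any(nn$dist == 0)) {
    stop("duplicate well coordinates at wells ",
         paste(utils::head(which(nn$dist == 0), 8L), collapse = ", "))
  }
  spacing0 <- stats::median(nn$dist)
  pairs <- cpp_pairs_within(coords[, 1L], coords[, 2L], 1.3 * spacing0)
  if (nrow(pairs) == 0L) stop("no neighbouring wells within 1.3 x spacing")
  theta <- atan2(pairs[, "dy"], pairs[, "dx"])
  sym <- vapply(c(square = 4, hexagonal = 6),
                function(f) Mod(mean(exp(1i * f * theta))), numeric(1))
  if (is.null(lattice_type)) {
    lattice_type <- names(sym)[which.max(sym)]
  } else {
    lattice_type <- match.arg(lattice_type, c("hexagonal", "square"))
  }
  f <- if (lattice_type == "hexagonal") 6 else 4
  theta0 <- Arg(mean(exp(1i * f * theta))) / f
  basis <- .lattice_basis(lattice_type, spacing0, theta0)
  origin_well <- which.min(colSums((t(coords) - colMeans(coords))^2))
  x0 <- coords[origin_well, ]
  axial <- NULL
  for (iter in 1:10) {
    new_axial <- round(t(solve(basis, t(coords) - x0)))
    if (!is.null(axial) && all(new_axial == axial)) break
    axial <- new_axial
    # refit basis + origin by least squares on the current assignment
    X <- cbind(1, axial)
    fit <- qr.solve(X, coords)            # 3 x 2: origin row, then basis rows
    x0 <- fit[1L, ]
    basis <- t(fit[2:3, , drop = FALSE])
  }
  storage.mode(axial) <- "integer"
  spacing <- mean(sqrt(colSums(basis^2)))
  ideal <- sweep(axial %*% t(basis), 2L, x0, "+")
  resid <- sqrt(rowSums((coords - ideal)^2))
  bad <- which(resid > snap_tolerance * spacing)
  if (length(bad) > max_fail_frac * n) {
    worst <- bad[order(resid[bad], decreasing = TRUE)]
    stop(sprintf(
      "%d/%d wells exceed the snap tolerance (%.3g x spacing); worst: %s",
      length(bad), n, snap_tolerance,
      paste(utils::head(worst, 8L), collapse = ", ")))
  }
  adj <- .axial_adjacency(axial, lattice_type)
  if (is.null(well_ids)) {
    well_ids <- rownames(coords)
    if (is.null(well_ids)) well_ids <- paste0("well_", seq_len(n))
  }
  structure(
    list(well_ids = as.character(well_ids), coords = coords,
         lattice_type = lattice_type, spacing = spacing,
         axial_index = axial, adjacency = adj$adjacency, edges = adj$edges,
         ideal_coords = ideal, basis = basis, origin = x0),
    class = "well_lattice")
}

#' @rdname well_lattice
#' @param x object to test.
#' @export
is.well_lattice <- function(x) inherits(x, "well_lattice")

#' Number of wells in a lattice
#' @param lattice a `well_lattice`.
#' @export
n_wells <- function(lattice) {
  stopifnot(is.well_lattice(lattice))
  length(lattice$well_ids)
}
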