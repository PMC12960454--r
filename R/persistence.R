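#' Build the upper-star filtered complex on the well graph
#'
#' Vertices are wells carrying the inverted landscape value `z_i`; edges are
#' the lattice adjacency pairs carrying `min(z_i, z_j)`. As the threshold
#' decreases, the superlevel sets of this complex nest into the upper star
#' filtration whose 0-dimensional persistence the scoring is built on.
#'
#' @param lattice a `well_lattice`.
#' @param field a `scalar_field` with stage `"inverted"`.
#' @return a `filtered_complex`: vertex values, edge index pairs, edge values.
#' @export
build_filtration <- function(lattice, field) {
  stopifnot(is.well_lattice(lattice))
  if (!inherits(field, "scalar_field") || field$stage != "inverted") {
    stop("build_filtration expects a scalar_field at stage 'inverted'")
  }
  z <- field$values
  if (length(z) != n_wells(lattice)) {
    stop("field length does not match well count")
  }
  e <- lattice$edges
  structure(
    list(z = z, edges = e,
         edge_value = pmin(z[e[, 1L]], z[e[, 2L]])),
    class = "filtered_complex")
}

#' Construct a filtered complex from an arbitrary graph
#'
#' Mostly for testing on graphs that are not lattices; same upper-star
#' index rule as [build_filtration()].
#'
#' @param z vertex values.
#' @param edges 2-column integer matrix of vertex index pairs (1-based).
#' @export
filtered_complex <- function(z, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  stopifnot(is.numeric(z), all(is.finite(z)),
            all(edges >= 1L), all(edges <= length(z)),
            all(edges[, 1L] != edges[, 2L]))
  structure(
    list(z = as.numeric(z), edges = edges,
         edge_value = pmin(z[edges[, 1L]], z[edges[, 2L]])),
    class = "filtered_complex")
}

.barcode <- function(bars, essential_policy) {
  bars <- matrix(as.numeric(bars), ncol = 2L,
                 dimnames = list(NULL, c("birth", "death")))
  structure(bars, essential_policy = essential_policy, class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  lt <- lifetimes(x)
  cat(sprintf("barcode: %d bars (%d with positive lifetime), policy %s\n",
              nrow(x), sum(lt > 0), attr(x, "essential_policy")))
  invisible(x)
}

#' Bar lifetimes of a barcode
#'
#' Superlevel convention: a bar is born at a high threshold and dies at a
#' lower one, so lifetime = birth - death >= 0.
#' @param barcode a `barcode`.
#' @export
lifetimes <- function(barcode) {
  stopifnot(inherits(barcode, "barcode"))
  if (nrow(barcode) == 0L) return(numeric(0))
  unname(barcode[, "birth"] - barcode[, "death"])
}

#' 0-dimensional persistence of the upper star filtration
#'
#' Union-find sweep over simplices in decreasing index order (vertices before
#' edges at equal index). A component is born at the value of its highest
#' vertex; when an edge merges two components the one with the lower birth
#' dies at the edge index (elder rule; birth ties broken by the smaller
#' creating-vertex index surviving). Merge pairings at the component's own
#' birth index are instantaneous (no homology class) and yield no bar.
#' Components that never die are handled by `essential_policy`:
#' `"kill_at_min"` assigns them death = global minimum vertex value (0 for
#' inverted fields), so every bar is finite and norms are defined;
#' `"drop"` omits them. With several disconnected tissue pieces each piece
#' contributes an essential class, all killed at the global minimum.
#'
#' @param complex a `filtered_complex`.
#' @param essential_policy `"kill_at_min"` (default) or `"drop"`.
#' @return a `barcode`.
#' @examples
#' fc <- filtered_complex(c(3, 1, 2), rbind(c(1, 2), c(2, 3)))
#' superlevel_persistence(fc)   # bars (3, 1) and (2, 1)
#' @export
superlevel_persistence <- function(complex,
                                   essential_policy = c("kill_at_min",
                                                        "drop")) {
  stopifnot(inherits(complex, "filtered_complex"))
  essential_policy <- match.arg(essential_policy)
  bars <- cpp_persistence(complex$z, complex$edges[, 1L],
                          complex$edges[, 2L],
                          essential_policy == "kill_at_min")
  .barcode(bars, essential_policy)
}

#' Brute-force persistence oracle by threshold sweeping
#'
#' Independent reference implementation: for each distinct vertex value t in
#' decreasing order, connected components of the subgraph induced on
#' `{z >= t}` are computed from scratch and matched against the components of
#' the previous (higher) threshold. A component containing none of the
#' previous components is born at t; when several previous components land in
#' one new component, the oldest survives (ties: smallest creating vertex)
#' and the others die at t. Same bar-multiset contract and
#' `essential_policy` semantics as [superlevel_persistence()]; quadratic,
#' intended for graphs up to about a thousand vertices.
#'
#' @inheritParams superlevel_persistence
#' @return a `barcode`.
#' @export
brute_force_persistence <- function(complex,
                                    essential_policy = c("kill_at_min",
                                                         "drop")) {
  stopifnot(inherits(complex, "filtered_complex"))
  essential_policy <- match.arg(essential_policy)
  z <- complex$z
  n <- length(z)
  if (n == 0L) return(.barcode(matrix(numeric(0), ncol = 2L),
                               essential_policy))
  adj <- vector("list", n)
  if (nrow(complex$edges) > 0L) {
    e <- complex$edges
    for (k in seq_len(nrow(e))) {
      adj[[e[k, 1L]]] <- c(adj[[e[k, 1L]]], e[k, 2L])
      adj[[e[k, 2L]]] <- c(adj[[e[k, 2L]]], e[k, 1L])
    }
  }
  thresholds <- sort(unique(z), decreasing = TRUE)
  # state: per live component a birth value and creator vertex; membership
  comp_of <- rep(NA_integer_, n)     # component id per vertex (if active)
  birth <- numeric(0)
  creator <- integer(0)
  alive <- logical(0)
  bars_b <- numeric(0)
  bars_d <- numeric(0)
  next_id <- 0L
  for (t in thresholds) {
    active <- which(z >= t)
    # components of induced subgraph via BFS
    lab <- rep(NA_integer_, n)
    ncomp <- 0L
    for (s in active) {
      if (!is.na(lab[s])) next
      ncomp <- ncomp + 1L
      queue <- s
      lab[s] <- ncomp
      while (length(queue)) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        for (u in adj[[v]]) {
          if (z[u] >= t && is.na(lab[u])) {
            lab[u] <- ncomp
            queue <- c(queue, u)
          }
        }
      }
    }
    new_comp_of <- rep(NA_integer_, n)
    for (g in seq_len(ncomp)) {
      members <- active[lab[active] == g]
      prev <- unique(comp_of[members])
      prev <- prev[!is.na(prev)]
      if (length(prev) == 0L) {
        next_id <- next_id + 1L
        birth[next_id] <- t
        creator[next_id] <- min(members)
        alive[next_id] <- TRUE
        id <- next_id
      } else {
        # oldest survives; ties by smallest creator vertex
        o <- prev[order(-birth[prev], creator[prev])]
        id <- o[1L]
        for (d in o[-1L]) {
          if (birth[d] > t) {       # instantaneous pairings emit no bar
            bars_b <- c(bars_b, birth[d])
            bars_d <- c(bars_d, t)
          }
          alive[d] <- FALSE
        }
      }
      new_comp_of[members] <- id
    }
    comp_of <- new_comp_of
  }
  if (essential_policy == "kill_at_min") {
    zmin <- min(z)
    for (id in which(alive)) {
      bars_b <- c(bars_b, birth[id])
      bars_d <- c(bars_d, zmin)
    }
  }
  .barcode(cbind(bars_b, bars_d), essential_policy)
}
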