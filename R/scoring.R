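#' L^p norm of a barcode
#'
#' `(sum lifetime^p)^(1/p)`; `p = Inf` gives the maximal lifetime. The
#' default CoSS uses p = 2 ("sum the squared bar lengths, take the square
#' root"); a higher p biases the score toward features whose structure is
#' carried by fewer, more prominent hotspots. An empty barcode has norm 0.
#'
#' @param barcode a `barcode`.
#' @param p norm order in `[1, Inf]`.
#' @export
barcode_norm <- function(barcode, p = 2) {
  lt <- lifetimes(barcode)
  if (length(lt) == 0L) return(0)
  if (is.infinite(p)) return(max(lt))
  if (!is.numeric(p) || p < 1) {
    stop("p must be in [1, Inf] (the bar count is a separate statistic)")
  }
  sum(lt^p)^(1 / p)
}

#' Ratio of the L-infinity to the L0 norm of a barcode
#'
#' Maximal bar lifetime divided by the number of bars with lifetime above
#' `lifetime_tolerance` (the usual l0 counting reading; `l0 = "l1"` divides
#' by the lifetime sum instead). High values mean one feature dominates the
#' spatial structure, which can indicate a technical artifact such as a
#' single highly expressed well. Returns 0 when no bar exceeds tolerance.
#'
#' @param barcode a `barcode`.
#' @param lifetime_tolerance bars at or below this lifetime are ignored;
#'   default `1e-12 * max(lifetime)` guards float noise.
#' @param l0 `"count"` (default) or `"l1"`.
#' @export
ratio_statistic <- function(barcode, lifetime_tolerance = NULL,
                            l0 = c("count", "l1")) {
  l0 <- match.arg(l0)
  lt <- lifetimes(barcode)
  if (length(lt) == 0L) return(0)
  if (is.null(lifetime_tolerance)) lifetime_tolerance <- 1e-12 * max(lt)
  keep <- lt > lifetime_tolerance
  if (!any(keep)) return(0)
  max(lt) / if (l0 == "count") sum(keep) else sum(lt[keep])
}

#' Score every feature of a sample with the Coefficient of Spatial Structure
#'
#' Full per-feature pipeline: normalize counts to unit mass, smooth with the
#' weighted distance-to-measure on idealized network distances, invert into
#' the expression landscape, take 0-dimensional persistence of the upper
#' star filtration on the well graph, and reduce the barcode to the L^p norm
#' (the CoSS) plus the max-lifetime / bar-count ratio statistic. Features
#' with all-zero counts cannot be normalized; they are reported with `NA`
#' scores and a reason flag rather than silently dropped.
#'
#' @param lattice a `well_lattice`, or a `sample_data` from [read_sample()] /
#'   [simulate_sample()] (in which case `expr` is taken from it).
#' @param expr features x wells nonnegative matrix (dense or sparse); row
#'   names are feature ids.
#' @param m mass fraction for the smoother, in (0, 1); see [weighted_dtm()].
#' @param p norm order, default 2.
#' @param essential_policy see [superlevel_persistence()].
#' @param lifetime_tolerance per-feature tolerance for bar counting; default
#'   `1e-12 * max(z)`.
#' @param l0 reading of the ratio denominator, `"count"` or `"l1"`.
#' @param ratio_flag optional ratio threshold above which a feature is
#'   flagged `"high_ratio"` as a possible artifact; default `NULL` (off, no
#'   universal threshold is assumed).
#' @param context optional precomputed [dtm_context()].
#' @return a `coss_table` data frame: feature_id, coss, ratio, n_bars, flag,
#'   in input feature order, with the scoring parameters as attributes.
#' @examples
#' lat <- well_lattice(as.matrix(expand.grid(0:9, 0:9)), "square")
#' expr <- rbind(uniform = rep(1, 100),
#'               spot    = ifelse(seq_len(100) %in% c(34, 35, 44, 45), 9, 1))
#' coss(lat, expr)
#' @export
coss <- function(lattice, expr = NULL, m = 0.1, p = 2,
                 essential_policy = c("kill_at_min", "drop"),
                 lifetime_tolerance = NULL, l0 = c("count", "l1"),
                 ratio_flag = NULL, context = NULL) {
  essential_policy <- match.arg(essential_policy)
  l0 <- match.arg(l0)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0 || m >= 1) {
    stop("m must be a single number in (0, 1), got ", format(m))
  }
  if (inherits(lattice, "sample_data")) {
    if (is.null(expr)) expr <- lattice$matrix
    lattice <- lattice$lattice
  }
  stopifnot(is.well_lattice(lattice), !is.null(expr))
  expr <- as.matrix(expr)
  n <- n_wells(lattice)
  if (ncol(expr) != n) stop("expression matrix width does not match wells")
  if (any(expr < 0) || any(!is.finite(expr))) {
    bad <- which(apply(expr, 1L, function(r) any(r < 0 | !is.finite(r))))
    stop("negative or non-finite values in features: ",
         paste(utils::head(rownames(expr)[bad], 5L), collapse = ", "))
  }
  ids <- rownames(expr)
  if (is.null(ids)) ids <- paste0("feature_", seq_len(nrow(expr)))
  tot <- rowSums(expr)
  ok <- tot > 0
  if (any(!ok)) {
    message(sum(!ok), " feature(s) with all-zero counts scored as NA: ",
            paste(utils::head(ids[!ok], 5L), collapse = ", "))
  }
  out <- data.frame(feature_id = ids, coss = NA_real_, ratio = NA_real_,
                    n_bars = NA_integer_, flag = ifelse(ok, "", "all_zero"),
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    if (is.null(context)) context <- dtm_context(lattice)
    W <- expr[ok, , drop = FALSE] / tot[ok]
    dtm <- cpp_dtm_matrix(context$order, context$group_end, W,
                          context$cumd2, m)
    e <- lattice$edges
    kill <- essential_policy == "kill_at_min"
    rows <- which(ok)
    for (r in seq_along(rows)) {
      z <- max(dtm[r, ]) - dtm[r, ]
      bars <- cpp_persistence(z, e[, 1L], e[, 2L], kill)
      lt <- bars[, 1L] - bars[, 2L]
      tol <- if (is.null(lifetime_tolerance)) {
        1e-12 * max(z)
      } else {
        lifetime_tolerance
      }
      i <- rows[r]
      out$coss[i] <- if (length(lt)) {
        if (is.infinite(p)) max(lt) else sum(lt^p)^(1 / p)
      } else 0
      keep <- lt > tol
      out$n_bars[i] <- sum(keep)
      out$ratio[i] <- if (any(keep)) {
        max(lt) / if (l0 == "count") sum(keep) else sum(lt[keep])
      } else 0
      if (!is.null(ratio_flag) && out$ratio[i] > ratio_flag) {
        out$flag[i] <- "high_ratio"
      }
    }
  }
  structure(out, class = c("coss_table", "data.frame"),
            m = m, p = p, essential_policy = essential_policy, l0 = l0)
}
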