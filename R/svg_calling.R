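#' Knee of a descending score-rank curve (kneedle)
#'
#' Locates the elbow of the CoSS-rank curve: both axes are min-max
#' normalized, the difference between the chord (from first to last point)
#' and the normalized curve is formed, and the knee is the first local
#' maximum of that difference curve that survives the sensitivity threshold:
#' each local maximum becomes the current candidate, and a candidate is
#' confirmed when the difference curve falls below its value minus
#' `sensitivity / (n - 1)` before another local maximum replaces it. Works
#' on the discrete curve; a centered moving average pre-smooths it. A straight line has a flat
#' difference curve and yields no knee; so do curves shorter than 5 points
#' or constant scores (for instance the qualitatively different score-rank
#' profiles seen on some mass spectrometry imaging samples -- no call is
#' forced there).
#'
#' @param scores numeric scores sorted in nonincreasing order (rank 1 first).
#' @param sensitivity positive; larger is more conservative. Default 1.
#' @param smoothing_window odd integer window for pre-smoothing; 1 = off.
#'   Default `NULL` picks `2 * floor(n / 200) + 1`: off for short curves,
#'   mild for transcriptome-sized ones. The original algorithm smooths with
#'   a spline before knee finding; on raw sampled curves the difference
#'   curve's noise otherwise produces spurious early candidates.
#' @return the knee rank K (integer), or `NA_integer_` when no knee exists.
#' @export
kneedle_cutoff <- function(scores, sensitivity = 1, smoothing_window = NULL) {
  n <- length(scores)
  if (is.null(smoothing_window)) {
    smoothing_window <- max(1L, 2L * (n %/% 200L) + 1L)
  }
  stopifnot(is.numeric(scores), sensitivity > 0,
            smoothing_window >= 1, smoothing_window %% 2 == 1)
  if (n < 5L) return(NA_integer_)
  if (any(diff(scores) > 1e-12 * max(abs(scores), 1))) {
    stop("scores must be sorted in nonincreasing order")
  }
  y <- scores
  if (smoothing_window > 1L) {
    k <- (smoothing_window - 1L) / 2L
    y <- vapply(seq_len(n), function(i) {
      mean(scores[max(1L, i - k):min(n, i + k)])
    }, numeric(1))
  }
  rng <- max(y) - min(y)
  if (rng <= 0) return(NA_integer_)
  yn <- (y - min(y)) / rng
  xn <- (seq_len(n) - 1) / (n - 1)
  d <- (1 - xn) - yn            # sag of the curve below the chord
  eps <- 1e-12
  thr_step <- sensitivity / (n - 1)
  # online sweep (Satopaa et al.): every local maximum of the difference
  # curve becomes the current knee candidate with threshold d - S/(n-1);
  # the candidate is confirmed when the curve falls below the threshold
  # before the next local maximum replaces it
  candidate <- NA_integer_
  threshold <- -Inf
  for (i in 2:n) {
    if (i < n && d[i] > d[i - 1L] + eps && d[i] >= d[i + 1L] - eps &&
        d[i] > eps) {
      candidate <- i
      threshold <- d[i] - thr_step
    } else if (!is.na(candidate) && d[i] < threshold) {
      return(candidate)
    }
  }
  NA_integer_
}

#' Call spatially variable features from CoSS scores
#'
#' Ranks features by descending CoSS (ties by feature id, so calls are
#' deterministic) and declares features with rank at or above the knee of
#' the CoSS-rank curve spatially variable. Either a practitioner-chosen rank
#' or score cutoff can replace the automatic knee. Features with `NA` scores
#' are never called.
#'
#' @param results a `coss_table` from [coss()], or any data frame with
#'   `feature_id` and `coss` columns.
#' @param cutoff_rank optional rank cutoff overriding the knee (features
#'   with rank <= cutoff are called).
#' @param cutoff_score optional score cutoff (features with
#'   `coss >= cutoff_score` are called).
#' @param sensitivity,smoothing_window passed to [kneedle_cutoff()].
#' @return the table with `rank` and `sv` columns added, sorted by rank;
#'   attribute `cutoff_rank` records the K used (NA when no knee).
#' @export
call_svgs <- function(results, cutoff_rank = NULL, cutoff_score = NULL,
                      sensitivity = 1, smoothing_window = NULL) {
  stopifnot(is.data.frame(results),
            all(c("feature_id", "coss") %in% names(results)))
  if (!is.null(cutoff_rank) && !is.null(cutoff_score)) {
    stop("give at most one of cutoff_rank, cutoff_score")
  }
  scored <- !is.na(results$coss)
  ord <- order(!scored, -replace(results$coss, !scored, -Inf),
               results$feature_id)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- NA_integer_
  out$rank[seq_len(sum(scored))] <- seq_len(sum(scored))
  out$sv <- FALSE
  if (!is.null(cutoff_score)) {
    out$sv <- !is.na(out$coss) & out$coss >= cutoff_score
    K <- sum(out$sv)
  } else {
    if (is.null(cutoff_rank)) {
      K <- kneedle_cutoff(out$coss[seq_len(sum(scored))],
                          sensitivity = sensitivity,
                          smoothing_window = smoothing_window)
      if (is.na(K)) {
        warning("no knee detected in the CoSS-rank curve; ",
                "zero features called (use cutoff_rank/cutoff_score)")
      }
    } else {
      cutoff_rank <- as.integer(cutoff_rank)
      if (is.na(cutoff_rank) || cutoff_rank < 1L ||
          cutoff_rank > sum(scored)) {
        stop("cutoff_rank out of range [1, ", sum(scored), "]")
      }
      K <- cutoff_rank
    }
    if (!is.na(K)) out$sv <- !is.na(out$rank) & out$rank <= K
  }
  attr(out, "cutoff_rank") <- K
  out
}
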