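# Per-filter share of positions nominated as candidates, as a multiple of
# the requested union fraction. Calibrated once on Gaussian noise so that
# the union over the default filter bank covers about the requested
# fraction of positions (default 15%); see the methods vignette.
.candidate_share <- 0.7

#' High-pass filter scores for breakpoint detection
#'
#' At position i the filter contrasts the k observations to the right of i
#' with the k observations to the left:
#' `sum(w * y[(i+1):(i+k)]) - sum(w * y[i:(i-k+1)])`, where the outer third
#' of the observations on each side (`floor(k/3)` probes farthest from i)
#' receive half weight to soften the abrupt window edges. The score is large
#' in absolute value when a level shift lies between i and i+1. Positions
#' where the window does not fit (`i < k` or `i > p - k`) score 0.
#'
#' @param y numeric vector, no missing values.
#' @param k window width on each side (probes).
#' @return numeric vector of length `length(y)` of filter scores.
#' @examples
#' highpass_scores(c(0, 0, 0, 1, 1, 1), k = 3)
#' @export
highpass_scores <- function(y, k) {
  if (k < 1) stop("k must be >= 1")
  p <- length(y)
  scores <- numeric(p)
  if (p <= 2 * k) return(scores)
  n_outer <- floor(k / 3)
  cs <- c(0, cumsum(y))
  i <- k:(p - k)
  right <- (cs[i + k + 1] - cs[i + 1]) -
    0.5 * (cs[i + k + 1] - cs[i + k - n_outer + 1])
  left <- (cs[i + 1] - cs[i - k + 1]) -
    0.5 * (cs[i - k + n_outer + 1] - cs[i - k + 1])
  scores[i] <- right - left
  scores
}

#' Select candidate breakpoints by high-pass filtering
#'
#' For each filter width in the bank, positions that are local maxima of the
#' absolute score and exceed a per-filter quantile threshold are nominated;
#' the candidate set is the union over filters, calibrated to cover roughly
#' `target_fraction` of all positions on featureless (pure noise) data.
#' True level shifts produce scores far above the noise quantile, so they
#' are retained with near certainty.
#'
#' @param y numeric vector, no missing values.
#' @param widths filter half-window widths; default `c(3, 12)` plus a
#'   width matching `kmin` when that differs, so that aberrations of the
#'   shortest accepted length are detectable.
#' @param kmin minimum accepted segment length (adds a matched filter).
#' @param target_fraction requested fraction of positions in the candidate
#'   set, in (0, 1]; default 0.15.
#' @return an object of class `candidate_set`: list with `starts` (sorted
#'   candidate segment-start indices r_0 = 1 < ... < r_q = p + 1), and `p`.
#' @export
select_candidates <- function(y, widths = NULL, kmin = 1L,
                              target_fraction = 0.15) {
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must be in (0, 1]")
  }
  p <- length(y)
  if (is.null(widths)) widths <- unique(c(3L, 12L, max(1L, as.integer(kmin))))
  if (any(widths < 1)) stop("filter widths must be >= 1")
  if (target_fraction >= 1) {
    return(candidate_set(seq_len(p), p))
  }
  share <- min(1, .candidate_share * target_fraction)
  bp <- integer(0)                    # breakpoint positions i (cut after i)
  for (k in widths) {
    sc <- abs(highpass_scores(y, k))
    lm <- local_maxima(sc)
    thr <- stats::quantile(sc, probs = 1 - share, names = FALSE, type = 7)
    bp <- c(bp, which(lm & sc > thr))
  }
  candidate_set(sort(unique(c(1L, bp + 1L))), p)
}

# Local maxima of a series: value strictly greater than the previous one
# (so a plateau keeps only its leftmost point) and >= the next one.
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n == 1L) return(TRUE)
  left <- c(TRUE, x[-1] > x[-n])
  right <- c(x[-n] >= x[-1], TRUE)
  left & right
}

#' @keywords internal
candidate_set <- function(starts, p) {
  starts <- as.integer(sort(unique(c(1L, starts, p + 1L))))
  starts <- starts[starts >= 1L & starts <= p + 1L]
  structure(list(starts = starts, p = as.integer(p)),
            class = "candidate_set")
}

#' PCF restricted to candidate breakpoints
#'
#' Solves the penalized least-squares segmentation exactly over the subset
#' of segmentations whose breakpoints lie in the candidate set, by running
#' the dynamic program on per-interval aggregated sums and probe counts.
#' With the full candidate set this reproduces [pcf_exact()]; with q
#' candidates the work is `O(q^2)` instead of `O(p^2)`.
#'
#' @param y numeric vector, no missing values.
#' @param candidates a `candidate_set` from [select_candidates()], or an
#'   integer vector of candidate segment-start indices.
#' @param gamma penalty per segment.
#' @param kmin minimum probes per segment.
#' @return a `pcf_segmentation`, as from [pcf_exact()].
#' @export
pcf_on_candidates <- function(y, candidates, gamma, kmin = 1L) {
  check_penalty(gamma, kmin)
  p <- length(y)
  if (anyNA(y)) stop("y must not contain missing values; impute first")
  if (!inherits(candidates, "candidate_set")) {
    candidates <- candidate_set(candidates, p)
  }
  r <- candidates$starts
  if (candidates$p != p || r[1] != 1L || r[length(r)] != p + 1L ||
      is.unsorted(r, strictly = TRUE)) {
    stop("malformed candidate set for this sequence")
  }
  if (p < kmin) {
    warning("fewer probes (", p, ") than kmin (", kmin,
            "); returning a single segment")
    return(new_segmentation(1L, p, mean(y),
                            cost = sum((y - mean(y))^2) + gamma,
                            cost_prime = -sum(y)^2 / p + gamma))
  }
  q <- length(r) - 1L
  cnt <- diff(r)
  cs <- c(0, cumsum(y))
  u <- cs[r[-1]] - cs[r[-length(r)]]
  dp <- pcf_dp_core(u, cnt, gamma, kmin)
  starts_c <- backtrack_starts(dp$t)     # in candidate-interval space
  starts <- r[starts_c]
  means <- segment_means(y, starts)
  new_segmentation(starts, p, means,
                   cost = dp$e[q + 1] + sum(y^2),
                   cost_prime = dp$e[q + 1])
}

#' Fast heuristic PCF
#'
#' Combines [select_candidates()] and [pcf_on_candidates()]. On arms longer
#' than `max_arm` probes the sequence is processed in overlapping
#' subsequences left to right: filter candidates are detected within each
#' new subsequence and pooled with the breakpoints already accepted on
#' earlier ones, and the candidate-restricted fit is re-run on the growing
#' prefix, which keeps the candidate count small while damping boundary
#' effects. Segment means are exact averages of the full data by
#' construction.
#'
#' @param y numeric vector, no missing values.
#' @param gamma penalty per segment.
#' @param kmin minimum probes per segment.
#' @param target_fraction requested candidate fraction, see
#'   [select_candidates()].
#' @param max_arm probe count above which subsequence processing is used.
#' @param sub_len subsequence length.
#' @param overlap overlap between consecutive subsequences.
#' @return a `pcf_segmentation`, as from [pcf_exact()].
#' @export
pcf_fast <- function(y, gamma, kmin = 1L, target_fraction = 0.15,
                     max_arm = 15000L, sub_len = 5000L, overlap = 1000L) {
  check_penalty(gamma, kmin)
  p <- length(y)
  if (p == 0) stop("empty input")
  if (anyNA(y)) stop("y must not contain missing values; impute first")
  if (p <= max_arm) {
    cand <- select_candidates(y, kmin = kmin,
                              target_fraction = target_fraction)
    return(pcf_on_candidates(y, cand, gamma, kmin))
  }
  step <- sub_len - overlap
  start <- 1L
  carried <- integer(0)
  fit <- NULL
  repeat {
    end <- min(p, start + sub_len - 1L)
    sub <- y[start:end]
    cand_sub <- select_candidates(sub, kmin = kmin,
                                  target_fraction = target_fraction)
    new_starts <- cand_sub$starts + start - 1L
    new_starts <- new_starts[new_starts <= end]
    cand <- candidate_set(c(carried, new_starts), end)
    fit <- pcf_on_candidates(y[1:end], cand, gamma, kmin)
    carried <- fit$start_indices
    if (end >= p) break
    start <- start + step
  }
  fit
}
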