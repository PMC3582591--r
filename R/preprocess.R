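#' Clip a value symmetrically at a threshold
#'
#' The Winsorizing transform: values beyond `theta` in absolute value are
#' moved to `theta` (keeping their sign); values within the band pass
#' through unchanged.
#'
#' @param x numeric vector of residuals.
#' @param theta positive clipping threshold.
#' @return `x` with every entry confined to `[-theta, theta]`.
#' @examples
#' psi_clip(c(2.7, -0.4, -9), theta = 1.5)
#' @export
psi_clip <- function(x, theta) {
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta <= 0) {
    stop("theta must be a positive number")
  }
  pmin(pmax(x, -theta), theta)
}

#' Running-median trend estimate
#'
#' The trend at probe j is the median of the window `y[j-k] ... y[j+k]`,
#' shrunk at the sequence edges (no padding). Even-sized edge windows use
#' the average of the two central order statistics (the usual median).
#'
#' @param y numeric vector, no missing values.
#' @param k half-width of the window in probes (window size `2k+1`).
#' @return numeric vector of the same length as `y`.
#' @examples
#' median_filter_trend(c(0, 0, 0, 10, 0, 0, 0), k = 2)
#' @export
median_filter_trend <- function(y, k = 25) {
  if (length(y) == 0) stop("empty input")
  if (k < 1) stop("k must be >= 1")
  p <- length(y)
  if (p == 1) return(y)
  k <- min(k, p - 1)
  # interior: fixed windows of size 2k+1 via stats::runmed; edges: shrinking
  if (p >= 2 * k + 1) {
    trend <- as.numeric(stats::runmed(y, 2 * k + 1, endrule = "keep"))
  } else {
    trend <- y
  }
  edge <- c(seq_len(min(k, p)), seq.int(max(p - k + 1, 1), p))
  for (j in unique(edge)) {
    win <- max(1, j - k):min(p, j + k)
    trend[j] <- stats::median(y[win])
  }
  trend
}

#' Robust scale by median absolute deviation
#'
#' Returns `1.4826 * median(|x - median(x)|)`, which estimates the standard
#' deviation for Gaussian data. Missing values are dropped.
#'
#' @param x numeric vector with at least 2 non-missing values.
#' @return scale estimate (>= 0).
#' @export
mad_scale <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 non-missing values")
  1.4826 * stats::median(abs(x - stats::median(x)))
}

#' Winsorize outliers in a copy number table
#'
#' Per sample and chromosome arm, a running-median trend is estimated, the
#' residual scale s is estimated by [mad_scale()], and residuals beyond
#' `tau * s` are clipped to that threshold: the Winsorized value is
#' `trend + psi_clip(y - trend, tau * s)`. Optionally the trend is
#' re-estimated from a PCF fit to the Winsorized values and the clipping
#' repeated (`iterate = TRUE`), which protects probes adjacent to true
#' breakpoints from being treated as outliers.
#'
#' @param tab a copy number table (see [cn_table()]).
#' @param tau clipping multiple of the robust SD; typical values 1.5--3,
#'   default 2.5.
#' @param k_trend half-width of the running-median window, default 25 probes.
#' @param iterate re-estimate the trend from a PCF fit and re-clip.
#' @param n_iter number of PCF refinement passes when `iterate = TRUE`.
#' @param gamma penalty used for the PCF trend fit when iterating.
#' @param kmin minimum segment length for the PCF trend fit.
#' @param centromeres,whole_chrom arm assignment, see [assign_arms()].
#' @return a copy number table of identical shape with outliers damped;
#'   missing values stay missing.
#' @examples
#' tab <- cn_table(rep(1, 10), 1:10,
#'                 c(0.1, -0.2, 0.1, -0.1, 10, 0.2, -0.1, 0.1, -0.2, 0.1))
#' winsorize(tab, tau = 2.5, k_trend = 2, whole_chrom = TRUE)
#' @export
winsorize <- function(tab, tau = 2.5, k_trend = 25, iterate = FALSE,
                      n_iter = 1, gamma = 40, kmin = 5,
                      centromeres = hg19_centromeres(), whole_chrom = FALSE) {
  if (tau <= 0) stop("tau must be positive")
  if (k_trend < 1) stop("k_trend must be >= 1")
  arms <- assign_arms(tab, centromeres, whole_chrom)
  out <- tab
  for (sid in sample_ids(tab)) {
    for (rows in arm_blocks(tab, arms)) {
      y <- tab[[sid]][rows]
      obs <- which(!is.na(y))
      if (length(obs) < 2) next
      yo <- y[obs]
      yw <- winsorize_track(yo, tau, k_trend)
      if (iterate) {
        for (i in seq_len(n_iter)) {
          sd_hat <- estimate_residual_sd(yw)
          fit <- pcf_exact(yw / sd_hat, gamma = gamma, kmin = kmin)
          trend <- fitted_values(fit) * sd_hat
          yw <- clip_to_trend(yo, trend, tau)
        }
      }
      y[obs] <- yw
      out[[sid]][rows] <- y
    }
  }
  out
}

#' @keywords internal
winsorize_track <- function(y, tau, k_trend) {
  trend <- median_filter_trend(y, k_trend)
  clip_to_trend(y, trend, tau)
}

#' @keywords internal
clip_to_trend <- function(y, trend, tau) {
  res <- y - trend
  s <- mad_scale(res)
  if (s == 0) {
    warning("residual scale is zero; all deviations clipped to the trend")
    s <- 1e-12
  }
  trend + psi_clip(res, tau * s)
}

#' Robust residual SD used for penalty scaling
#'
#' The PCF penalty is scale dependent, so each sample's data are divided by
#' an estimate of the noise SD before fitting (equivalently, the penalty is
#' multiplied by the residual variance). The estimator is the MAD scale of
#' lag-1 differences divided by sqrt(2), which is insensitive to the true
#' piecewise-constant signal since only probes adjacent to a breakpoint
#' contribute level shifts to the differences. With multiple arms, the
#' per-arm estimates are combined by their median.
#'
#' @param y numeric vector (one arm), or a list of numeric vectors (arms).
#' @return scalar SD estimate.
#' @export
estimate_residual_sd <- function(y) {
  if (!is.list(y)) y <- list(y)
  ests <- vapply(y, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3) return(NA_real_)
    mad_scale(diff(v)) / sqrt(2)
  }, numeric(1))
  ests <- ests[!is.na(ests)]
  if (!length(ests)) stop("too few values to estimate the residual SD")
  stats::median(ests)
}

#' @keywords internal
sample_residual_sd <- function(tab, arms, sid) {
  estimate_residual_sd(lapply(arm_blocks(tab, arms),
                              function(rows) tab[[sid]][rows]))
}

#' Impute missing values from the nearest observed neighbours
#'
#' Within each sample and arm, a missing probe value is replaced by the mean
#' of the nearest observed value on each side (the single nearest value at
#' the arm edges). A fully observed table is returned unchanged.
#'
#' @param tab a copy number table.
#' @param centromeres,whole_chrom arm assignment, see [assign_arms()].
#' @return a copy number table with no missing values.
#' @examples
#' tab <- cn_table(rep(1, 3), 1:3, c(1, NA, 3))
#' impute_missing(tab, whole_chrom = TRUE)
#' @export
impute_missing <- function(tab, centromeres = hg19_centromeres(),
                           whole_chrom = FALSE) {
  arms <- assign_arms(tab, centromeres, whole_chrom)
  out <- tab
  for (sid in sample_ids(tab)) {
    for (rows in arm_blocks(tab, arms)) {
      y <- tab[[sid]][rows]
      if (!anyNA(y)) next
      out[[sid]][rows] <- impute_track(y)
    }
  }
  out
}

#' @keywords internal
impute_track <- function(y) {
  obs <- which(!is.na(y))
  if (!length(obs)) stop("cannot impute an arm with no observed values")
  miss <- which(is.na(y))
  li <- findInterval(miss, obs)        # index of nearest observed probe <= j
  ri <- li + 1L                        # nearest observed probe > j
  lv <- ifelse(li >= 1L, y[obs[pmax(li, 1L)]], NA_real_)
  rv <- ifelse(ri <= length(obs), y[obs[pmin(ri, length(obs))]], NA_real_)
  y[miss] <- rowMeans(cbind(lv, rv), na.rm = TRUE)
  y
}
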