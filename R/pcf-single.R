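# Core dynamic program shared by the exact and candidate-restricted fits.
#
# Operates on aggregated data: u[k] is the sum of observations in the k-th
# inter-candidate interval and cnt[k] the number of probes in it (for the
# exact fit u = y and cnt = 1). e[k+1] is the optimal value of the
# penalized criterion (in its sum-free form, i.e. without the constant
# sum(y^2)) over the first k intervals; t[k] is the interval index at which
# the last segment of that optimum starts. Segments shorter than kmin probes
# are excluded by giving them infinite cost; prefixes that admit no legal
# split inherit e = Inf. Ties in the minimization go to the smallest start
# index (the longest final segment).
#' @keywords internal
pcf_dp_core <- function(u, cnt, gamma, kmin = 1L) {
  q <- length(u)
  cu <- c(0, cumsum(u))
  cc <- c(0, cumsum(cnt))
  e <- numeric(q + 1)
  tk <- integer(q)
  for (k in seq_len(q)) {
    j <- seq_len(k)
    len <- cc[k + 1] - cc[j]
    v <- e[j] - (cu[k + 1] - cu[j])^2 / len + gamma
    if (kmin > 1L) v[len < kmin] <- Inf
    w <- which.min(v)
    e[k + 1] <- v[w]
    tk[k] <- w
  }
  list(e = e, t = tk)
}

#' @keywords internal
backtrack_starts <- function(tk) {
  starts <- integer(0)
  k <- length(tk)
  while (k >= 1L) {
    s <- tk[k]
    starts <- c(s, starts)
    k <- s - 1L
  }
  starts
}

#' @keywords internal
new_segmentation <- function(start_indices, p, means, cost, cost_prime,
                             sd_hat = 1) {
  lengths <- diff(c(start_indices, p + 1L))
  structure(list(start_indices = as.integer(start_indices),
                 lengths = as.integer(lengths),
                 n_segments = length(start_indices),
                 means = means,
                 cost = cost,
                 cost_prime = cost_prime,
                 p = as.integer(p),
                 sd_hat = sd_hat),
            class = "pcf_segmentation")
}

#' Exact single-sample piecewise constant fit
#'
#' Minimizes the penalized least-squares criterion
#' `sum_m sum_{j in segment m} (y_j - mean_m)^2 + gamma * M`
#' over all segmentations of `y` into `M` contiguous segments of at least
#' `kmin` probes, by an `O(p^2)` dynamic program expressed through running
#' cumulative sums. The fitted value on a segment is the segment average.
#'
#' The penalty is scale dependent; with `normalize = TRUE` the data are
#' divided by the robust residual SD of the sample ([estimate_residual_sd()])
#' before fitting and the segment means are rescaled afterwards, which is
#' equivalent to using a sample-specific penalty `gamma * sd^2`.
#'
#' @param y numeric vector of log2 ratios for one sample on one chromosome
#'   arm; no missing values (see [impute_missing()]).
#' @param gamma positive penalty per segment.
#' @param kmin minimum number of probes per segment (`kmin = 1` places no
#'   constraint).
#' @param normalize divide by the estimated residual SD before fitting.
#' @return an object of class `pcf_segmentation`: a list with
#'   `start_indices` (1-based probe index where each segment starts),
#'   `lengths`, `n_segments`, `means` (segment averages on the original
#'   scale), `cost` (criterion value at the optimum, on the fitted scale),
#'   and `cost_prime` (the equivalent criterion without the constant
#'   `sum(y^2)` term).
#' @examples
#' pcf_exact(c(0, 0, 0, 4, 4, 4), gamma = 1)
#' @export
pcf_exact <- function(y, gamma, kmin = 1L, normalize = FALSE) {
  check_penalty(gamma, kmin)
  if (length(y) == 0) stop("empty input")
  if (anyNA(y)) stop("y must not contain missing values; impute first")
  p <- length(y)
  sd_hat <- 1
  yf <- y
  if (normalize) {
    sd_hat <- estimate_residual_sd(y)
    if (sd_hat <= 0) sd_hat <- 1
    yf <- y / sd_hat
  }
  if (p < kmin) {
    warning("fewer probes (", p, ") than kmin (", kmin,
            "); returning a single segment")
    m <- mean(yf)
    return(new_segmentation(1L, p, mean(y),
                            cost = sum((yf - m)^2) + gamma,
                            cost_prime = -sum(yf)^2 / p + gamma,
                            sd_hat = sd_hat))
  }
  dp <- pcf_dp_core(yf, rep(1L, p), gamma, kmin)
  starts <- backtrack_starts(dp$t)
  means <- segment_means(yf, starts) * sd_hat
  new_segmentation(starts, p, means,
                   cost = dp$e[p + 1] + sum(yf^2),
                   cost_prime = dp$e[p + 1],
                   sd_hat = sd_hat)
}

#' @keywords internal
check_penalty <- function(gamma, kmin) {
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) || gamma <= 0) {
    stop("gamma must be a positive number")
  }
  if (kmin < 1) stop("kmin must be >= 1")
}

#' @keywords internal
segment_means <- function(y, starts) {
  p <- length(y)
  ends <- c(starts[-1] - 1L, p)
  vapply(seq_along(starts),
         function(m) mean(y[starts[m]:ends[m]]), numeric(1))
}

#' Per-probe fitted values of a segmentation
#'
#' @param seg a `pcf_segmentation` (or the analogous multi-sample object).
#' @return numeric vector (or probe-by-sample matrix for multi-sample fits)
#'   with each probe set to its segment mean.
#' @export
fitted_values <- function(seg) {
  if (is.matrix(seg$means)) {
    apply(seg$means, 2, function(mm) rep(mm, seg$lengths))
  } else {
    rep(seg$means, seg$lengths)
  }
}

#' Evaluate the penalized least-squares criterion for a given segmentation
#'
#' For segment starts `S` this computes
#' `L = sum of within-segment squared deviations + gamma * M`, and its
#' equivalent form `L' = -sum_m (segment sum)^2 / segment length + gamma * M`
#' which differs from `L` by the constant `sum(y^2)`.
#'
#' @param y numeric vector.
#' @param start_indices 1-based segment start indices (first must be 1).
#' @param gamma penalty per segment.
#' @param form `"L"` (default) or `"Lprime"`.
#' @return the criterion value.
#' @examples
#' criterion_value(c(0, 0, 0, 4, 4, 4), c(1, 4), gamma = 1)
#' @export
criterion_value <- function(y, start_indices, gamma, form = c("L", "Lprime")) {
  form <- match.arg(form)
  p <- length(y)
  start_indices <- as.integer(start_indices)
  if (length(start_indices) == 0 || start_indices[1] != 1L ||
      is.unsorted(start_indices, strictly = TRUE) ||
      any(start_indices > p)) {
    stop("start_indices must be strictly increasing, begin at 1, and not exceed length(y)")
  }
  if (anyNA(y)) stop("y must not contain missing values")
  ends <- c(start_indices[-1] - 1L, p)
  M <- length(start_indices)
  lp <- 0
  sse <- 0
  for (m in seq_len(M)) {
    seg <- y[start_indices[m]:ends[m]]
    lp <- lp - sum(seg)^2 / length(seg)
    sse <- sse + sum((seg - mean(seg))^2)
  }
  if (form == "L") sse + gamma * M else lp + gamma * M
}

#' Number of segments as a function of the penalty
#'
#' Runs [pcf_exact()] for each penalty in `gammas` and reports the number of
#' segments, the standard diagnostic for choosing gamma: the count is
#' non-increasing in gamma, and a plateau suggests a stable segmentation.
#'
#' @param y numeric vector.
#' @param gammas positive, sorted penalty grid.
#' @param kmin,normalize passed to [pcf_exact()].
#' @return `data.frame` with columns `gamma` and `n_segments`.
#' @export
pcf_profile_over_gamma <- function(y, gammas, kmin = 1L, normalize = FALSE) {
  if (length(gammas) == 0) stop("empty penalty grid")
  if (any(gammas <= 0)) stop("penalties must be positive")
  data.frame(
    gamma = gammas,
    n_segments = vapply(gammas, function(g) {
      pcf_exact(y, g, kmin = kmin, normalize = normalize)$n_segments
    }, numeric(1)))
}

#' Per-sample PCF segmentation of a copy number table
#'
#' Segments every sample on every chromosome arm independently. Data are
#' Winsorized beforehand if desired (see [winsorize()]); missing values are
#' imputed internally ([impute_missing()]). Each sample is normalized by its
#' robust residual SD before fitting so that `gamma` refers to
#' variance-normalized data.
#'
#' @param tab a copy number table (see [cn_table()]).
#' @param gamma penalty per segment on variance-normalized data; the
#'   conservative default is 40.
#' @param kmin minimum probes per segment, default 5.
#' @param normalize scale each sample by its estimated residual SD.
#' @param method `"auto"` uses the exact dynamic program on arms up to
#'   `max_arm` probes and the fast candidate-based fit above; `"exact"` and
#'   `"fast"` force one or the other.
#' @param max_arm arm length above which `"auto"` switches to the fast fit.
#' @param centromeres,whole_chrom arm assignment, see [assign_arms()].
#' @param return_fitted also return per-probe fitted values.
#' @param ... expert parameters passed to [pcf_fast()].
#' @return a segment `data.frame` with columns `sampleID`, `chrom`, `arm`,
#'   `start.pos`, `end.pos`, `n.probes`, `mean`; if `return_fitted = TRUE`,
#'   a list with elements `segments` and `fitted` (a copy number table of
#'   fitted values).
#' @examples
#' tab <- cn_table(rep(1, 8), 1:8, c(0, 0, 0, 0, 3, 3, 3, 3))
#' pcf(tab, gamma = 5, kmin = 1, normalize = FALSE, whole_chrom = TRUE)
#' @export
pcf <- function(tab, gamma = 40, kmin = 5L, normalize = TRUE,
                method = c("auto", "exact", "fast"), max_arm = 15000L,
                centromeres = hg19_centromeres(), whole_chrom = FALSE,
                return_fitted = FALSE, ...) {
  method <- match.arg(method)
  check_penalty(gamma, kmin)
  arms <- assign_arms(tab, centromeres, whole_chrom)
  tab_c <- impute_missing(tab, centromeres, whole_chrom)
  blocks <- arm_blocks(tab_c, arms)
  seg_rows <- list()
  fitted_tab <- if (return_fitted) tab_c else NULL
  for (sid in sample_ids(tab_c)) {
    sd_hat <- if (normalize) sample_residual_sd(tab_c, arms, sid) else 1
    if (!is.finite(sd_hat) || sd_hat <= 0) sd_hat <- 1
    for (rows in blocks) {
      y <- tab_c[[sid]][rows] / sd_hat
      p <- length(y)
      use_fast <- method == "fast" || (method == "auto" && p > max_arm)
      fit <- if (use_fast) {
        pcf_fast(y, gamma = gamma, kmin = kmin, max_arm = max_arm, ...)
      } else {
        pcf_exact(y, gamma = gamma, kmin = kmin)
      }
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        sampleID = sid,
        chrom = tab_c$chrom[rows[1]],
        arm = arms[rows[1]],
        start.pos = tab_c$pos[rows][fit$start_indices],
        end.pos = tab_c$pos[rows][c(fit$start_indices[-1] - 1L, p)],
        n.probes = fit$lengths,
        mean = fit$means * sd_hat,
        stringsAsFactors = FALSE)
      if (return_fitted) {
        fitted_tab[[sid]][rows] <- fitted_values(fit) * sd_hat
      }
    }
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  if (return_fitted) list(segments = segments, fitted = fitted_tab)
  else segments
}
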