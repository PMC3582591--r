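# Multi-sample dynamic program: identical structure to the single-sample
# recursion, but the candidate cost of a final segment is summed over
# samples and the per-segment penalty is n * gamma (one term per sample in
# the summed criterion).
#' @keywords internal
multipcf_dp_core <- function(Y, gamma, kmin = 1L) {
  n <- nrow(Y)
  p <- ncol(Y)
  CS <- cbind(0, t(apply(Y, 1L, cumsum)))   # n x (p+1) running sums
  if (n == 1L) CS <- matrix(c(0, cumsum(Y[1L, ])), nrow = 1L)
  e <- numeric(p + 1)
  tk <- integer(p)
  for (k in seq_len(p)) {
    j <- seq_len(k)
    len <- k - j + 1
    sq <- (CS[, k + 1] - CS[, j, drop = FALSE])^2
    v <- e[j] - .colSums(sq, n, k) / len + n * gamma
    if (kmin > 1L) v[len < kmin] <- Inf
    w <- which.min(v)
    e[k + 1] <- v[w]
    tk[k] <- w
  }
  list(e = e, t = tk)
}

#' Exact multi-sample PCF with common breakpoints
#'
#' Jointly segments `n` samples measured on the same probe grid, minimizing
#' the sum over samples of the single-sample penalized criterion under one
#' segmentation common to all samples. Each segment therefore costs
#' `n * gamma`. Joint fitting pools evidence across samples, which raises
#' sensitivity for concordant low-amplitude events at the price of forcing
#' shared boundaries.
#'
#' @param Y numeric matrix, samples in rows, probes in columns; no missing
#'   values.
#' @param gamma positive penalty per segment per sample.
#' @param kmin minimum probes per segment.
#' @param w optional per-sample weights; sample i is multiplied by
#'   `w[i]` (after any normalization) before fitting and its means are
#'   scaled back afterwards.
#' @param normalize divide each sample by its robust residual SD
#'   ([estimate_residual_sd()]) before fitting and rescale the means after.
#' @return a list of class `multipcf_segmentation` with `start_indices`,
#'   `lengths`, `n_segments`, `means` (an M x n matrix of per-sample segment
#'   averages on the original scale), `cost` and `cost_prime` (on the
#'   fitted scale).
#' @examples
#' Y <- rbind(a = c(0, 0, 0, 4, 4, 4), b = c(1, 1, 1, 1, 1, 1))
#' multipcf_exact(Y, gamma = 1)
#' @export
multipcf_exact <- function(Y, gamma, kmin = 1L, w = NULL, normalize = FALSE) {
  check_penalty(gamma, kmin)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  n <- nrow(Y)
  p <- ncol(Y)
  if (n == 0L || p == 0L) stop("empty input matrix")
  if (anyNA(Y)) stop("Y must not contain missing values; impute first")
  scale_i <- rep(1, n)
  if (normalize) {
    scale_i <- apply(Y, 1L, estimate_residual_sd)
    scale_i[!is.finite(scale_i) | scale_i <= 0] <- 1
  }
  if (!is.null(w)) {
    if (length(w) != n || any(w <= 0)) {
      stop("w must hold one positive weight per sample")
    }
    scale_i <- scale_i / w
  }
  Yf <- Y / scale_i
  if (p < kmin) {
    warning("fewer probes (", p, ") than kmin (", kmin,
            "); returning a single segment")
    starts <- 1L
  } else {
    starts <- backtrack_starts(multipcf_dp_core(Yf, gamma, kmin)$t)
  }
  ends <- c(starts[-1] - 1L, p)
  means <- t(vapply(seq_along(starts), function(m) {
    rowMeans(Yf[, starts[m]:ends[m], drop = FALSE]) * scale_i
  }, numeric(n)))
  if (n == 1L) means <- matrix(means, ncol = 1L)
  colnames(means) <- rownames(Y)
  lp <- summed_criterion(Yf, starts, gamma, form = "Lprime")
  seg <- new_segmentation(starts, p, means,
                          cost = lp + sum(Yf^2),
                          cost_prime = lp,
                          sd_hat = scale_i)
  class(seg) <- c("multipcf_segmentation", class(seg))
  seg
}

#' Summed multi-sample criterion for a given common segmentation
#'
#' Sums the single-sample criterion [criterion_value()] over the rows of
#' `Y` for one common set of segment starts.
#'
#' @param Y samples x probes matrix.
#' @param start_indices common 1-based segment start indices.
#' @param gamma penalty per segment per sample.
#' @param form `"L"` or `"Lprime"`, as in [criterion_value()].
#' @return the summed criterion value.
#' @export
summed_criterion <- function(Y, start_indices, gamma,
                             form = c("L", "Lprime")) {
  form <- match.arg(form)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  sum(vapply(seq_len(nrow(Y)), function(i) {
    criterion_value(Y[i, ], start_indices, gamma, form = form)
  }, numeric(1)))
}

#' Joint multi-sample PCF segmentation of a copy number table
#'
#' Applies [multipcf_exact()] per chromosome arm across all samples of the
#' table, producing segments with boundaries common to every sample and one
#' mean column per sample. Samples are normalized by their robust residual
#' SD by default so that samples with equal signal-to-noise contribute
#' equally; additional per-sample weights (e.g. for tumor cell fraction)
#' may be supplied.
#'
#' @param tab a copy number table (see [cn_table()]).
#' @param gamma penalty per segment per sample (variance-normalized scale).
#' @param kmin minimum probes per segment.
#' @param normalize divide each sample by its estimated residual SD.
#' @param w optional vector of per-sample weights.
#' @param centromeres,whole_chrom arm assignment, see [assign_arms()].
#' @param return_fitted also return per-probe fitted values.
#' @return a segment `data.frame` with columns `chrom`, `arm`, `start.pos`,
#'   `end.pos`, `n.probes`, then one mean column per sample; or a list with
#'   `segments` and `fitted` when `return_fitted = TRUE`.
#' @export
multipcf <- function(tab, gamma = 40, kmin = 5L, normalize = TRUE, w = NULL,
                     centromeres = hg19_centromeres(), whole_chrom = FALSE,
                     return_fitted = FALSE) {
  check_penalty(gamma, kmin)
  arms <- assign_arms(tab, centromeres, whole_chrom)
  tab_c <- impute_missing(tab, centromeres, whole_chrom)
  sids <- sample_ids(tab_c)
  # one residual SD per sample, pooled over arms, as in pcf()
  sd_all <- if (normalize) {
    vapply(sids, function(sid) sample_residual_sd(tab_c, arms, sid),
           numeric(1))
  } else rep(1, length(sids))
  sd_all[!is.finite(sd_all) | sd_all <= 0] <- 1
  seg_rows <- list()
  fitted_tab <- if (return_fitted) tab_c else NULL
  for (rows in arm_blocks(tab_c, arms)) {
    Y <- t(cn_values(tab_c[rows, , drop = FALSE])) / sd_all
    fit <- multipcf_exact(Y, gamma = gamma, kmin = kmin, w = w)
    p <- length(rows)
    means <- fit$means * rep(sd_all, each = fit$n_segments)
    colnames(means) <- sids
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      chrom = tab_c$chrom[rows[1]],
      arm = arms[rows[1]],
      start.pos = tab_c$pos[rows][fit$start_indices],
      end.pos = tab_c$pos[rows][c(fit$start_indices[-1] - 1L, p)],
      n.probes = fit$lengths,
      means,
      stringsAsFactors = FALSE, check.names = FALSE)
    if (return_fitted) {
      for (i in seq_along(sids)) {
        fitted_tab[[sids[i]]][rows] <- rep(means[, i], fit$lengths)
      }
    }
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  if (return_fitted) list(segments = segments, fitted = fitted_tab)
  else segments
}
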