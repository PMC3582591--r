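#' Threshold-based aberration calling
#'
#' Classifies fitted copy number values into gains (`fitted > theta_plus`),
#' losses (`fitted < -theta_minus`) and normal (everything else; exact
#' equality with a threshold is called normal). The thresholds are in log2
#' ratio units and determine what counts as a biologically meaningful
#' aberration.
#'
#' @param fitted numeric vector, matrix or fitted copy number table of
#'   per-probe fitted values.
#' @param theta_plus positive gain threshold (default 0.1).
#' @param theta_minus positive loss threshold (default `theta_plus`).
#' @return calls as a factor-like character structure matching the shape of
#'   `fitted`, with values `"loss"`, `"normal"`, `"gain"` (NA propagates).
#' @examples
#' call_aberrations(c(-0.3, 0.01, 0.4), theta_plus = 0.1)
#' @export
call_aberrations <- function(fitted, theta_plus = 0.1,
                             theta_minus = theta_plus) {
  if (theta_plus <= 0 || theta_minus <= 0) {
    stop("calling thresholds must be positive")
  }
  if (is.data.frame(fitted) && all(c("chrom", "pos") %in% names(fitted))) {
    out <- fitted
    for (sid in sample_ids(fitted)) {
      out[[sid]] <- call_aberrations(fitted[[sid]], theta_plus, theta_minus)
    }
    return(out)
  }
  calls <- ifelse(fitted > theta_plus, "gain",
                  ifelse(fitted < -theta_minus, "loss", "normal"))
  calls
}

#' Per-probe gain and loss frequencies across samples
#'
#' @param calls a matrix or call table from [call_aberrations()] with one
#'   column per sample, probes in rows.
#' @return a `data.frame` (with `chrom`/`pos` carried over when present)
#'   holding `gain.freq`, `loss.freq` and `normal.freq`, each the fraction
#'   of samples with that call at the probe.
#' @export
aberration_frequencies <- function(calls) {
  meta <- NULL
  if (is.data.frame(calls) && all(c("chrom", "pos") %in% names(calls))) {
    meta <- calls[, c("chrom", "pos")]
    calls <- as.matrix(calls[, -(1:2), drop = FALSE])
  }
  if (is.null(dim(calls))) calls <- matrix(calls, ncol = 1)
  if (ncol(calls) == 0 || nrow(calls) == 0) stop("no calls supplied")
  freq <- function(lbl) rowMeans(calls == lbl, na.rm = TRUE)
  out <- data.frame(gain.freq = freq("gain"),
                    loss.freq = freq("loss"),
                    normal.freq = freq("normal"))
  if (!is.null(meta)) out <- cbind(meta, out)
  rownames(out) <- NULL
  out
}

#' Goodness-of-fit diagnostics over a penalty grid
#'
#' For each penalty the exact fit is computed and summarized by its segment
#' count and residual variance (mean squared deviation of the data from the
#' fitted curve). Inspecting where the segment count plateaus and the
#' residual variance stops improving is the practical way to choose gamma.
#'
#' @param y numeric vector (one sample, one arm), no missing values.
#' @param gammas positive penalty grid.
#' @param kmin,normalize passed to [pcf_exact()].
#' @return `data.frame` with columns `gamma`, `n_segments`, `residual_var`.
#' @export
gamma_diagnostics <- function(y, gammas, kmin = 1L, normalize = FALSE) {
  if (length(gammas) == 0) stop("empty penalty grid")
  rows <- lapply(gammas, function(g) {
    fit <- pcf_exact(y, g, kmin = kmin, normalize = normalize)
    data.frame(gamma = g,
               n_segments = fit$n_segments,
               residual_var = mean((y - fitted_values(fit))^2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
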