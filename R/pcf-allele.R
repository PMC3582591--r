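#' Mirror B-allele frequencies around 0.5
#'
#' Replaces b with 1 - b when b > 0.5, folding the two heterozygote bands
#' onto one; allelic balance then reads 0.5 and any imbalance pushes the
#' mirrored value below 0.5. Missing values pass through. Idempotent.
#'
#' @param b numeric vector of BAF values in `[0, 1]` (NA allowed).
#' @return mirrored values in `[0, 0.5]`.
#' @examples
#' mirror_baf(c(0.7, 0.5, 0.2, NA))
#' @export
mirror_baf <- function(b) {
  if (any(b < 0 | b > 1, na.rm = TRUE)) stop("BAF values must lie in [0, 1]")
  ifelse(!is.na(b) & b > 0.5, 1 - b, b)
}

#' Retention mask for informative (heterozygous) BAF probes
#'
#' Germline homozygous probes carry no allelic information; after mirroring
#' they sit near 0, so mirrored values below `theta_baf` are dropped
#' (default 0.1). If homozygous probes have already been set to NA from a
#' matched germline genotype, use `theta_baf = 0` to drop only the NAs.
#'
#' @param b_mirrored mirrored BAF values (see [mirror_baf()]).
#' @param theta_baf threshold in `[0, 0.5]`.
#' @return logical vector, `TRUE` where the probe is retained.
#' @examples
#' filter_homozygous(c(0.05, 0.3, NA), theta_baf = 0.1)
#' @export
filter_homozygous <- function(b_mirrored, theta_baf = 0.1) {
  if (theta_baf < 0 || theta_baf > 0.5) {
    stop("theta_baf must lie in [0, 0.5]")
  }
  !is.na(b_mirrored) & b_mirrored >= theta_baf
}

#' Pair logR probes with retained BAF probes
#'
#' Each logR probe is assigned to the retained BAF probe nearest in genomic
#' position (ties to the leftward probe), and logR values assigned to the
#' same BAF probe are averaged. The result is a pair of equal-length tracks
#' on the retained-BAF grid: mirrored BAF values and paired logR averages.
#' A retained BAF probe to which no logR probe is nearest receives the value
#' of the globally nearest single logR probe.
#'
#' @param logr_pos,logr genomic positions and values of the logR probes.
#' @param baf_pos,baf_mirrored positions and mirrored values of the
#'   retained BAF probes.
#' @return a list of class `baf_logr_pair` with `positions` (retained BAF
#'   probe positions), `y1` (mirrored BAF), `y2` (paired logR averages),
#'   and `map` (for each logR probe, the index of its paired BAF probe).
#' @export
pair_logr_to_baf <- function(logr_pos, logr, baf_pos, baf_mirrored) {
  m <- length(baf_pos)
  if (m == 0) stop("no retained BAF probes to pair with")
  if (length(logr_pos) != length(logr) || length(baf_pos) != length(baf_mirrored)) {
    stop("positions and values must have equal length")
  }
  map <- nearest_index(logr_pos, baf_pos)
  y2 <- vapply(seq_len(m), function(t) {
    hit <- which(map == t)
    if (length(hit)) mean(logr[hit], na.rm = TRUE) else NA_real_
  }, numeric(1))
  empty <- which(is.na(y2))
  if (length(empty)) {
    back <- nearest_index(baf_pos[empty], logr_pos)
    y2[empty] <- logr[back]
  }
  structure(list(positions = baf_pos, y1 = baf_mirrored, y2 = y2, map = map),
            class = "baf_logr_pair")
}

# For each query position, index of the nearest reference position
# (ties broken toward the earlier/leftward reference probe).
#' @keywords internal
nearest_index <- function(query, ref) {
  vapply(query, function(q) {
    d <- abs(ref - q)
    which.min(d)                       # first minimum = leftward on ties
  }, integer(1))
}

#' Allele-specific PCF of paired logR/BAF tracks
#'
#' Fits one common segmentation to a sample's logR and BAF tracks so that a
#' copy number event visible in either track (or only one, as for a loss of
#' one allele compensated by a gain of the other, which changes BAF but not
#' logR) produces a breakpoint in both. The preprocessing mirrors BAF
#' around 0.5, drops homozygous probes (mirrored BAF below `theta_baf`),
#' pairs each logR probe with the nearest retained BAF probe (averaging
#' logR within a pair), and then runs the two-sample joint fit
#' [multipcf_exact()] on the stacked tracks with per-track residual-SD
#' normalization (BAF and logR live on different scales, and without
#' rescaling the noisier track would dominate the summed criterion).
#'
#' @param logr_pos,logr positions and log2-ratio values of the logR probes
#'   (one sample, one chromosome arm).
#' @param baf_pos,baf positions and raw BAF values (same arm); probe grids
#'   need not coincide.
#' @param gamma penalty per segment per track.
#' @param kmin minimum retained-BAF probes per segment.
#' @param theta_baf homozygote filter threshold, see [filter_homozygous()].
#' @param normalize per-track residual SD normalization (recommended).
#' @return a list of class `aspcf_segmentation` with `start_indices` (in
#'   retained-BAF probe space), `lengths`, `n_segments`, `means` (M x 2
#'   matrix, columns `BAF.mean` and `logR.mean`), `cost`, `start_pos` and
#'   `end_pos` (original genomic coordinates: a segment starts at the first
#'   logR probe paired into its first BAF probe), and the `pair` object.
#' @examples
#' pos <- 1:40
#' baf <- rep(c(0.5, 0.33), each = 20) + 0
#' logr <- rep(0, 40)
#' aspcf_track(pos, logr, pos, baf, gamma = 2, kmin = 1, normalize = FALSE)
#' @export
aspcf_track <- function(logr_pos, logr, baf_pos, baf, gamma = 40, kmin = 5L,
                        theta_baf = 0.1, normalize = TRUE) {
  check_penalty(gamma, kmin)
  bm <- mirror_baf(baf)
  keep <- filter_homozygous(bm, theta_baf)
  if (!any(keep)) stop("no informative BAF probes after filtering")
  obs_logr <- !is.na(logr)
  pair <- pair_logr_to_baf(logr_pos[obs_logr], logr[obs_logr],
                           baf_pos[keep], bm[keep])
  Y <- rbind(BAF = pair$y1, logR = pair$y2)
  fit <- multipcf_exact(Y, gamma = gamma, kmin = kmin, normalize = normalize)
  colnames(fit$means) <- c("BAF.mean", "logR.mean")
  m <- length(pair$y1)
  ends <- c(fit$start_indices[-1] - 1L, m)
  lp <- logr_pos[obs_logr]
  start_pos <- vapply(fit$start_indices, function(s) {
    hit <- which(pair$map >= s)
    if (length(hit)) lp[hit[1]] else pair$positions[s]
  }, numeric(1))
  end_pos <- vapply(ends, function(s) {
    hit <- which(pair$map <= s)
    if (length(hit)) lp[hit[length(hit)]] else pair$positions[s]
  }, numeric(1))
  fit$start_pos <- start_pos
  fit$end_pos <- end_pos
  fit$pair <- pair
  class(fit) <- c("aspcf_segmentation", class(fit))
  fit
}

#' Allele-specific PCF over copy number tables
#'
#' Runs [aspcf_track()] for every sample and chromosome arm of a paired
#' logR/BAF table set. The two tables must share sample columns; probe
#' grids may differ between the tables but each is sorted per arm.
#'
#' @param logr_tab copy number table of logR values.
#' @param baf_tab table of BAF values with the same sample columns.
#' @param gamma,kmin,theta_baf,normalize see [aspcf_track()].
#' @param centromeres,whole_chrom arm assignment, see [assign_arms()].
#' @return a segment `data.frame` with columns `sampleID`, `chrom`, `arm`,
#'   `start.pos`, `end.pos`, `n.probes` (retained BAF probes), `logR.mean`,
#'   `BAF.mean`.
#' @export
aspcf <- function(logr_tab, baf_tab, gamma = 40, kmin = 5L, theta_baf = 0.1,
                  normalize = TRUE, centromeres = hg19_centromeres(),
                  whole_chrom = FALSE) {
  sids <- sample_ids(logr_tab)
  if (!identical(sids, sample_ids(baf_tab))) {
    stop("logR and BAF tables must have identical sample columns")
  }
  arms_l <- assign_arms(logr_tab, centromeres, whole_chrom)
  arms_b <- assign_arms(baf_tab, centromeres, whole_chrom)
  blocks_l <- arm_blocks(logr_tab, arms_l)
  blocks_b <- arm_blocks(baf_tab, arms_b)
  seg_rows <- list()
  for (key in names(blocks_l)) {
    if (!key %in% names(blocks_b)) {
      stop("no BAF probes for chromosome arm ", key)
    }
    rl <- blocks_l[[key]]
    rb <- blocks_b[[key]]
    for (sid in sids) {
      fit <- aspcf_track(logr_tab$pos[rl], logr_tab[[sid]][rl],
                         baf_tab$pos[rb], baf_tab[[sid]][rb],
                         gamma = gamma, kmin = kmin, theta_baf = theta_baf,
                         normalize = normalize)
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        sampleID = sid,
        chrom = logr_tab$chrom[rl[1]],
        arm = arms_l[rl[1]],
        start.pos = fit$start_pos,
        end.pos = fit$end_pos,
        n.probes = fit$lengths,
        logR.mean = fit$means[, "logR.mean"],
        BAF.mean = fit$means[, "BAF.mean"],
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  segments
}
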