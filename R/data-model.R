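#' Construct a probe-by-sample copy number table
#'
#' A copy number table is a plain `data.frame` whose first two columns are
#' `chrom` and `pos` (1-based genomic coordinate of each probe) followed by
#' one numeric column of log2 ratios per sample. Probes are sorted by
#' `(chrom, pos)` and duplicates are rejected; `NA` entries mark missing
#' measurements.
#'
#' @param chrom character or integer vector of chromosome labels (a leading
#'   `"chr"` is stripped).
#' @param pos integer vector of probe positions (bp, 1-based).
#' @param values numeric matrix or data.frame with one column per sample, or
#'   a numeric vector for a single sample.
#' @param sample_ids optional sample names; defaults to the column names of
#'   `values` or `sample1`, `sample2`, ...
#' @return a `data.frame` with columns `chrom`, `pos`, and one column per
#'   sample, sorted by `(chrom, pos)`.
#' @examples
#' cn_table(chrom = c(1, 1, 2), pos = c(100, 200, 50),
#'          values = cbind(s1 = c(0.1, -0.2, 0.4)))
#' @export
cn_table <- function(chrom, pos, values, sample_ids = NULL) {
  chrom <- normalize_chrom(chrom)
  pos <- as.integer(pos)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1)
  unnamed <- is.matrix(values) && is.null(colnames(values))
  values <- as.data.frame(values)
  if (!is.null(sample_ids)) {
    names(values) <- sample_ids
  } else if (unnamed) {
    names(values) <- paste0("sample", seq_len(ncol(values)))
  }
  if (length(chrom) != length(pos) || nrow(values) != length(pos)) {
    stop("chrom, pos and values must describe the same number of probes")
  }
  for (j in seq_along(values)) values[[j]] <- as.numeric(values[[j]])
  tab <- data.frame(chrom = chrom, pos = pos, values,
                    stringsAsFactors = FALSE, check.names = FALSE)
  validate_cn_table(sort_cn_table(tab))
}

#' @keywords internal
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

# Sort probes by (chrom, pos) with chromosomes in karyotype order
# (1..22, X, Y, then anything else alphabetically).
#' @keywords internal
sort_cn_table <- function(tab) {
  tab <- tab[order(chrom_rank(tab$chrom), tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' @keywords internal
chrom_rank <- function(chrom) {
  known <- c(as.character(1:22), "X", "Y")
  r <- match(chrom, known)
  extra <- sort(unique(chrom[is.na(r)]))
  r[is.na(r)] <- length(known) + match(chrom[is.na(r)], extra)
  r
}

#' @keywords internal
validate_cn_table <- function(tab) {
  if (!is.data.frame(tab) || ncol(tab) < 3 ||
      !identical(names(tab)[1:2], c("chrom", "pos"))) {
    stop("a copy number table needs columns chrom, pos and >=1 sample column")
  }
  if (anyNA(tab$pos)) stop("probe positions must not be missing")
  key <- paste(tab$chrom, tab$pos)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos) probe at ", key[which(duplicated(key))[1]])
  }
  tab
}

#' @keywords internal
sample_ids <- function(tab) names(tab)[-(1:2)]

#' @keywords internal
cn_values <- function(tab) {
  as.matrix(tab[, -(1:2), drop = FALSE])
}

#' Read a copy number (or BAF) table from a tab-separated file
#'
#' The file must have a header line `chrom<TAB>pos<TAB><sample1>...`;
#' values are numeric or the token `NA` (case-sensitive). Rows are sorted by
#' `(chrom, pos)` on reading.
#'
#' @param source path to a file or a connection.
#' @param na_tokens strings to read as missing; default `"NA"`.
#' @return a copy number table (see [cn_table()]).
#' @export
read_cn_table <- function(source, na_tokens = "NA") {
  raw <- utils::read.delim(source, header = TRUE, sep = "\t",
                           na.strings = na_tokens, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3 || tolower(names(raw)[1]) != "chrom" ||
      tolower(names(raw)[2]) != "pos") {
    stop("expected header 'chrom<TAB>pos<TAB><sample>...'")
  }
  names(raw)[1:2] <- c("chrom", "pos")
  pos <- suppressWarnings(as.numeric(raw$pos))
  if (anyNA(pos)) {
    stop("non-numeric position in row ", which(is.na(pos))[1])
  }
  vals <- raw[, -(1:2), drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", v[bad[1]], "' in row ", bad[1],
           ", column '", names(vals)[j], "'")
    }
    vals[[j]] <- num
  }
  cn_table(raw$chrom, pos, vals)
}

#' Write a copy number table to a tab-separated file
#'
#' @param tab a copy number table.
#' @param sink output path or connection.
#' @export
write_cn_table <- function(tab, sink) {
  utils::write.table(tab, sink, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

#' Built-in hg19 centromere coordinates
#'
#' Approximate centromere midpoint per chromosome (GRCh37/hg19), used by
#' default to split chromosomes into p and q arms. Probes at positions less
#' than or equal to the centromere coordinate fall on the p arm.
#'
#' @return a `data.frame` with columns `chrom` and `centromere_pos`.
#' @export
hg19_centromeres <- function() {
  data.frame(
    chrom = c(as.character(1:22), "X", "Y"),
    centromere_pos = c(
      125000000L, 93300000L, 91000000L, 50400000L, 48400000L,
      61000000L, 59900000L, 45600000L, 49000000L, 40200000L,
      53700000L, 35800000L, 17900000L, 17600000L, 19000000L,
      36600000L, 24000000L, 17200000L, 26500000L, 27500000L,
      13200000L, 14700000L, 60600000L, 12500000L),
    stringsAsFactors = FALSE)
}

#' Read a centromere table
#'
#' @param source TSV file with header `chrom<TAB>centromere_pos`.
#' @return a `data.frame` with columns `chrom`, `centromere_pos`.
#' @export
read_centromeres <- function(source) {
  cen <- utils::read.delim(source, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(cen)[1:2] <- c("chrom", "centromere_pos")
  cen$chrom <- normalize_chrom(cen$chrom)
  cen$centromere_pos <- as.numeric(cen$centromere_pos)
  cen
}

#' Assign each probe to a chromosome arm
#'
#' Segmentation never crosses a centromere, so probes are partitioned into p
#' and q arms first. Probes at positions `<=` the centromere coordinate are
#' labelled `"p"`, the rest `"q"`. In whole-chromosome mode no centromere
#' table is needed and every probe is labelled `"q"`.
#'
#' @param tab a copy number table.
#' @param centromeres `data.frame` with columns `chrom`, `centromere_pos`;
#'   default [hg19_centromeres()].
#' @param whole_chrom if `TRUE`, treat each chromosome as a single arm.
#' @return character vector of arm labels, one per probe.
#' @examples
#' tab <- cn_table(c(1, 1), c(500, 1500), c(0, 0))
#' assign_arms(tab, data.frame(chrom = "1", centromere_pos = 1000))
#' @export
assign_arms <- function(tab, centromeres = hg19_centromeres(),
                        whole_chrom = FALSE) {
  if (whole_chrom) return(rep("q", nrow(tab)))
  centromeres$chrom <- normalize_chrom(centromeres$chrom)
  idx <- match(tab$chrom, centromeres$chrom)
  if (anyNA(idx)) {
    stop("no centromere coordinate for chromosome ",
         tab$chrom[which(is.na(idx))[1]],
         "; supply one or use whole_chrom = TRUE")
  }
  ifelse(tab$pos <= centromeres$centromere_pos[idx], "p", "q")
}

# Iterate over (chrom, arm) blocks of a table in probe order; returns a list
# of integer row-index vectors named "chrom.arm".
#' @keywords internal
arm_blocks <- function(tab, arms) {
  key <- paste(tab$chrom, arms, sep = ".")
  split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
}

#' Write a segment table
#'
#' @param segments a segment `data.frame` as returned by [pcf()],
#'   [multipcf()] or [aspcf()].
#' @param sink output path or connection.
#' @param format `"native"` writes all columns as tab-separated text;
#'   `"seg"` writes the IGV SEG dialect (single-sample tables only:
#'   columns sample, chrom, start, end, num_mark, seg.mean).
#' @export
write_segments <- function(segments, sink, format = c("native", "seg")) {
  format <- match.arg(format)
  if (format == "seg") {
    if (!("sampleID" %in% names(segments)) || !("mean" %in% names(segments))) {
      stop("SEG export needs per-sample segments with a single 'mean' column")
    }
    out <- data.frame(sample = segments$sampleID,
                      chrom = segments$chrom,
                      start = segments$start.pos,
                      end = segments$end.pos,
                      num_mark = segments$n.probes,
                      seg.mean = segments$mean,
                      stringsAsFactors = FALSE)
    out <- out[order(out$sample, chrom_rank(out$chrom), out$start), ]
    utils::write.table(out, sink, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(segments, sink, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}

#' Read a native segment table written by [write_segments()]
#'
#' @param source path or connection.
#' @return segment `data.frame`.
#' @export
read_segments <- function(source) {
  seg <- utils::read.delim(source, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  seg$chrom <- normalize_chrom(seg$chrom)
  seg
}
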