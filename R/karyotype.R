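## Single-cell karyotype statistics on called copy-number matrices:
## bin-size-weighted aneuploidy score, pairwise-discordance heterogeneity
## score, and the library curation filters (algorithm concordance, read
## depth).  Copy-number calling itself is upstream; this module consumes
## integer call matrices over genomic bins.

#' Assemble a single-cell copy-number matrix
#'
#' @param bins data.frame with `chrom`, `start`, `end` (0-based half-open,
#'   bases); widths `end - start` must be positive.
#' @param calls integer matrix of copy-number calls, bins x libraries
#'   (complete, no missing cells).
#' @param expected_ploidy per-bin expected copy number when euploid
#'   (recycled; default 2).  Sex-chromosome conventions can be encoded here.
#' @param read_totals optional named numeric vector of total read counts per
#'   library (names matching `colnames(calls)`).
#' @return Object of class `cn_matrix`: list with `bins` (including `width`),
#'   `calls`, `expected_ploidy`, `read_totals`.
#' @export
cn_matrix <- function(bins, calls, expected_ploidy = 2, read_totals = NULL) {
  stopifnot(is.data.frame(bins), all(c("chrom", "start", "end") %in% names(bins)))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(bins))
    stop("calls must have one row per bin")
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("lib", seq_len(ncol(calls)))
  bins$width <- as.numeric(bins$end) - as.numeric(bins$start)
  if (any(bins$width <= 0)) stop("all bin widths must be positive")
  if (anyNA(calls) || any(calls < 0)) stop("calls must be complete and >= 0")
  expected_ploidy <- rep_len(as.numeric(expected_ploidy), nrow(bins))
  if (any(expected_ploidy <= 0)) stop("expected_ploidy must be positive")
  if (!is.null(read_totals)) {
    read_totals <- read_totals[colnames(calls)]
    if (anyNA(read_totals))
      stop("read_totals must cover every library")
  }
  structure(list(bins = bins, calls = calls,
                 expected_ploidy = expected_ploidy,
                 read_totals = read_totals),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("<cn_matrix> %d bins x %d libraries (%.1f Mb)\n",
              nrow(x$calls), ncol(x$calls), sum(x$bins$width) / 1e6))
  invisible(x)
}

#' Aneuploidy score
#'
#' Per bin, the absolute difference between the called copy number and the
#' expected euploid copy number; per library, the bin-size-weighted average
#' of those deviations; per sample, the unweighted mean over libraries.
#'
#' @param matrix a curated `cn_matrix`.
#' @return list with `per_library` (named vector) and `sample`.
#' @export
aneuploidy_score <- function(matrix) {
  if (ncol(matrix$calls) == 0L) stop("no libraries")
  w <- matrix$bins$width
  dev <- abs(matrix$calls - matrix$expected_ploidy)
  per_library <- colSums(dev * w) / sum(w)
  list(per_library = per_library, sample = mean(per_library))
}

#' Karyotype heterogeneity score
#'
#' Per bin, the proportion of library pairs whose calls differ (the
#' magnitude of the difference is ignored); per sample, the
#' bin-size-weighted average of the bin scores.
#'
#' @param matrix a curated `cn_matrix` with at least 2 libraries.
#' @return list with `per_bin` (vector of pairwise-discordance fractions)
#'   and `sample`.
#' @export
heterogeneity_score <- function(matrix) {
  n <- ncol(matrix$calls)
  if (n < 2L) stop("heterogeneity requires at least 2 libraries")
  npair <- n * (n - 1) / 2
  per_bin <- apply(matrix$calls, 1L, function(v) {
    cnt <- table(v)
    (npair - sum(cnt * (cnt - 1) / 2)) / npair
  })
  w <- matrix$bins$width
  list(per_bin = per_bin, sample = sum(per_bin * w) / sum(w))
}

#' Concordance between two call tracks of one library
#'
#' Fraction of the genome on which two segmentation algorithms called the
#' same copy number, weighted by bin size (an unweighted per-bin variant is
#' reported alongside); the library is kept when the weighted concordance
#' reaches the threshold.
#'
#' @param calls_a,calls_b integer call vectors over the same bins.
#' @param width bin widths in bases.
#' @param min_concordance keep threshold (default 0.90).
#' @return list with `concordance` (weighted), `concordance_unweighted`,
#'   `keep`.
#' @export
concordance_filter <- function(calls_a, calls_b, width,
                               min_concordance = 0.90) {
  if (length(calls_a) != length(calls_b) || length(calls_a) != length(width))
    stop("call tracks and widths must cover the same bins")
  same <- calls_a == calls_b
  conc <- sum(width[same]) / sum(width)
  list(concordance = conc, concordance_unweighted = mean(same),
       keep = conc >= min_concordance)
}

#' Read-depth library filter
#'
#' Keeps a library when its mean number of reads per bin and per chromosome
#' copy -- total reads divided by the summed copy number over all bins --
#' reaches the threshold.  A library whose calls are all zero is discarded
#' and flagged as degenerate.
#'
#' @param matrix a `cn_matrix` carrying `read_totals`.
#' @param min_reads_per_bin_per_copy threshold (default 10).
#' @return data.frame per library: `library_id`, `reads_per_bin_per_copy`,
#'   `keep`, `degenerate`.
#' @export
depth_filter <- function(matrix, min_reads_per_bin_per_copy = 10) {
  if (is.null(matrix$read_totals))
    stop("matrix carries no per-library read totals")
  copies <- colSums(matrix$calls)
  rate <- ifelse(copies > 0, matrix$read_totals / copies, NA_real_)
  data.frame(library_id = colnames(matrix$calls),
             reads_per_bin_per_copy = unname(rate),
             keep = !is.na(rate) & rate >= min_reads_per_bin_per_copy,
             degenerate = copies == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write copy-number matrices (TSV)
#'
#' The TSV has columns `chrom`, `start`, `end` followed by one integer
#' column per library; an optional sidecar CSV `library_id,total_reads`
#' supplies read totals.
#'
#' @param file path to the copy-number TSV.
#' @param reads_file optional path to the read-totals CSV.
#' @param expected_ploidy per-bin expected ploidy (default 2).
#' @return `read_cn_matrix`: a `cn_matrix`.
#' @export
read_cn_matrix <- function(file, reads_file = NULL, expected_ploidy = 2) {
  d <- read.csv(file, sep = "\t", check.names = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(d)))
  libs <- setdiff(names(d), c("chrom", "start", "end"))
  calls <- as.matrix(d[, libs, drop = FALSE])
  storage.mode(calls) <- "integer"
  read_totals <- NULL
  if (!is.null(reads_file)) {
    rt <- read.csv(reads_file)
    read_totals <- setNames(rt$total_reads, rt$library_id)
  }
  cn_matrix(d[, c("chrom", "start", "end")], calls,
            expected_ploidy = expected_ploidy, read_totals = read_totals)
}

#' @rdname read_cn_matrix
#' @param matrix a `cn_matrix`.
#' @return `write_cn_matrix`: `file`, invisibly.
#' @export
write_cn_matrix <- function(matrix, file) {
  d <- data.frame(chrom = matrix$bins$chrom,
                  start = format(matrix$bins$start, trim = TRUE,
                                 scientific = FALSE),
                  end = format(matrix$bins$end, trim = TRUE,
                               scientific = FALSE),
                  matrix$calls, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(file)
}
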