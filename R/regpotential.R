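#' Read ChIP-seq peak intervals from BED
#'
#' Thin wrapper around `rtracklayer::import` for BED3+ files (0-based
#' half-open input coordinates).
#'
#' @param path Path to a BED file.
#' @return A `GRanges` of peak intervals.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop_io("peak file not found: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Read a gene TSS annotation table
#'
#' @param path TSV `gene<TAB>chrom<TAB>tss<TAB>strand`, no header.
#' @return Data frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) stop_io("TSS annotation not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop_io("TSS annotation needs gene, chrom, tss, strand columns")
  names(tab)[1:4] <- c("gene", "chrom", "tss", "strand")
  validate_tss(tab[1:4])
}

validate_tss <- function(genes) {
  if (!is.data.frame(genes) || !all(c("gene", "chrom", "tss") %in% names(genes))) {
    stop_validation("gene annotation must have gene, chrom, tss[, strand] columns")
  }
  if (!nrow(genes)) stop_validation("gene annotation is empty")
  if (anyDuplicated(genes$gene)) {
    stop_validation("one TSS per gene required (pick a canonical transcript upstream)")
  }
  genes$tss <- as.numeric(genes$tss)
  if (anyNA(genes$tss)) stop_validation("non-numeric TSS positions")
  if (is.null(genes$strand)) genes$strand <- "+"
  if (!all(genes$strand %in% c("+", "-"))) {
    stop_validation("strand must be '+' or '-'")
  }
  genes
}

# Peak centers on the 0-based coordinate axis, per input flavour.
peak_centers <- function(peaks) {
  if (methods::is(peaks, "GRanges")) {
    # GRanges is 1-based closed; recover the 0-based half-open midpoint
    data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
               center = (GenomicRanges::start(peaks) - 1 +
                           GenomicRanges::end(peaks)) / 2,
               stringsAsFactors = FALSE)
  } else if (is.data.frame(peaks) &&
             all(c("chrom", "start", "end") %in% names(peaks))) {
    if (any(peaks$start >= peaks$end)) {
      stop_validation("peak intervals must satisfy start < end (0-based half-open)")
    }
    data.frame(chrom = as.character(peaks$chrom),
               center = (peaks$start + peaks$end) / 2,
               stringsAsFactors = FALSE)
  } else {
    stop_validation("peaks must be a GRanges or a data frame with chrom, start, end")
  }
}

#' Regulatory potential of ChIP-seq peaks on gene promoters
#'
#' Summarises a factor's or histone mark's regulatory impact on each gene
#' as a distance-weighted sum of binding sites around the TSS:
#' `RP(g) = sum over peaks within the window of 2^(-d / d0)`, where `d` is
#' the distance in bases between the peak center (interval midpoint) and
#' the TSS, and `d0 = decay_kb * 1000` is the half-decay distance. A peak
#' centered at the TSS contributes 1, one at `decay_kb` contributes 1/2,
#' and peaks beyond `window_kb` contribute nothing. The window is
#' symmetric; strand does not affect the distance.
#'
#' @param peaks Peak intervals: a `GRanges` (e.g. from [read_peaks()]) or a
#'   data frame with 0-based half-open `chrom`, `start`, `end`.
#' @param genes Gene annotation data frame with `gene`, `chrom`, `tss`
#'   (and optionally `strand`) columns, e.g. from [read_tss()].
#' @param decay_kb Half-decay distance in kb (default 10).
#' @param window_kb Maximum TSS distance in kb considered (default 100).
#' @return Named numeric vector of RP scores, one per annotated gene
#'   (0 when no peak falls in the window).
#' @export
regulatory_potential <- function(peaks, genes, decay_kb = 10, window_kb = 100) {
  genes <- validate_tss(genes)
  assert_scalar_number(decay_kb, "decay_kb", lower = 0, strict_lower = TRUE)
  assert_scalar_number(window_kb, "window_kb", lower = 0, strict_lower = TRUE)
  ctr <- peak_centers(peaks)
  rp <- stats::setNames(numeric(nrow(genes)), genes$gene)
  if (!nrow(ctr)) return(rp)
  window <- window_kb * 1000
  d0 <- decay_kb * 1000
  by_chrom <- split(ctr$center, ctr$chrom)
  for (i in seq_len(nrow(genes))) {
    centers <- by_chrom[[genes$chrom[i]]]
    if (is.null(centers)) next
    d <- abs(centers - genes$tss[i])
    d <- d[d <= window]
    if (length(d)) rp[i] <- sum(2^(-d / d0))
  }
  rp
}

#' Center regulatory-potential profiles across samples
#'
#' RP profiles over several cell lines are normalised exactly like
#' expression: each gene's mean across the profiled samples is subtracted.
#' Delegates to [center_values()].
#'
#' @param m Numeric gene x sample matrix of RP scores.
#' @return Centered matrix.
#' @export
center_rp <- function(m) center_values(m)
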