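#' Center a gene-by-sample value matrix across samples
#'
#' Subtracts each gene's across-sample mean from its row, the normalisation
#' applied to expression cohorts (and to regulatory-potential profiles)
#' before neighbor scoring. With a single sample every value equals its own
#' mean, so the output is all zeros. Missing entries are excluded from the
#' mean and remain missing.
#'
#' @param m Numeric matrix, genes in rows (rownames required), samples in
#'   columns.
#' @return A matrix of the same dimensions with row means removed.
#' @examples
#' m <- matrix(1:6, 2, dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' center_values(m)
#' @export
center_values <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_validation("m must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop_validation("m must have unique gene rownames")
  }
  if (ncol(m) < 1L) stop_validation("m needs at least one sample column")
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " gene(s) have no observed values and stay missing",
            call. = FALSE)
  }
  mu <- rowMeans(m, na.rm = TRUE)
  mu[all_missing] <- 0  # leave all-NA rows untouched (still all NA)
  m - mu
}

#' Read a gene-by-sample value matrix TSV
#'
#' First column gene identifier, header row of sample names; empty cells or
#' `NA` are treated as missing.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene rownames.
#' @export
read_value_matrix <- function(path) {
  if (!file.exists(path)) stop_io("value matrix not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = c("character"), na.strings = c("", "NA"))
  if (ncol(tab) < 2L) stop_io("value matrix needs a gene column plus >=1 sample")
  genes <- tab[[1L]]
  if (anyDuplicated(genes)) stop_validation("duplicate gene identifiers in ", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(is.infinite(m), na.rm = TRUE)) {
    stop_validation("value matrix contains non-finite entries")
  }
  m
}

#' Read a two-column gene/value table
#'
#' MAGeCK-style per-gene summary: `gene<TAB>value`, no header by default.
#'
#' @param path Path to the TSV.
#' @param header If `TRUE`, skip one header line.
#' @return Named numeric vector.
#' @export
read_gene_values <- function(path, header = FALSE) {
  if (!file.exists(path)) stop_io("gene value table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = header, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_io("gene value table needs two tab-separated columns")
  as_gene_values(data.frame(gene = as.character(tab[[1L]]),
                            value = as.numeric(tab[[2L]])))
}

# Align a gene -> value mapping onto the node order of a network.
# Returns the zero-filled value vector, the observed mask, and any genes
# present in `values` but absent from the network.
align_values <- function(net, values) {
  values <- as_gene_values(values)
  values <- values[!is.na(values)]
  idx <- match(names(values), net$nodes)
  if (all(is.na(idx))) {
    stop_validation("no overlap between value genes and network nodes")
  }
  v <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  has <- stats::setNames(logical(length(net$nodes)), net$nodes)
  inside <- !is.na(idx)
  v[idx[inside]] <- values[inside]
  has[idx[inside]] <- TRUE
  list(v = v, has = has, extra_genes = names(values)[!inside])
}

#' Neighbor-sum (NEST) scores for one value vector
#'
#' For every network node g the score is the confidence-weighted sum of its
#' neighbors' values, `score(g) = sum_n w(g, n) * v(n)` — equivalently the
#' connectivity matrix applied to the value vector. A gene's own value never
#' enters its own score. Isolated nodes score 0.
#'
#' Neighbors without an observed value contribute 0 under either missing
#' policy (after mean-centering, 0 is the neutral "average" value);
#' `"exclude"` additionally records per-gene counts of observed neighbors so
#' sparse coverage can be flagged downstream. Genes present in `values` but
#' absent from the network are reported with a missing score so that
#' rankings can exclude them.
#'
#' @param net A [gene_network].
#' @param values Gene -> value mapping: named numeric vector, two-column
#'   data frame, or one-column matrix with rownames.
#' @param missing_policy `"zero"` (default) or `"exclude"`.
#' @return A data frame (`gene`, `score`, and `n_observed_neighbors` under
#'   `"exclude"`) of class `nest_score_table`, network nodes first.
#' @examples
#' net <- gene_network(data.frame(from = c("A", "A", "B"),
#'                                to   = c("B", "C", "C"),
#'                                weight = c(0.5, 1, 0.2)))
#' nest_scores(net, c(A = 1, B = 2, C = -1))
#' @export
nest_scores <- function(net, values, missing_policy = c("zero", "exclude")) {
  stopifnot(inherits(net, "gene_network"))
  missing_policy <- match.arg(missing_policy)
  if (!length(net$nodes)) stop_validation("network has no nodes")
  al <- align_values(net, values)
  A <- as_adjacency(net)
  score <- as.numeric(A %*% al$v)
  out <- data.frame(gene = net$nodes, score = score, stringsAsFactors = FALSE)
  if (missing_policy == "exclude") {
    out$n_observed_neighbors <- as.integer(as.numeric((A != 0) %*% al$has))
  }
  if (length(al$extra_genes)) {
    extra <- data.frame(gene = al$extra_genes, score = NA_real_,
                        stringsAsFactors = FALSE)
    if (missing_policy == "exclude") extra$n_observed_neighbors <- NA_integer_
    out <- rbind(out, extra)
  }
  attr(out, "missing_policy") <- missing_policy
  class(out) <- c("nest_score_table", "data.frame")
  out
}

#' Neighbor-sum scores for every sample of a value matrix
#'
#' Computes per-sample scores as a single sparse connectivity-matrix product
#' with the (typically centered) value matrix; each column agrees with
#' [nest_scores()] applied to that sample.
#'
#' @param net A [gene_network].
#' @param m Numeric gene x sample matrix with rownames.
#' @param missing_policy Passed to the per-sample tables (see
#'   [nest_scores()]).
#' @return Named list of `nest_score_table` data frames, one per sample.
#' @export
nest_scores_matrix <- function(net, m, missing_policy = c("zero", "exclude")) {
  stopifnot(inherits(net, "gene_network"))
  missing_policy <- match.arg(missing_policy)
  if (!is.matrix(m) || is.null(rownames(m))) {
    stop_validation("m must be a numeric matrix with gene rownames")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("sample", seq_len(ncol(m)))
  idx <- match(rownames(m), net$nodes)
  if (all(is.na(idx))) {
    stop_validation("no overlap between value genes and network nodes")
  }
  n <- length(net$nodes)
  V <- matrix(0, n, ncol(m), dimnames = list(net$nodes, colnames(m)))
  has <- matrix(FALSE, n, ncol(m), dimnames = list(net$nodes, colnames(m)))
  inside <- !is.na(idx)
  vals <- m[inside, , drop = FALSE]
  vals_obs <- !is.na(vals)
  vals[!vals_obs] <- 0
  V[idx[inside], ] <- vals
  has[idx[inside], ] <- vals_obs
  A <- as_adjacency(net)
  S <- as.matrix(A %*% V)
  extra_genes <- rownames(m)[!inside]
  cover <- if (missing_policy == "exclude") as.matrix((A != 0) %*% has) else NULL
  out <- lapply(colnames(m), function(s) {
    tab <- data.frame(gene = net$nodes, score = S[, s], stringsAsFactors = FALSE)
    if (!is.null(cover)) tab$n_observed_neighbors <- as.integer(cover[, s])
    if (length(extra_genes)) {
      extra <- data.frame(gene = extra_genes, score = NA_real_,
                          stringsAsFactors = FALSE)
      if (!is.null(cover)) extra$n_observed_neighbors <- NA_integer_
      tab <- rbind(tab, extra)
    }
    attr(tab, "missing_policy") <- missing_policy
    attr(tab, "sample") <- s
    class(tab) <- c("nest_score_table", "data.frame")
    rownames(tab) <- NULL
    tab
  })
  stats::setNames(out, colnames(m))
}

#' Convert scores to ascending rank percentiles
#'
#' Adds a `rank_percentile` column: the fractional ascending rank (average
#' rank on ties) divided by the number of scored genes, so values lie in
#' (0, 1], a unique maximum maps to exactly 1, and highly ranked (more
#' essential) genes sit near 1. Genes with a missing score keep a missing
#' percentile and do not count towards N.
#'
#' @param scores A `nest_score_table` from [nest_scores()], or any data
#'   frame with `gene` and `score` columns.
#' @return The input with a `rank_percentile` column appended.
#' @export
rank_percentile <- function(scores) {
  if (!is.data.frame(scores) || !all(c("gene", "score") %in% names(scores))) {
    stop_validation("scores must have gene and score columns")
  }
  obs <- !is.na(scores$score)
  if (!any(obs)) stop_validation("no non-missing scores to rank")
  pct <- rep(NA_real_, nrow(scores))
  pct[obs] <- rank(scores$score[obs], ties.method = "average") / sum(obs)
  scores$rank_percentile <- pct
  scores
}

#' Write a score table as TSV
#'
#' @param scores A `nest_score_table` (optionally with percentiles).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
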