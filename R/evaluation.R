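#' Gold-standard gene sets for evaluation
#'
#' @param positives Character vector of positive genes (e.g. negatively
#'   selected screen hits at FDR 0.05).
#' @param negatives Character vector of negative genes; must be disjoint
#'   from `positives`.
#' @return A list of class `gold_standard`.
#' @export
gold_standard <- function(positives, negatives) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (!length(positives) || !length(negatives)) {
    stop_validation("both positive and negative sets must be non-empty")
  }
  if (length(intersect(positives, negatives))) {
    stop_validation("positive and negative sets must be disjoint")
  }
  structure(list(positives = positives, negatives = negatives),
            class = "gold_standard")
}

#' Equal-sized bottom-ranked negative control set
#'
#' Mirrors the screen convention of matching the positives with the same
#' number of genes from the bottom of the ranking.
#'
#' @param ranking Named numeric vector used to rank genes (higher = more
#'   hit-like); typically the original screen statistic.
#' @param positives Positive gene set to exclude and size-match.
#' @param n Number of negatives; defaults to `length(positives)`.
#' @return Character vector of negative genes.
#' @export
auto_negatives <- function(ranking, positives, n = NULL) {
  ranking <- as_gene_values(ranking, "ranking")
  pool <- setdiff(names(sort(ranking, decreasing = FALSE)), positives)
  n <- n %||% length(unique(positives))
  if (n > length(pool)) {
    stop_validation("not enough genes outside the positive set for ", n,
                    " negatives")
  }
  pool[seq_len(n)]
}

# Shared preparation: named score vector restricted to gold-standard genes.
prepare_gold_scores <- function(scores, gold) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$gene)
  }
  scores <- scores[!is.na(scores)]
  scores <- as_gene_values(scores, "scores")
  pos <- intersect(gold$positives, names(scores))
  neg <- intersect(gold$negatives, names(scores))
  dropped <- length(gold$positives) + length(gold$negatives) -
    length(pos) - length(neg)
  if (dropped > 0L) message(dropped, " gold-standard gene(s) without scores excluded")
  if (!length(pos) || !length(neg)) {
    stop_validation("gold standard has no scored positives or no scored negatives")
  }
  list(pos = scores[pos], neg = scores[neg])
}

#' ROC curve and AUC for a gene ranking
#'
#' Ranks genes by descending score against a gold standard. The AUC is the
#' tie-aware Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counting 1/2 — identical to trapezoidal integration of the ROC curve.
#'
#' @param scores Named numeric vector or a score table with `gene` and
#'   `score` columns. Genes without a score are excluded with a message.
#' @param gold A [gold_standard].
#' @return List of class `roc_result` with `fpr`, `tpr` (threshold-ordered,
#'   starting at 0,0 and ending at 1,1), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, gold) {
  gs <- prepare_gold_scores(scores, gold)
  x <- c(gs$pos, gs$neg)
  lab <- rep(c(1L, 0L), c(length(gs$pos), length(gs$neg)))
  n1 <- length(gs$pos); n0 <- length(gs$neg)
  r <- rank(x, ties.method = "average")
  auc <- (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # threshold sweep, descending score, tied scores grouped
  ord <- order(x, decreasing = TRUE)
  lab_o <- lab[ord]
  x_o <- x[ord]
  grp_end <- cumsum(rle(x_o)$lengths)
  tpr <- c(0, cumsum(lab_o)[grp_end] / n1)
  fpr <- c(0, cumsum(1L - lab_o)[grp_end] / n0)
  structure(list(fpr = fpr, tpr = tpr, auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Wilcoxon rank-sum Z for positives versus negatives
#'
#' Normal-approximation Z of the two-sample Wilcoxon rank-sum statistic
#' with tie correction and a 1/2 continuity correction. Positive Z means
#' positives rank higher than negatives; swapping the labels flips the
#' sign. This is the specificity statistic used to ask which expression
#' profile best predicts a given screen.
#'
#' @inheritParams roc_auc
#' @return A single numeric Z value.
#' @export
rank_sum_z <- function(scores, gold) {
  gs <- prepare_gold_scores(scores, gold)
  x <- c(gs$pos, gs$neg)
  n1 <- length(gs$pos); n0 <- length(gs$neg); n <- n1 + n0
  r <- rank(x, ties.method = "average")
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(0)
  d <- W - mu
  cc <- 0.5 * sign(d)
  d_cc <- d - cc
  if (sign(d_cc) != sign(d) && d != 0) d_cc <- 0  # don't overshoot zero
  d_cc / sqrt(sigma2)
}

#' Multivariate logistic confounder analysis
#'
#' Fits a maximum-likelihood logistic regression of a binary essentiality
#' outcome on several per-gene covariates (typically neighbor score,
#' network degree, and the gene's own expression) over complete cases, and
#' reports each covariate's coefficient, standard error, Logit Z
#' (coefficient / standard error), and Wald p-value. The fitted
#' probabilities are attached so the combined predictor can be compared
#' against single covariates.
#'
#' @param outcome Named binary (0/1 or logical) vector keyed by gene.
#' @param covariates Named list of gene -> value mappings, one per
#'   covariate.
#' @return Data frame of class `logit_table` (`covariate`, `coefficient`,
#'   `std_error`, `z`, `p`) excluding the intercept, with attributes
#'   `fitted` (named probabilities) and `n` (genes used). Errors on a
#'   constant covariate or perfect separation.
#' @export
logistic_confounder_test <- function(outcome, covariates) {
  if (is.logical(outcome)) outcome <- as.numeric(outcome)
  outcome <- as_gene_values(outcome, "outcome")
  if (!all(outcome %in% c(0, 1))) {
    stop_validation("outcome must be binary (0/1)")
  }
  if (!is.list(covariates) || is.null(names(covariates)) ||
      any(names(covariates) == "")) {
    stop_validation("covariates must be a named list of gene -> value mappings")
  }
  covs <- lapply(covariates, as_gene_values, arg = "covariate")
  genes <- Reduce(intersect, c(list(names(outcome)), lapply(covs, names)))
  df <- data.frame(.outcome = outcome[genes],
                   lapply(covs, function(v) unname(v[genes])),
                   check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(covs) + 2L) {
    stop_validation("too few complete cases for logistic regression")
  }
  if (length(unique(df$.outcome)) < 2L) {
    stop_validation("outcome is constant over complete cases")
  }
  constant <- vapply(df[-1L], function(v) stats::sd(v) == 0, logical(1L))
  if (any(constant)) {
    stop_validation("covariate(s) constant across genes: ",
                    paste(names(df[-1L])[constant], collapse = ", "))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.outcome ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  mu <- stats::fitted(fit)
  if (separated || !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)) {
    stop_validation(
      "logistic fit unreliable: perfect (or quasi-perfect) separation detected")
  }
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  out <- data.frame(covariate = sub("^`|`$", "", rownames(sm)[keep]),
                    coefficient = sm[keep, "Estimate"],
                    std_error = sm[keep, "Std. Error"],
                    z = sm[keep, "Estimate"] / sm[keep, "Std. Error"],
                    p = sm[keep, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fitted") <- stats::setNames(stats::fitted(fit), rownames(df))
  attr(out, "n") <- nrow(df)
  class(out) <- c("logit_table", "data.frame")
  out
}

#' Add Gaussian white noise to per-gene values
#'
#' Injects i.i.d. normal noise with standard deviation
#' `level * sd(values)`: the sample standard deviation of all input values
#' is the base noise level, and `level` scales relative to it. `level = 0`
#' returns the input unchanged.
#'
#' @param values Named numeric vector of per-gene values (>= 2 genes).
#' @param level Non-negative noise level relative to the base level.
#' @param seed Integer seed; the same seed and level reproduce the output.
#' @return Named numeric vector of the same length.
#' @export
inject_noise <- function(values, level, seed) {
  values <- as_gene_values(values)
  if (length(values) < 2L) stop_validation("need >= 2 values to set a base noise level")
  assert_scalar_number(level, "level", lower = 0)
  if (level == 0) return(values)
  base_sd <- stats::sd(values)
  with_seed(seed, values + stats::rnorm(length(values), 0, level * base_sd))
}

#' Noise-degradation experiment: raw values versus neighbor scores
#'
#' Repeatedly perturbs the per-gene values with Gaussian white noise at
#' each requested level, then measures how the gold-standard AUC of (a) the
#' noisy raw values and (b) neighbor scores recomputed from the noisy
#' values decays relative to each predictor's own noise-free AUC. The
#' reduction ratio at a level is `(AUC0 - AUC_level) / AUC0`; a robust
#' predictor keeps this small as noise grows.
#'
#' @param net A [gene_network].
#' @param values Named numeric gene -> value vector (e.g. screen fold
#'   changes).
#' @param gold A [gold_standard].
#' @param levels Non-negative noise levels relative to `sd(values)`.
#' @param n_reps Noise replicates per level.
#' @param seed Integer base seed; replicate seeds are derived
#'   deterministically from it.
#' @return Data frame `level`, `predictor` (`"raw"` or `"nest"`),
#'   `mean_auc`, `mean_reduction_ratio`, `sd_reduction_ratio`, `n_reps`.
#' @export
degradation_experiment <- function(net, values, gold,
                                   levels = c(0.25, 0.5, 1, 2, 4),
                                   n_reps = 20L, seed = 1L) {
  stopifnot(inherits(net, "gene_network"), inherits(gold, "gold_standard"))
  values <- as_gene_values(values)
  if (any(levels < 0)) stop_validation("noise levels must be non-negative")
  assert_scalar_number(n_reps, "n_reps", lower = 1)
  auc0_raw <- roc_auc(values, gold)$auc
  auc0_nest <- roc_auc(nest_scores(net, values), gold)$auc
  rows <- list()
  for (li in seq_along(levels)) {
    lev <- levels[li]
    auc_raw <- auc_nest <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      noisy <- inject_noise(values, lev,
                            seed = seed + (li - 1L) * n_reps + (r - 1L))
      auc_raw[r] <- roc_auc(noisy, gold)$auc
      auc_nest[r] <- roc_auc(nest_scores(net, noisy), gold)$auc
    }
    red_raw <- (auc0_raw - auc_raw) / auc0_raw
    red_nest <- (auc0_nest - auc_nest) / auc0_nest
    rows[[length(rows) + 1L]] <- data.frame(
      level = lev, predictor = c("raw", "nest"),
      mean_auc = c(mean(auc_raw), mean(auc_nest)),
      mean_reduction_ratio = c(mean(red_raw), mean(red_nest)),
      sd_reduction_ratio = c(stats::sd(red_raw), stats::sd(red_nest)),
      n_reps = as.integer(n_reps), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "auc0") <- c(raw = auc0_raw, nest = auc0_nest)
  out
}
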