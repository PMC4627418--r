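#' Specification for a synthetic planted-module benchmark
#'
#' Describes a sparse background interaction network containing dense
#' "complex" modules, a subset of which are active: their member genes
#' carry an elevated mean value on top of Gaussian noise. This emulates the
#' structure the neighbor-scoring model exploits — essential genes sitting
#' in active, densely connected protein complexes — while keeping module
#' membership independent of degree so confounder analyses have a clean
#' null.
#'
#' Default weights mimic a STRING-like confidence split: high-confidence
#' intra-complex edges (0.9) over a low-confidence background (0.2).
#'
#' @param n_genes Total number of genes.
#' @param background_edge_prob Edge probability for between-module and
#'   background pairs.
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module (`n_modules * module_size <=
#'   n_genes`).
#' @param intra_module_edge_prob Edge probability within a module; must
#'   exceed `background_edge_prob`.
#' @param intra_module_weight Confidence weight on intra-module edges.
#' @param background_weight Confidence weight on background edges.
#' @param active_fraction Fraction of modules that are active.
#' @param effect_size Mean value shift of genes in active modules.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param n_samples Number of value-matrix samples.
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 500L, background_edge_prob = 0.01,
                           n_modules = 10L, module_size = 10L,
                           intra_module_edge_prob = 0.6,
                           intra_module_weight = 0.9,
                           background_weight = 0.2,
                           active_fraction = 0.3, effect_size = 1,
                           noise_sd = 1, n_samples = 1L, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               background_edge_prob = background_edge_prob,
               n_modules = as.integer(n_modules),
               module_size = as.integer(module_size),
               intra_module_edge_prob = intra_module_edge_prob,
               intra_module_weight = intra_module_weight,
               background_weight = background_weight,
               active_fraction = active_fraction,
               effect_size = effect_size, noise_sd = noise_sd,
               n_samples = as.integer(n_samples), seed = as.integer(seed))
  assert_scalar_number(spec$n_genes, "n_genes", lower = 2)
  assert_scalar_number(spec$background_edge_prob, "background_edge_prob",
                       lower = 0, upper = 1)
  assert_scalar_number(spec$n_modules, "n_modules", lower = 0)
  assert_scalar_number(spec$module_size, "module_size", lower = 1)
  assert_scalar_number(spec$intra_module_edge_prob, "intra_module_edge_prob",
                       lower = 0, upper = 1)
  assert_scalar_number(spec$intra_module_weight, "intra_module_weight",
                       lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(spec$background_weight, "background_weight",
                       lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(spec$active_fraction, "active_fraction",
                       lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(spec$effect_size, "effect_size")
  assert_scalar_number(spec$noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(spec$n_samples, "n_samples", lower = 1)
  assert_scalar_number(spec$seed, "seed")
  if (spec$n_modules * spec$module_size > spec$n_genes) {
    stop_validation("n_modules * module_size must not exceed n_genes")
  }
  if (spec$n_modules > 0L &&
      spec$intra_module_edge_prob <= spec$background_edge_prob) {
    stop_validation("intra_module_edge_prob must exceed background_edge_prob")
  }
  structure(spec, class = "synthetic_spec")
}

synthetic_gene_names <- function(n) sprintf("g%04d", seq_len(n))

# Module id per gene: modules fill the first n_modules*module_size genes,
# 0 marks background.
module_assignment <- function(spec) {
  lab <- integer(spec$n_genes)
  if (spec$n_modules > 0L) {
    lab[seq_len(spec$n_modules * spec$module_size)] <-
      rep(seq_len(spec$n_modules), each = spec$module_size)
  }
  stats::setNames(lab, synthetic_gene_names(spec$n_genes))
}

#' Generate a planted-module network
#'
#' Samples each within-module gene pair independently with
#' `intra_module_edge_prob` (weight `intra_module_weight`) and every other
#' pair with `background_edge_prob` (weight `background_weight`). Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec].
#' @return List with `network` (a [gene_network] over all genes) and
#'   `module_labels` (named integer vector; 0 = background).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_genes
  genes <- synthetic_gene_names(n)
  lab <- module_assignment(spec)
  # upper-triangle pair enumeration
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  same <- lab[i] > 0L & lab[i] == lab[j]
  p <- ifelse(same, spec$intra_module_edge_prob, spec$background_edge_prob)
  keep <- with_seed(spec$seed, stats::runif(length(p)) < p)
  w <- ifelse(same[keep], spec$intra_module_weight, spec$background_weight)
  net <- gene_network(data.frame(from = genes[i[keep]], to = genes[j[keep]],
                                 weight = w, stringsAsFactors = FALSE),
                      nodes = genes)
  list(network = net, module_labels = lab)
}

#' Choose which planted modules are active
#'
#' Samples `round(active_fraction * n_modules)` module ids (at least 1 when
#' any module exists) uniformly without replacement, deterministically from
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec].
#' @return Integer vector of active module ids (empty when `n_modules` is
#'   0).
#' @export
choose_active_modules <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_modules == 0L) return(integer(0))
  k <- max(1L, round(spec$active_fraction * spec$n_modules))
  sort(with_seed(spec$seed + 1L, sample(spec$n_modules, k)))
}

#' Generate a value matrix with elevated active-module means
#'
#' Per sample, each gene's value is
#' `effect_size * 1[gene in an active module] + N(0, noise_sd)`. Values are
#' generated pre-centered: the background mean is 0, so they are ready for
#' neighbor scoring without a further centering step.
#'
#' @param labels Module labels from [generate_network()].
#' @param active_modules Integer vector of active module ids.
#' @param spec A [synthetic_spec].
#' @return List with `values` (gene x sample matrix) and `truth_positives`
#'   (genes of active modules).
#' @export
generate_values <- function(labels, active_modules, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- names(labels)
  active <- labels %in% active_modules & labels > 0L
  m <- with_seed(spec$seed + 2L, {
    noise <- matrix(stats::rnorm(length(genes) * spec$n_samples, 0, spec$noise_sd),
                    length(genes), spec$n_samples)
    spec$effect_size * active + noise
  })
  dimnames(m) <- list(genes, sprintf("s%d", seq_len(spec$n_samples)))
  list(values = m, truth_positives = genes[active])
}

#' Generate a synthetic screen fold-change vector
#'
#' Emulates a selection screen with hits in both directions: genes of
#' "protective" active modules get `+effect_size`, genes of "sensitizing"
#' active modules get `-effect_size`, background genes 0, all plus
#' `N(0, noise_sd)` noise. Active modules alternate
#' protective/sensitizing in id order (odd positions protective).
#'
#' @inheritParams generate_values
#' @return List with `values` (named vector), `truth_protective`, and
#'   `truth_sensitizing` gene sets.
#' @export
generate_screen <- function(labels, active_modules, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- names(labels)
  active_modules <- sort(active_modules)
  protective <- active_modules[seq_along(active_modules) %% 2L == 1L]
  sensitizing <- setdiff(active_modules, protective)
  sign <- numeric(length(genes))
  sign[labels %in% protective & labels > 0L] <- 1
  sign[labels %in% sensitizing & labels > 0L] <- -1
  v <- with_seed(spec$seed + 3L,
                 sign * spec$effect_size +
                   stats::rnorm(length(genes), 0, spec$noise_sd))
  list(values = stats::setNames(v, genes),
       truth_protective = genes[sign > 0],
       truth_sensitizing = genes[sign < 0])
}

#' Generate a complete synthetic benchmark dataset
#'
#' Bundles [generate_network()], [choose_active_modules()],
#' [generate_values()], and [generate_screen()] into the offline test
#' substrate: network, module labels, active modules, value matrix, screen
#' vector, and ground-truth gene sets. Pure function of the spec.
#'
#' @param spec A [synthetic_spec].
#' @return A list of class `synthetic_dataset`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nw <- generate_network(spec)
  active <- choose_active_modules(spec)
  vals <- generate_values(nw$module_labels, active, spec)
  scr <- generate_screen(nw$module_labels, active, spec)
  structure(list(network = nw$network, module_labels = nw$module_labels,
                 active_modules = active, values = vals$values,
                 truth_positives = vals$truth_positives,
                 screen = scr$values,
                 truth_protective = scr$truth_protective,
                 truth_sensitizing = scr$truth_sensitizing,
                 spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d genes, %d edges, %d/%d modules ",
                     "active, %d truth positives\n"),
              length(x$network$nodes), edge_count(x$network),
              length(x$active_modules), x$spec$n_modules,
              length(x$truth_positives)))
  invisible(x)
}
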