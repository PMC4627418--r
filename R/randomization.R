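#' Configuration for network randomization
#'
#' @param n_random Number of random networks for the permutation test
#'   (default 1000, matching the published protocol).
#' @param seed Base integer seed; replicate r uses `seed + r` so results do
#'   not depend on execution order. Keep `seed + n_random` below 2^31.
#' @param min_reconnect_fraction A rewiring attempt is accepted once at
#'   least this fraction of the original edges has been placed and no
#'   further legal pairing exists (default 0.98: rewiring restarts until
#'   98% of edges are reconnected).
#' @param max_restarts Restarts allowed before giving up (default 100).
#' @return A list of class `randomization_config`.
#' @export
randomization_config <- function(n_random = 1000L, seed = 1L,
                                 min_reconnect_fraction = 0.98,
                                 max_restarts = 100L) {
  assert_scalar_number(n_random, "n_random", lower = 1)
  assert_scalar_number(seed, "seed")
  assert_scalar_number(min_reconnect_fraction, "min_reconnect_fraction",
                       lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(max_restarts, "max_restarts", lower = 1)
  structure(list(n_random = as.integer(n_random), seed = as.integer(seed),
                 min_reconnect_fraction = min_reconnect_fraction,
                 max_restarts = as.integer(max_restarts)),
            class = "randomization_config")
}

#' Degree-preserving stub rewiring
#'
#' Randomizes the unweighted topology of a network while preserving every
#' node's degree. Each edge is cut into two stubs attached to its
#' endpoints; stubs are then re-paired uniformly at random, rejecting
#' pairings that would create a self-loop or a duplicate edge. Because
#' rejections can leave the process stuck with only illegal pairings, the
#' whole pass restarts from scratch until at least
#' `min_reconnect_fraction` of the original edges are reconnected; any
#' unplaceable stubs are then discarded. All edges of the rewired network
#' carry weight 1: the null model randomizes the unweighted network even
#' though real scores use the true confidence weights.
#'
#' @param net A [gene_network] with at least 2 edges.
#' @param seed Integer seed; the same seed always yields the same rewiring.
#' @param cfg A [randomization_config] (only `min_reconnect_fraction` and
#'   `max_restarts` are used).
#' @return A [gene_network] on the same node set, all weights 1.
#' @export
stub_rewire <- function(net, seed, cfg = randomization_config()) {
  stopifnot(inherits(net, "gene_network"))
  m <- nrow(net$edges)
  if (m < 2L) stop_validation("stub rewiring needs a network with >= 2 edges")
  n <- length(net$nodes)
  deg <- unname(network_degree(net))
  all_stubs <- rep.int(seq_len(n), deg)
  with_seed(seed, {
    best_fraction <- 0
    for (restart in seq_len(cfg$max_restarts)) {
      res <- rewire_pass(all_stubs, n)
      frac <- length(res$i) / m
      best_fraction <- max(best_fraction, frac)
      if (frac >= cfg$min_reconnect_fraction) {
        edges <- data.frame(from = net$nodes[res$i], to = net$nodes[res$j],
                            weight = 1, stringsAsFactors = FALSE)
        out <- gene_network(edges, nodes = net$nodes)
        attr(out, "placed_fraction") <- frac
        attr(out, "restarts") <- restart - 1L
        return(out)
      }
    }
    stop_validation(sprintf(
      "stub rewiring failed after %d restarts (best fraction placed: %.3f < %.3f)",
      cfg$max_restarts, best_fraction, cfg$min_reconnect_fraction))
  })
}

# One rewiring pass: repeatedly shuffle the remaining stubs, pair them
# consecutively, and keep the legal pairs. A pass is stalled -- no further
# legal pairing assumed to exist -- when several consecutive full sweeps
# place nothing.
rewire_pass <- function(stubs, n, max_stalled_sweeps = 10L) {
  placed_i <- integer(0)
  placed_j <- integer(0)
  placed_keys <- numeric(0)
  stalled <- 0L
  while (length(stubs) >= 2L && stalled < max_stalled_sweeps) {
    s <- sample(stubs)
    half <- length(s) %/% 2L
    a <- s[2L * seq_len(half) - 1L]
    b <- s[2L * seq_len(half)]
    leftover <- if (length(s) %% 2L) s[length(s)] else integer(0)
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- (lo - 1) * n + hi  # unique id per unordered pair (double-safe)
    legal <- lo != hi & !duplicated(key) & !(key %in% placed_keys)
    if (any(legal)) {
      placed_i <- c(placed_i, lo[legal])
      placed_j <- c(placed_j, hi[legal])
      placed_keys <- c(placed_keys, key[legal])
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
    }
    stubs <- c(a[!legal], b[!legal], leftover)
  }
  list(i = placed_i, j = placed_j)
}

#' Summarise real scores against a null score matrix
#'
#' Given each gene's real score and its scores across random networks,
#' computes the permutation Z-score
#' `z = (real - mean(null)) / sd(null)` (sample standard deviation over the
#' random networks) and the sign-conditional empirical p-value: for
#' `z >= 0` the fraction of random scores at least the real score, for
#' `z < 0` the fraction at most the real score. A zero count is reported as
#' `p = 1/n_random` with `p_upper_bound` set, so p always lies in
#' (0, 1] and never below the permutation resolution.
#'
#' @param real Named numeric vector of real scores.
#' @param null_scores Numeric matrix, genes x random networks, rownames
#'   matching `names(real)`.
#' @return Data frame `gene`, `score`, `null_mean`, `null_sd`, `z`, `p`,
#'   `p_upper_bound` with attribute `n_random`.
#' @export
permutation_summary <- function(real, null_scores) {
  if (!is.matrix(null_scores) || is.null(rownames(null_scores))) {
    stop_validation("null_scores must be a matrix with gene rownames")
  }
  n_random <- ncol(null_scores)
  if (n_random < 2L) {
    stop_validation("need n_random >= 2 random networks to estimate the null spread")
  }
  real <- as_gene_values(real, "real")
  if (!identical(names(real), rownames(null_scores))) {
    null_scores <- null_scores[names(real), , drop = FALSE]
  }
  null_mean <- rowMeans(null_scores)
  null_sd <- apply(null_scores, 1L, stats::sd)
  z <- ifelse(null_sd > 0, (real - null_mean) / null_sd, NA_real_)
  upper_tail <- is.na(z) | z >= 0
  cnt <- ifelse(upper_tail,
                rowSums(null_scores >= real),
                rowSums(null_scores <= real))
  p_upper_bound <- cnt == 0L
  p <- pmax(cnt, 1L) / n_random
  out <- data.frame(gene = names(real), score = unname(real),
                    null_mean = unname(null_mean), null_sd = unname(null_sd),
                    z = unname(z), p = unname(p),
                    p_upper_bound = unname(p_upper_bound),
                    stringsAsFactors = FALSE)
  attr(out, "n_random") <- n_random
  out
}

#' Permutation test of neighbor scores against a degree-preserving null
#'
#' Computes real neighbor scores on the weighted network, then re-scores
#' the same values on `n_random` independently seeded stub-rewired networks
#' (unweighted, weight-1 edges) and summarises each gene's real score
#' against its random-score distribution via [permutation_summary()].
#' Replicate r uses seed `cfg$seed + r`, so the result is reproducible and
#' independent of execution order.
#'
#' @param net A [gene_network].
#' @param values Gene -> value mapping (see [nest_scores()]).
#' @param cfg A [randomization_config].
#' @return Data frame as in [permutation_summary()], restricted to network
#'   nodes.
#' @export
permutation_test <- function(net, values, cfg = randomization_config()) {
  stopifnot(inherits(net, "gene_network"))
  if (cfg$n_random < 2L) {
    stop_validation("cfg$n_random must be >= 2 for a permutation test")
  }
  real_tab <- nest_scores(net, values)
  real_tab <- real_tab[!is.na(real_tab$score), , drop = FALSE]
  real <- stats::setNames(real_tab$score, real_tab$gene)
  al <- align_values(net, values)
  null_scores <- matrix(NA_real_, length(net$nodes), cfg$n_random,
                        dimnames = list(net$nodes, NULL))
  for (r in seq_len(cfg$n_random)) {
    rnet <- stub_rewire(net, seed = cfg$seed + r, cfg = cfg)
    null_scores[, r] <- as.numeric(as_adjacency(rnet) %*% al$v)
  }
  permutation_summary(real, null_scores[names(real), , drop = FALSE])
}
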