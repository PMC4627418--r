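# Shared fixtures and independent oracles, built in code at test time.

# The worked 3-gene network: A-B 0.5, A-C 1.0, B-C 0.2.
tiny_network <- function() {
  gene_network(data.frame(from = c("A", "A", "B"),
                          to = c("B", "C", "C"),
                          weight = c(0.5, 1, 0.2)))
}

# Erdos-Renyi style random weighted network over `n` genes.
random_network <- function(n, p = 0.1, seed = 1) {
  genes <- sprintf("t%03d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  set.seed(seed)
  keep <- stats::runif(nrow(pairs)) < p
  w <- stats::runif(sum(keep), 0.05, 1)
  gene_network(data.frame(from = genes[pairs[keep, 1]],
                          to = genes[pairs[keep, 2]],
                          weight = w),
               nodes = genes)
}

# Independent oracle: naive double loop over the edge list.
naive_nest_scores <- function(net, values) {
  out <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  for (k in seq_len(nrow(net$edges))) {
    a <- net$edges$from[k]; b <- net$edges$to[k]; w <- net$edges$weight[k]
    va <- if (a %in% names(values)) values[[a]] else 0
    vb <- if (b %in% names(values)) values[[b]] else 0
    out[a] <- out[a] + w * vb
    out[b] <- out[b] + w * va
  }
  out
}

# Independent oracle: AUC by brute-force counting over all (pos, neg) pairs.
brute_force_auc <- function(scores, positives, negatives) {
  pos <- scores[intersect(positives, names(scores))]
  neg <- scores[intersect(negatives, names(scores))]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

expect_no_duplicate_edges <- function(net) {
  key <- paste(net$edges$from, net$edges$to)
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(net$edges$from != net$edges$to))
}
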