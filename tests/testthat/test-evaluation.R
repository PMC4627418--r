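test_that("AUC matches hand cases and the pair-counting convention", {
  g <- gold_standard(c("p1", "p2"), c("n1", "n2"))

  # perfect separation
  expect_equal(roc_auc(c(p1 = 0.9, p2 = 0.8, n1 = 0.7, n2 = 0.1), g)$auc, 1)

  # 3 of 4 pairs correctly ordered
  expect_equal(roc_auc(c(p1 = 0.9, p2 = 0.4, n1 = 0.7, n2 = 0.1), g)$auc, 3 / 4)

  # all tied: every pair counts 1/2
  expect_equal(roc_auc(c(p1 = 1, p2 = 1, n1 = 1, n2 = 1), g)$auc, 0.5)

  expect_error(roc_auc(c(p1 = 1, p2 = 2), g), "no scored")
})

test_that("AUC equals brute-force pair counting on random instances", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    genes <- sprintf("g%02d", seq_len(n))
    scores <- stats::setNames(sample(round(rnorm(n), 1)), genes)  # forces ties
    pos <- sample(genes, sample(2:(n %/% 2), 1))
    neg <- sample(setdiff(genes, pos), sample(2:(n %/% 2), 1))
    g <- gold_standard(pos, neg)
    expect_equal(roc_auc(scores, g)$auc, brute_force_auc(scores, pos, neg))
  }
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(32)
  genes <- sprintf("g%03d", 1:200)
  scores <- stats::setNames(rnorm(200), genes)
  pos <- sample(genes, 60)
  g <- gold_standard(pos, setdiff(genes, pos))
  ours <- roc_auc(scores, g)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = names(scores) %in% pos, predictor = unname(scores),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("ROC curves are monotone from (0,0) to (1,1) and integrate to the AUC", {
  set.seed(33)
  genes <- sprintf("g%03d", 1:150)
  scores <- stats::setNames(round(rnorm(150), 1), genes)
  pos <- sample(genes, 50)
  g <- gold_standard(pos, setdiff(genes, pos))
  roc <- roc_auc(scores, g)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[length(roc$fpr)], 1)
  expect_equal(roc$tpr[length(roc$tpr)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  expect_equal(trap, roc$auc, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(34)
  genes <- sprintf("g%03d", 1:100)
  scores <- stats::setNames(rnorm(100), genes)
  pos <- sample(genes, 30)
  g <- gold_standard(pos, setdiff(genes, pos))
  base <- roc_auc(scores, g)$auc
  for (f in list(function(x) 10 * x - 4, exp, function(x) x^3)) {
    expect_equal(roc_auc(f(scores), g)$auc, base)
  }
})

test_that("rank-sum Z matches closed forms, flips sign on label swap, tracks AUC", {
  # complete separation at n1 = n2 = 20: closed-form maximum of the
  # tie-free normal approximation with continuity correction
  genes <- sprintf("g%02d", 1:40)
  scores <- stats::setNames(c(21:40, 1:20), genes)
  pos <- genes[1:20]; neg <- genes[21:40]
  g <- gold_standard(pos, neg)
  n1 <- 20; n0 <- 20; n <- 40
  z_max <- (n1 * n0 / 2 - 0.5) / sqrt(n1 * n0 * (n + 1) / 12)
  expect_equal(rank_sum_z(scores, g), z_max)

  # antisymmetry under label swap
  set.seed(35)
  scores2 <- stats::setNames(rnorm(40), genes)
  expect_equal(rank_sum_z(scores2, gold_standard(pos, neg)),
               -rank_sum_z(scores2, gold_standard(neg, pos)))

  # directional agreement with AUC
  for (i in 1:10) {
    s <- stats::setNames(rnorm(40), genes)
    z <- rank_sum_z(s, g)
    auc <- roc_auc(s, g)$auc
    if (abs(auc - 0.5) > 0.02) expect_equal(z > 0, auc > 0.5)
  }
})

test_that("rank-sum Z agrees with the reference Wilcoxon implementation", {
  set.seed(36)
  for (i in 1:8) {
    pos_n <- sample(10:30, 1); neg_n <- sample(10:30, 1)
    x <- round(rnorm(pos_n + neg_n), 1)  # include ties
    genes <- sprintf("g%02d", seq_along(x))
    scores <- stats::setNames(x, genes)
    g <- gold_standard(genes[1:pos_n], genes[-(1:pos_n)])
    # the sign-symmetric continuity correction matches the two-sided z
    ref <- stats::wilcox.test(x[1:pos_n], x[-(1:pos_n)],
                              alternative = "two.sided", correct = TRUE,
                              exact = FALSE)
    expect_equal(2 * stats::pnorm(-abs(rank_sum_z(scores, g))),
                 ref$p.value, tolerance = 1e-9)
  }
})

test_that("rank-sum Z stays near 0 when both groups share a distribution", {
  set.seed(37)
  genes <- sprintf("g%04d", 1:1000)
  scores <- stats::setNames(rnorm(1000), genes)
  g <- gold_standard(genes[1:500], genes[501:1000])
  expect_lt(abs(rank_sum_z(scores, g)), 3)
})

test_that("logistic confounder analysis recovers generating coefficients", {
  set.seed(38)
  n <- 5000
  genes <- sprintf("g%04d", 1:n)
  x <- stats::setNames(rnorm(n), genes)
  null_cov <- stats::setNames(rnorm(n), genes)
  pr <- 1 / (1 + exp(-x))
  y <- stats::setNames(rbinom(n, 1, pr), genes)
  tab <- logistic_confounder_test(y, list(signal = x, nullcov = null_cov))
  expect_s3_class(tab, "logit_table")
  co <- tab$coefficient[tab$covariate == "signal"]
  expect_gte(co, 0.8); expect_lte(co, 1.2)
  expect_lt(abs(tab$z[tab$covariate == "nullcov"]), 3)
  expect_equal(tab$z, tab$coefficient / tab$std_error)
  # Wald p consistent with z
  expect_equal(tab$p, 2 * stats::pnorm(-abs(tab$z)), tolerance = 1e-9)
  fitted <- attr(tab, "fitted")
  expect_true(all(fitted > 0 & fitted < 1))
  expect_equal(length(fitted), attr(tab, "n"))
})

test_that("degenerate logistic designs are rejected", {
  genes <- sprintf("g%03d", 1:100)
  y <- stats::setNames(rep(c(0, 1), 50), genes)
  const <- stats::setNames(rep(2, 100), genes)
  ok <- stats::setNames(rnorm(100), genes)
  expect_error(logistic_confounder_test(y, list(a = const, b = ok)), "constant")

  # perfect separation flagged rather than silently reported
  sep <- stats::setNames(c(rep(-1, 50), rep(1, 50)), genes)
  ysep <- stats::setNames(c(rep(0, 50), rep(1, 50)), genes)
  expect_error(logistic_confounder_test(ysep, list(a = sep)), "converge|separation")
})

test_that("noise injection honors level, base sd, and seed", {
  set.seed(39)
  vals <- stats::setNames(rnorm(10000, sd = 2), sprintf("g%05d", 1:10000))

  # level 0 is the identity
  expect_identical(inject_noise(vals, 0, seed = 1), vals)

  # injected component has sd level * sd(values)
  noisy <- inject_noise(vals, 1, seed = 2)
  expect_gt(stats::sd(noisy - vals), 1.9)
  expect_lt(stats::sd(noisy - vals), 2.1)
  half <- inject_noise(vals, 0.5, seed = 3)
  expect_gt(stats::sd(half - vals), 0.9)
  expect_lt(stats::sd(half - vals), 1.1)

  # determinism and seed sensitivity
  expect_identical(inject_noise(vals, 1, seed = 2), noisy)
  expect_false(identical(inject_noise(vals, 1, seed = 4), noisy))
})

test_that("degradation experiment: zero level is exact, huge noise erases both predictors", {
  ds <- generate_dataset(synthetic_spec(n_genes = 200, n_modules = 6,
                                        module_size = 8, seed = 41))
  gold <- gold_standard(ds$truth_protective,
                        setdiff(names(ds$screen), ds$truth_protective))
  de <- degradation_experiment(ds$network, ds$screen, gold,
                               levels = c(0, 100), n_reps = 40, seed = 42)
  at0 <- de[de$level == 0, ]
  expect_true(all(at0$mean_reduction_ratio == 0))
  expect_true(all(at0$sd_reduction_ratio == 0))

  # noise-dominated limit: AUC -> 0.5 in expectation (per-replicate AUCs
  # fluctuate strongly because module-mates share neighbor noise),
  # so the mean ratio approaches (AUC0 - 0.5)/AUC0
  auc0 <- attr(de, "auc0")
  big <- de[de$level == 100, ]
  expect_equal(big$mean_auc, c(0.5, 0.5), tolerance = 0.12)
  expect_equal(big$mean_reduction_ratio,
               unname((auc0 - 0.5) / auc0)[match(big$predictor, names(auc0))],
               tolerance = 0.3)
})

test_that("averaging over larger complexes makes neighbor scores noise-robust", {
  # the screen-enhancement mechanism: summing over many in-complex
  # neighbors cancels injected noise, so the neighbor score's AUC decays
  # more slowly than the raw values' AUC relative to its own baseline
  ds <- generate_dataset(synthetic_spec(n_genes = 500, n_modules = 6,
                                        module_size = 25,
                                        active_fraction = 0.5, seed = 1))
  gold <- gold_standard(ds$truth_protective,
                        setdiff(names(ds$screen), ds$truth_protective))
  de <- degradation_experiment(ds$network, ds$screen, gold,
                               levels = c(0.5, 1, 2), n_reps = 10, seed = 1)
  for (lev in c(0.5, 1, 2)) {
    expect_lt(de$mean_reduction_ratio[de$level == lev & de$predictor == "nest"],
              de$mean_reduction_ratio[de$level == lev & de$predictor == "raw"])
  }
})

test_that("auto negatives take bottom-ranked genes outside the positive set", {
  ranking <- c(a = 5, b = 4, c = 3, d = 2, e = 1, f = 0)
  expect_equal(sort(auto_negatives(ranking, positives = c("a", "f"))),
               sort(c("e", "d")))
  expect_equal(auto_negatives(ranking, positives = "a", n = 3),
               c("f", "e", "d"))
  expect_error(auto_negatives(ranking, positives = letters[1:5], n = 3),
               "not enough")
  expect_error(gold_standard(c("a", "b"), c("b", "c")), "disjoint")
})
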