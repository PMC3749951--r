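# logistic commitment classifier, hazard normalization, commitment runs

test_that("classifier probability is the logistic of the linear predictor", {
  clf <- structure(list(beta0 = -3, beta = c(A = 0.5), genes = "A"),
                   class = "commitment_classifier")
  expect_equal(classifier_probability(clf, c(A = 6)), 0.5)  # z = 0
  expect_equal(classifier_probability(clf, c(A = 0)), plogis(-3))
  expect_error(classifier_probability(clf, c(B = 1)), "lacks gene")
  # monotone in each input with the sign of its weight
  g <- seq(0, 10, 1)
  p <- classifier_probability(clf, cbind(A = g))
  expect_true(all(diff(p) > 0))
})

test_that("training separates a one-gene toy set with the boundary between the classes", {
  tab <- expression_table(data.frame(A = c(0, 0, 1, 9, 10, 10)),
                          population = c(rep("SR", 3), rep("CP1", 3)))
  clf <- suppressWarnings(train_logistic(tab, genes = "A"))
  boundary <- -clf$beta0 / clf$beta[["A"]]
  expect_gt(boundary, 1)
  expect_lt(boundary, 9)
  # independent route: direct likelihood maximization over (beta0, beta)
  nll <- function(par) {
    z <- par[1] + par[2] * tab$A
    -sum((tab$population == "CP1") * z - log1p(exp(z)))
  }
  ref <- optim(c(0, 0), nll, method = "BFGS")$par
  ref_boundary <- -ref[1] / ref[2]
  # perfect separation: both routes bound the boundary between the classes
  expect_gt(ref_boundary, 1)
  expect_lt(ref_boundary, 9)
  expect_equal(clf$auc, 1)
})

test_that("indistinguishable classes give near-zero weights and prevalence probability", {
  x <- c(1, 2, 3, 4, 5, 6)
  tab <- expression_table(data.frame(A = c(x, x)),
                          population = c(rep("SR", 6), rep("CP1", 6)))
  clf <- train_logistic(tab, genes = "A")
  expect_lt(abs(clf$beta[["A"]]), 1e-6)
  expect_equal(unname(classifier_probability(clf, c(A = 3))), 0.5,
               tolerance = 1e-6)
  expect_error(train_logistic(tab[tab$population == "SR", ], genes = "A"),
               "both classes")
})

test_that("perfect separation falls back to a bounded ridge fit with a warning", {
  tab <- expression_table(data.frame(A = c(0, 1, 2, 8, 9, 10)),
                          population = c(rep("SR", 3), rep("CP1", 3)))
  expect_warning(clf <- train_logistic(tab, genes = "A"), "separation")
  expect_true(all(is.finite(c(clf$beta0, clf$beta))))
  expect_true(clf$separation)
  expect_gt(clf$beta[["A"]], 0)
})

test_that("training on synthetic populations recovers the direction of the boundary", {
  tab <- gen_expression_table(seed = 13)
  clf <- train_logistic(tab)
  # the generator raises Gata2 (and Gata1) and lowers Mpo across the boundary
  expect_gt(clf$beta[["Gata2"]], 0)
  expect_lt(clf$beta[["Mpo"]], 0)
  expect_gt(clf$auc, 0.8)
})

test_that("mean probability reduces to constants in degenerate cases", {
  kin <- default_archetypes()
  flat <- structure(list(beta0 = 0, beta = c(Gata1 = 0, Gata2 = 0, Mpo = 0),
                         genes = kin$gene),
                    class = "commitment_classifier")
  expect_equal(as.numeric(mean_probability(flat, kin, duration = 50, seed = 1)),
               0.5)
  kin_locked <- lock_promoter(kin, "Gata1", "OFF")
  only_g1 <- structure(list(beta0 = -1, beta = c(Gata1 = 2), genes = "Gata1"),
                       class = "commitment_classifier")
  expect_equal(as.numeric(mean_probability(only_g1, kin_locked, duration = 50,
                                           seed = 2)),
               plogis(-1))
})

test_that("mean probability is reproducible across seeds within sampling error", {
  kin <- default_archetypes()
  tab <- gen_expression_table(kin, seed = 14)
  clf <- train_logistic(tab)
  p1 <- as.numeric(mean_probability(clf, kin, duration = 15000, seed = 31))
  p2 <- as.numeric(mean_probability(clf, kin, duration = 15000, seed = 32))
  expect_lt(abs(p1 - p2), 0.03)
})

test_that("the expression-specific rate is the normalized classifier probability", {
  clf <- structure(list(beta0 = 0, beta = c(A = 1), genes = "A"),
                   class = "commitment_classifier")
  p_bar <- 0.25
  # probability 0.5 at g = 0: lambda = c * 0.5 / 0.25 = 2c
  expect_equal(unname(expression_commitment_rate(clf, c(A = 0), c = 0.002,
                                                 p_bar = p_bar)),
               0.004)
  # probability equal to p_bar gives exactly c
  g_star <- qlogis(p_bar)
  expect_equal(unname(expression_commitment_rate(clf, c(A = g_star), c = 0.002,
                                                 p_bar = p_bar)),
               0.002, tolerance = 1e-12)
  # vanishing probability gives a vanishing rate
  clf0 <- structure(list(beta0 = -1e4, beta = c(A = 0), genes = "A"),
                    class = "commitment_classifier")
  expect_equal(unname(expression_commitment_rate(clf0, c(A = 5), c = 0.002,
                                                 p_bar = p_bar)),
               0)
  expect_error(expression_commitment_rate(clf, c(A = 1), c = 0.002, p_bar = 0),
               "p_bar")
})

test_that("an impossible classifier yields no commitment events", {
  kin <- toy_gene("A")
  clf0 <- structure(list(beta0 = -1e4, beta = c(A = 0), genes = "A"),
                    class = "commitment_classifier")
  sim <- simulate_commitment(kin, clf0, c = 0.01, duration = 2000,
                             p_bar = 0.5, seed = 15)
  expect_equal(sim$n_events, 0)
  expect_equal(commitment_frequency(sim), 0)
})

test_that("a flat classifier produces a Poisson stream at the configured rate", {
  kin <- toy_gene("A")
  flat <- structure(list(beta0 = 0, beta = c(A = 0), genes = "A"),
                    class = "commitment_classifier")
  # constant probability 0.5 with p_bar = 0.5: hazard is exactly c
  sim <- simulate_commitment(kin, flat, c = 0.02, duration = 5000,
                             p_bar = 0.5, seed = 16)
  expected <- 0.02 * 5000
  expect_lt(abs(sim$n_events - expected), 3 * sqrt(expected))
  # inter-event times exponential: mean within 3 SE of 1/c
  gaps <- diff(c(0, sim$commitments$time))
  expect_lt(abs(mean(gaps) - 50), 3 * 50 / sqrt(length(gaps)))
})

test_that("the long-run commitment frequency is normalized to c", {
  kin <- default_archetypes()
  tab <- gen_expression_table(kin, seed = 17)
  clf <- train_logistic(tab)
  p_bar <- as.numeric(mean_probability(clf, kin, duration = 15000, seed = 18))
  c0 <- 0.02
  sim <- simulate_commitment(kin, clf, c = c0, duration = 20000,
                             p_bar = p_bar, seed = 19)
  expect_lt(abs(sim$frequency - c0) / c0, 0.15)
})

test_that("commitment snapshots are biased toward high classifier probability", {
  kin <- default_archetypes()
  tab <- gen_expression_table(kin, seed = 20)
  clf <- train_logistic(tab)
  p_bar <- as.numeric(mean_probability(clf, kin, duration = 10000, seed = 21))
  sim <- simulate_commitment(kin, clf, c = 0.01, duration = 20000,
                             p_bar = p_bar, seed = 22)
  expect_gt(sim$n_events, 30)
  # committed cells sit above the time-average probability...
  expect_gt(mean(sim$commitments$probability_at_commit),
            sim$mean_probability_observed)
  # ...yet low-probability commitments still occur
  expect_gt(sum(sim$commitments$probability_at_commit <
                  sim$mean_probability_observed), 0)
  # snapshot distribution is stochastically larger than the stationary one:
  # compare against probabilities of states drawn from the stationary law
  set.seed(23)
  stat_g <- vapply(kin$gene, function(g) {
    p <- stationary_oracle(kin, gene = g, m_max = 256)
    m <- sample(0:256, 500, replace = TRUE, prob = p)
    multiplicity_to_g(m, kin$delta[match(g, kin$gene)])
  }, numeric(500))
  stat_p <- classifier_probability(clf, stat_g)
  wt <- suppressWarnings(
    wilcox.test(sim$commitments$probability_at_commit, stat_p,
                alternative = "greater"))
  expect_lt(wt$p.value, 0.01)
})

test_that("absorbing mode stops the clock at the first transition", {
  kin <- toy_gene("A")
  flat <- structure(list(beta0 = 0, beta = c(A = 0), genes = "A"),
                    class = "commitment_classifier")
  sim <- simulate_commitment(kin, flat, c = 0.05, duration = 10000,
                             p_bar = 0.5, seed = 24, restart = FALSE)
  expect_equal(sim$n_events, 1)
  expect_lt(sim$duration, 10000)
  expect_equal(sim$commitments$time, sim$duration)
})

test_that("commitment frequency is count over duration", {
  expect_equal(commitment_frequency(60, duration = 30000), 0.002)
  expect_equal(commitment_frequency(data.frame(time = numeric(0)),
                                    duration = 100), 0)
  expect_error(commitment_frequency(3, duration = 0), "positive")
})
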