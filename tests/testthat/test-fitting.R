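# histogram objective, annealing contracts, scans, promoter locks

test_that("the histogram error is a symmetric sum of squares over shared bins", {
  h1 <- build_histogram(c(0, 0, 2.5))
  expect_equal(distribution_error(h1, h1), 0)
  h_u <- build_histogram(0)           # all undetected
  h_b <- build_histogram(0.5)         # all in (0,1]
  expect_equal(distribution_error(h_u, h_b), 2)
  set.seed(27)
  ha <- build_histogram(runif(20, 0, 30))
  hb <- build_histogram(runif(20, 0, 30))
  expect_equal(distribution_error(ha, hb), distribution_error(hb, ha))
  hc <- build_histogram(runif(20, 0, 30), bin_width = 0.5)
  expect_error(distribution_error(ha, hc), "binning")
})

test_that("annealing tracks a non-increasing best error and respects bounds", {
  krow <- default_archetypes()[2, ]
  tt <- simulate_telegraph(krow, 4000, seed = 28, record_events = FALSE)
  target <- telecommit:::occupancy_to_histogram(tt$occupancy[[1]], krow$delta,
                                                0.5, 30)
  cfg <- fit_config(n_evals = 120, n_starts = 1, steps_per_temp = 10,
                    sim_duration = 400, seed = 29)
  truth <- c(tau_act = krow$tau_act, tau_rep = krow$tau_rep,
             tau_prod = krow$tau_prod, delta = krow$delta)
  fit <- anneal_fit(target, tau_dec = krow$tau_dec, config = cfg,
                    gene = krow$gene, init = truth)
  expect_true(all(diff(fit$best_trace) <= 0))
  expect_true(all(c(fit$kinetics$tau_act, fit$kinetics$tau_rep,
                    fit$kinetics$tau_prod) >= cfg$bounds[1]))
  expect_true(fit$kinetics$delta >= 0 && fit$kinetics$delta <= 30)
  expect_gte(fit$error, 0)
  expect_identical(fit$kinetics$tau_dec, krow$tau_dec)  # decay never proposed
})

test_that("grid refinement never worsens the incumbent and honors a trivial grid", {
  krow <- default_archetypes()[2, ]
  tt <- simulate_telegraph(krow, 4000, seed = 30, record_events = FALSE)
  target <- telecommit:::occupancy_to_histogram(tt$occupancy[[1]], krow$delta,
                                                0.5, 30)
  cfg <- fit_config(sim_duration = 500, final_factor = 2, seed = 31)
  start <- list(kinetics = krow, error = NA_real_, gene = krow$gene,
                config = cfg)
  class(start) <- "fit_result"
  trivial <- grid_refine(start, target, multipliers = 1, delta_offsets = 0,
                         config = cfg)
  expect_equal(trivial$kinetics$tau_act, krow$tau_act)
  expect_equal(trivial$kinetics$delta, krow$delta)

  # offset incumbent: refinement moves toward (or stays at) lower error
  off <- start
  off$kinetics$tau_prod <- krow$tau_prod * 1.12
  refined <- grid_refine(off, target,
                         multipliers = seq(0.85, 1.15, 0.05),
                         delta_offsets = 0, config = cfg)
  expect_lte(refined$error_grid, refined$error_grid_incumbent)
})

test_that("the robustness scan covers the full multiplier grid with the optimum near center", {
  krow <- default_archetypes()[2, ]
  tt <- simulate_telegraph(krow, 6000, seed = 32, record_events = FALSE)
  target <- list()
  target[[krow$gene]] <- telecommit:::occupancy_to_histogram(
    tt$occupancy[[1]], krow$delta, 1, 30)
  mult <- c(0.5, 1, 1.6)
  scan <- robustness_scan(krow, target, multipliers = mult, duration = 3000,
                          seed = 33)
  expect_equal(nrow(scan), length(mult)^3)
  expect_setequal(unique(scan$m_act), mult)
  center <- scan$error[scan$m_act == 1 & scan$m_rep == 1 & scan$m_prod == 1]
  corners <- scan$error[scan$m_act != 1 & scan$m_rep != 1 & scan$m_prod != 1]
  expect_lt(center, min(corners))  # identifiable gene: extremes fit worse
  # the default multiplier set spans 0.5-1.6 in 0.1 steps (12^3 grid)
  expect_length(seq(0.5, 1.6, by = 0.1), 12)
})

test_that("perturbation scans are reproducible, order-invariant and monotone where expected", {
  krow <- toy_gene("A", delta = 6)
  clf <- structure(list(beta0 = -4, beta = c(A = 0.6), genes = "A"),
                   class = "commitment_classifier")
  p_bar <- as.numeric(mean_probability(clf, krow, duration = 4000, seed = 34))
  scan <- perturbation_scan(krow, clf, c = 0.01, p_bar = p_bar,
                            multipliers = c(0.4, 1, 2.5), duration = 4000,
                            seed = 35)
  expect_equal(nrow(scan), 4 * 3)
  # identity multiplier reproduces the wild-type frequency within noise
  wt <- simulate_commitment(krow, clf, c = 0.01, duration = 20000,
                            p_bar = p_bar, seed = 36)
  id_rows <- scan[scan$multiplier == 1, ]
  for (f in id_rows$frequency) {
    expect_lt(abs(f - wt$frequency), 4 * sqrt(wt$frequency / 4000))
  }
  # execution order does not matter: permuted multipliers, same cells
  scan_perm <- perturbation_scan(krow, clf, c = 0.01, p_bar = p_bar,
                                 multipliers = c(2.5, 1, 0.4), duration = 4000,
                                 seed = 35)
  merged <- merge(scan, scan_perm, by = c("gene", "parameter", "multiplier"))
  expect_equal(merged$frequency.x, merged$frequency.y)
  # slowing production of a positive-weight gene lowers commitment frequency
  slow <- scan[scan$parameter == "tau_prod" & scan$multiplier == 2.5, "frequency"]
  fast <- scan[scan$parameter == "tau_prod" & scan$multiplier == 0.4, "frequency"]
  expect_lt(slow, fast)
})

test_that("locking a promoter fixes its state and the constitutive mean", {
  kin <- toy_gene("g")
  on <- lock_promoter(kin, "g", "ON")
  expect_true(is.infinite(on$tau_rep))
  expect_true(on$therm_exempt)
  traj <- simulate_telegraph(on, duration = 3000, seed = 37)
  expect_equal(sum(traj$events$action == "repress"), 0)
  occ <- occupancy(traj, "g")
  mu_hat <- sum(as.numeric(names(occ)) * occ)
  mu <- kin$tau_dec / kin$tau_prod
  expect_lt(abs(mu_hat - mu), 0.25 * mu)

  off <- lock_promoter(kin, "g", "OFF")
  traj_off <- simulate_telegraph(off, duration = 500, seed = 38)
  expect_equal(occupancy(traj_off, "g"), c("0" = 1))
  expect_error(lock_promoter(kin, "nope", "ON"), "unknown gene")
})

test_that("locking promoters of a positive-weight gene shifts commitment frequency", {
  kin <- default_archetypes()
  tab <- gen_expression_table(kin, seed = 39)
  clf <- train_logistic(tab)
  stopifnot(clf$beta[["Gata2"]] > 0)
  p_bar <- as.numeric(mean_probability(clf, kin, duration = 8000, seed = 40))
  freqs <- vapply(1:3, function(s) {
    wt <- simulate_commitment(kin, clf, c = 0.002, duration = 8000,
                              p_bar = p_bar, seed = 200 + s)$frequency
    on <- simulate_commitment(lock_promoter(kin, "Gata2", "ON"), clf,
                              c = 0.002, duration = 8000, p_bar = p_bar,
                              seed = 300 + s)$frequency
    off <- simulate_commitment(lock_promoter(kin, "Gata2", "OFF"), clf,
                               c = 0.002, duration = 8000, p_bar = p_bar,
                               seed = 400 + s)$frequency
    c(on > wt, off < wt)
  }, logical(2))
  expect_true(all(freqs))  # sign-consistent across seeds
})
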