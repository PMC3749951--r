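# first-reaction Gillespie core and the master-equation oracle

test_that("waiting times are exponential with the requested mean", {
  expect_identical(draw_waiting_time(Inf), Inf)
  set.seed(1); a <- draw_waiting_time(1)
  set.seed(1); b <- draw_waiting_time(1)
  expect_identical(a, b)
  set.seed(2)
  draws <- draw_waiting_time(2, n = 1e5)
  expect_lt(abs(mean(draws) - 2), 3 * 2 / sqrt(1e5))
  expect_error(draw_waiting_time(0), "positive")
  expect_error(draw_waiting_time(-1), "positive")
})

test_that("a single step executes the only possible action when forced", {
  kin <- gene_kinetics("g", tau_act = 5, tau_rep = 5, tau_prod = 1, tau_dec = 2)
  st <- cell_state(kin)
  out <- sim_step(st, kin)
  expect_equal(out$event$action, "activate")
  expect_equal(out$state$s[["g"]], 1L)
  expect_gt(out$state$t, 0)

  locked <- lock_promoter(kin, "g", "OFF")
  expect_error(sim_step(cell_state(locked), locked), "stalled")
})

test_that("the dominant rate wins when it is overwhelmingly fast", {
  kin <- gene_kinetics("g", tau_act = 1000, tau_rep = 1000, tau_prod = 1e-7,
                       tau_dec = 1000)
  st <- cell_state(kin)
  st$s[1] <- 1L
  set.seed(3)
  for (i in 1:25) {
    out <- sim_step(st, kin)
    expect_equal(out$event$action, "produce")
    st$m[1] <- 0L  # reset so decay never competes with substantial rate
  }
})

test_that("action selection follows competing-exponential probabilities", {
  # from state (ON, m = 1): repress at 1/2, produce at 1, decay at 1/4
  kin <- gene_kinetics("g", tau_act = 10, tau_rep = 2, tau_prod = 1, tau_dec = 4)
  rates <- c(repress = 1 / 2, produce = 1, decay = 1 / 4)
  set.seed(4)
  n <- 1e5
  counts <- c(repress = 0, produce = 0, decay = 0)
  st0 <- cell_state(kin)
  st0$s[1] <- 1L; st0$m[1] <- 1L
  for (i in seq_len(n)) {
    out <- sim_step(st0, kin)
    counts[out$event$action] <- counts[out$event$action] + 1
  }
  test <- suppressWarnings(chisq.test(counts, p = rates / sum(rates)))
  expect_gt(test$p.value, 0.01)
})

test_that("event-log replay reproduces the final state exactly", {
  kin <- default_archetypes()
  traj <- simulate_telegraph(kin, duration = 400, seed = 11)
  replayed <- telecommit:::replay_trajectory(traj)
  expect_identical(replayed$m, traj$final_state$m)
  expect_identical(replayed$s, traj$final_state$s)

  # action legality along the log: activate only from OFF, repress from ON,
  # decay never drives m negative
  ev <- traj$events
  for (g in kin$gene) {
    evg <- ev[ev$gene == g, ]
    s_changes <- evg$action[evg$action %in% c("activate", "repress")]
    start <- if (traj$initial_state$s[[g]] == 0L) "activate" else "repress"
    expect_identical(s_changes,
                     rep(c(start, setdiff(c("activate", "repress"), start)),
                         length.out = length(s_changes)))
    expect_true(all(evg$new_m >= 0))
  }
})

test_that("compiled occupancy matches an independent replay accumulation", {
  kin <- default_archetypes()
  traj <- simulate_telegraph(kin, duration = 300, seed = 12)
  for (g in kin$gene) {
    occ_cpp <- occupancy(traj, g)
    occ_r <- telecommit:::occupancy_from_events(traj, g)
    n <- max(length(occ_cpp), length(occ_r))
    expect_equal(c(occ_cpp, numeric(n - length(occ_cpp))),
                 c(occ_r, numeric(n - length(occ_r))),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(sum(occ_cpp), 1, tolerance = 1e-12)
  }
  expect_error(occupancy(traj, "nonexistent"), "unknown gene")
})

test_that("thermalization cycles every promoter and can be waived for locked genes", {
  kin <- default_archetypes()
  st <- thermalize(kin, seed = 5)
  expect_true(all(attr(st, "n_act") >= 1))
  expect_true(all(attr(st, "n_rep") >= 1))
  expect_identical(st$t, 0)

  locked <- lock_promoter(kin, "Gata1", "ON")
  st2 <- thermalize(locked, seed = 6)
  expect_identical(st2$s[["Gata1"]], 1L)

  naughty <- kin
  naughty$tau_rep[1] <- Inf  # locked without the waiver flag
  expect_error(thermalize(naughty), "Gata1")
})

test_that("thermalized states are closer to stationarity than the cold start", {
  # Three genes whose stationary laws are not dominated by the silent state.
  # (For a rarely expressed gene the ON/OFF-cycle stopping rule conditions
  # on having just completed a burst, which sits farther from the mostly
  # silent stationary law than the cold start does; that residual bias
  # washes out over the subsequent timed run.)
  kin <- rbind(toy_gene("fast"), default_archetypes()[2:3, ])
  oracle <- lapply(kin$gene, function(g) stationary_oracle(kin, gene = g, m_max = 128))
  names(oracle) <- kin$gene
  set.seed(7)
  n_rep <- 300
  m_draws <- matrix(0L, n_rep, nrow(kin), dimnames = list(NULL, kin$gene))
  for (i in seq_len(n_rep)) {
    st <- thermalize(kin)
    m_draws[i, ] <- st$m
  }
  for (g in kin$gene) {
    emp <- tabulate(m_draws[, g] + 1L, nbins = 129) / n_rep
    tv_therm <- tv_dist(emp, oracle[[g]])
    tv_cold <- tv_dist(c(1, numeric(128)), oracle[[g]])  # cold start: m = 0
    expect_lt(tv_therm, tv_cold)
  }
})

test_that("a promoter locked OFF stays silent", {
  kin <- lock_promoter(toy_gene(), "g", "OFF")
  traj <- simulate_telegraph(kin, duration = 200, seed = 8)
  expect_equal(occupancy(traj, "g"), c("0" = 1))
})

test_that("time-averaged multiplicity matches the telegraph closed form", {
  kin <- default_archetypes()[2, ]  # frequent-burst gene, fast mixing
  mu <- stationary_mean(kin)
  means <- vapply(1:12, function(s) {
    traj <- simulate_telegraph(kin, duration = 1500, seed = 100 + s,
                               record_events = FALSE)
    occ <- occupancy(traj, kin$gene)
    sum(as.numeric(names(occ)) * occ)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - mu), 3 * se)
})

test_that("simulator occupancy converges to the master-equation stationary law", {
  kin <- default_archetypes()
  traj <- simulate_telegraph(kin, duration = 8000, seed = 9, record_events = FALSE)
  for (g in kin$gene) {
    expect_lt(tv_dist(occupancy(traj, g),
                      stationary_oracle(kin, gene = g, m_max = 256)), 0.05)
  }
})

test_that("the stationary oracle has the analytic limits and mean", {
  # constitutive limit: locked ON is Poisson with mean tau_dec / tau_prod
  kin_on <- lock_promoter(toy_gene(), "g", "ON")
  p <- stationary_oracle(kin_on, m_max = 64)
  expect_equal(as.numeric(p), dpois(0:64, 4) / sum(dpois(0:64, 4)),
               tolerance = 1e-10)

  kin_off <- lock_promoter(toy_gene(), "g", "OFF")
  expect_equal(unname(stationary_oracle(kin_off, m_max = 16)[1]), 1)

  for (krow in split(default_archetypes(), seq_len(3))) {
    p <- stationary_oracle(krow, m_max = 300)
    expect_equal(sum(as.numeric(names(p)) * p), stationary_mean(krow),
                 tolerance = 1e-8)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }

  expect_error(stationary_oracle(toy_gene(), m_max = 4), "m_max")
})

test_that("common scaling of promoter dwells changes the law only through burst statistics", {
  # faster switching at fixed ON fraction narrows the multiplicity law
  # toward the constitutive Poisson; checked against the oracle
  kin_slow <- gene_kinetics("g", tau_act = 40, tau_rep = 40, tau_prod = 0.5,
                            tau_dec = 2)
  kin_fast <- gene_kinetics("g", tau_act = 0.1, tau_rep = 0.1, tau_prod = 0.5,
                            tau_dec = 2)
  p_slow <- stationary_oracle(kin_slow, m_max = 128)
  p_fast <- stationary_oracle(kin_fast, m_max = 128)
  m <- 0:128
  mean_slow <- sum(m * p_slow); mean_fast <- sum(m * p_fast)
  expect_equal(mean_slow, mean_fast, tolerance = 1e-8)  # mean preserved
  var_slow <- sum(m^2 * p_slow) - mean_slow^2
  var_fast <- sum(m^2 * p_fast) - mean_fast^2
  expect_gt(var_slow, var_fast)  # slow switching is over-dispersed
  # fast-switching limit approaches Poisson at the effective rate
  expect_lt(tv_dist(p_fast, dpois(m, mean_fast)), 0.02)
})
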