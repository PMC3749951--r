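#' Draw an exponential waiting time
#'
#' Samples the waiting time of a Gillespie action from the exponential
#' distribution with the given mean (hours). An infinite mean describes an
#' action that never fires (locked promoter) and returns `Inf`.
#'
#' @param mean mean waiting time in hours; strictly positive, may be `Inf`.
#' @param n number of draws.
#' @return Numeric vector of `n` waiting times.
#' @export
draw_waiting_time <- function(mean, n = 1) {
  if (length(mean) != 1 || is.na(mean) || mean <= 0) {
    stopf("mean waiting time must be a single positive number (or Inf)")
  }
  if (is.infinite(mean)) return(rep(Inf, n))
  rexp(n, rate = 1 / mean)
}

action_names <- c("activate", "repress", "produce", "decay", "commit")

# action code (0-based, matching the C++ core) -> name
action_label <- function(code) action_names[code + 1L]

#' Initial cell state for a kinetics table
#'
#' All promoters start OFF with zero mRNA, except genes locked ON
#' (`tau_rep = Inf`), which start in their locked state. Thermalization
#' removes the dependence on this choice for switchable genes.
#'
#' @param kin kinetics table.
#' @return A `cell_state`: list with integer vectors `s` (0 = OFF, 1 = ON)
#'   and `m` (mRNA multiplicity), both named by gene, and clock `t` in hours.
#' @export
cell_state <- function(kin) {
  kin <- as_kinetics(kin)
  s <- ifelse(is.infinite(kin$tau_rep), 1L, 0L)
  structure(list(s = setNames(as.integer(s), kin$gene),
                 m = setNames(rep(0L, nrow(kin)), kin$gene),
                 t = 0),
            class = "cell_state")
}

#' Execute one first-reaction Gillespie step
#'
#' Draws a fresh exponential waiting time for every currently possible action
#' of every gene (activation if OFF; repression and production if ON; one
#' aggregate decay clock with mean `tau_dec / m` if `m > 0`), executes the
#' action with the shortest time and advances the clock by that time.
#' Unexecuted times are discarded: by memorylessness of the exponential,
#' redrawing them at the next step leaves the process law unchanged.
#'
#' This is a reference single-step implementation in R; long simulations use
#' the compiled loop in [simulate_telegraph()].
#'
#' @param state a `cell_state` (see [cell_state()]).
#' @param kin kinetics table.
#' @return List with elements `state` (updated) and `event` (one-row
#'   data.frame: `time`, `gene`, `action`, `new_m`, `new_s`).
#' @export
sim_step <- function(state, kin) {
  kin <- as_kinetics(kin)
  n <- nrow(kin)
  best <- list(dt = Inf, gene = NA_integer_, action = NA_integer_)
  consider <- function(best, dt, gene, action) {
    if (dt < best$dt) list(dt = dt, gene = gene, action = action) else best
  }
  for (i in seq_len(n)) {
    if (state$s[i] == 0L) {
      best <- consider(best, draw_waiting_time(kin$tau_act[i]), i, 0L)
    } else {
      best <- consider(best, draw_waiting_time(kin$tau_rep[i]), i, 1L)
      best <- consider(best, draw_waiting_time(kin$tau_prod[i]), i, 2L)
    }
    if (state$m[i] > 0L) {
      best <- consider(best, draw_waiting_time(kin$tau_dec[i] / state$m[i]), i, 3L)
    }
  }
  if (is.infinite(best$dt)) {
    stopf("simulation stalled: no possible actions (all promoters locked OFF with no mRNA)")
  }
  i <- best$gene
  state$t <- state$t + best$dt
  switch(action_label(best$action),
         activate = { state$s[i] <- 1L },
         repress = { state$s[i] <- 0L },
         produce = { state$m[i] <- state$m[i] + 1L },
         decay = { state$m[i] <- state$m[i] - 1L })
  event <- data.frame(time = state$t, gene = kin$gene[i],
                      action = action_label(best$action),
                      new_m = state$m[i], new_s = state$s[i],
                      stringsAsFactors = FALSE)
  list(state = state, event = event)
}

#' Thermalize a cell
#'
#' Runs the event loop (off the clock) until every gene has executed at least
#' one activation and one repression, discarding the transient from the cold
#' start. Genes flagged `therm_exempt` (locked promoters, see
#' [lock_promoter()]) are exempted and start in their locked state; a locked
#' gene without the waiver is an error naming the blocking gene.
#'
#' @param kin kinetics table.
#' @param seed optional RNG seed.
#' @return A `cell_state` with clock 0, with attributes `n_act`/`n_rep`
#'   giving the per-gene switch counts observed during thermalization.
#' @export
thermalize <- function(kin, seed = NULL) {
  kin <- as_kinetics(kin)
  blocked <- !kin$therm_exempt &
    (is.infinite(kin$tau_act) | is.infinite(kin$tau_rep))
  if (any(blocked)) {
    stopf("gene '%s' blocks thermalization: locked promoter cannot complete an ON/OFF cycle (use lock_promoter() to waive)",
          kin$gene[which(blocked)[1]])
  }
  res <- with_seed(seed, run_core(kin, duration = 0, do_therm = TRUE,
                                  record_events = FALSE))
  st <- structure(list(s = setNames(res$s0, kin$gene),
                       m = setNames(res$m0, kin$gene),
                       t = 0),
                  class = "cell_state")
  attr(st, "n_act") <- setNames(res$therm_act, kin$gene)
  attr(st, "n_rep") <- setNames(res$therm_rep, kin$gene)
  st
}

# shared wrapper around the compiled core
run_core <- function(kin, duration, do_therm = TRUE, record_events = FALSE,
                     state = NULL, with_commit = FALSE, beta0 = 0,
                     beta = NULL, rate_scale = 0, restart_on_commit = TRUE,
                     track_prob = FALSE) {
  if (is.null(state)) state <- cell_state(kin)
  if (is.null(beta)) beta <- rep(0, nrow(kin))
  .sim_core(kin$tau_act, kin$tau_rep, kin$tau_prod, kin$tau_dec, kin$delta,
            duration, as.integer(state$s), as.integer(state$m),
            do_therm, kin$therm_exempt, record_events,
            with_commit, beta0, beta, rate_scale, restart_on_commit,
            track_prob)
}

core_events <- function(res, genes) {
  data.frame(time = res$ev_time,
             gene = ifelse(is.na(res$ev_gene), "COMMIT", genes[res$ev_gene]),
             action = action_label(res$ev_action),
             new_m = res$ev_m, new_s = res$ev_s,
             stringsAsFactors = FALSE)
}

#' Simulate telegraph-model expression dynamics
#'
#' Thermalizes a cell (see [thermalize()]) and then runs the first-reaction
#' Gillespie loop for the stated duration. Genes evolve independently: no
#' gene influences another's rates. Time is accumulated per (gene,
#' multiplicity) state, so the fraction of simulated time spent at each
#' multiplicity is available through [occupancy()].
#'
#' @param kin kinetics table.
#' @param duration simulated time in hours (> 0).
#' @param seed optional RNG seed, recorded in the result.
#' @param therm logical; thermalize before the timed run (default `TRUE`).
#' @param record_events keep the full event log (default `TRUE`; disable for
#'   long scan runs where only occupancies are needed).
#' @return A `telegraph_trajectory`: list with `events` (data.frame: `time`,
#'   `gene`, `action`, `new_m`, `new_s`), `occupancy` (per-gene vector of
#'   hours spent at multiplicity 0, 1, ...), `initial_state` (post
#'   thermalization), `final_state`, `duration`, `kinetics`, `seed`.
#' @examples
#' kin <- gene_kinetics("g", tau_act = 5, tau_rep = 5, tau_prod = 1,
#'                      tau_dec = 2, delta = 6)
#' traj <- simulate_telegraph(kin, duration = 200, seed = 1)
#' occupancy(traj, "g")
#' @export
simulate_telegraph <- function(kin, duration, seed = NULL, therm = TRUE,
                               record_events = TRUE) {
  kin <- as_kinetics(kin)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stopf("duration must be a single positive number of hours")
  }
  res <- with_seed(seed, run_core(kin, duration, do_therm = therm,
                                  record_events = record_events))
  occ <- setNames(res$occupancy, kin$gene)
  structure(list(events = if (record_events) core_events(res, kin$gene) else NULL,
                 occupancy = occ,
                 initial_state = list(s = setNames(res$s0, kin$gene),
                                      m = setNames(res$m0, kin$gene), t = 0),
                 final_state = list(s = setNames(res$s, kin$gene),
                                    m = setNames(res$m, kin$gene),
                                    t = res$t_end),
                 duration = res$t_end,
                 kinetics = kin,
                 seed = seed),
            class = "telegraph_trajectory")
}

#' @export
print.telegraph_trajectory <- function(x, ...) {
  cat(sprintf("telegraph trajectory: %d gene(s), %.1f h, %s events\n",
              nrow(x$kinetics), x$duration,
              if (is.null(x$events)) "unrecorded" else nrow(x$events)))
  invisible(x)
}

#' Time-weighted multiplicity occupancy
#'
#' Returns the fraction of simulated time a gene spent at each mRNA
#' multiplicity; after a completed simulation this is the model's probability
#' of finding a cell in that state. Fractions sum to 1.
#'
#' @param traj a `telegraph_trajectory` (or `commitment_simulation`).
#' @param gene gene identifier.
#' @return Named numeric vector of probabilities over multiplicities
#'   `0, 1, ...`.
#' @export
occupancy <- function(traj, gene) {
  occ <- traj$occupancy[[gene]]
  if (is.null(occ)) stopf("unknown gene '%s'", gene)
  if (sum(occ) <= 0) stopf("trajectory has zero duration")
  setNames(occ / sum(occ), seq_along(occ) - 1L)
}

# Replay the event log from the post-thermalization initial state; used to
# verify the integer bookkeeping of the compiled loop.
replay_trajectory <- function(traj) {
  s <- traj$initial_state$s
  m <- traj$initial_state$m
  ev <- traj$events
  for (i in seq_len(nrow(ev))) {
    gene <- ev$gene[i]
    switch(ev$action[i],
           activate = { s[gene] <- 1L },
           repress = { s[gene] <- 0L },
           produce = { m[gene] <- m[gene] + 1L },
           decay = { m[gene] <- m[gene] - 1L },
           commit = { s[] <- NA_integer_; m[] <- NA_integer_ })
    if (ev$action[i] %in% c("activate", "repress")) {
      if (s[gene] != ev$new_s[i]) stopf("replay mismatch at event %d", i)
    }
    if (ev$action[i] %in% c("produce", "decay")) {
      if (m[gene] != ev$new_m[i]) stopf("replay mismatch at event %d", i)
    }
  }
  list(s = s, m = m)
}

# Time-weighted occupancy recomputed in R from an event log; independent
# cross-check of the compiled accumulation.
occupancy_from_events <- function(traj, gene) {
  ev <- traj$events
  m <- traj$initial_state$m[gene]
  t_prev <- 0
  w <- numeric(1)
  for (i in seq_len(nrow(ev))) {
    dt <- ev$time[i] - t_prev
    if (length(w) <= m) w <- c(w, numeric(m + 1 - length(w)))
    w[m + 1] <- w[m + 1] + dt
    t_prev <- ev$time[i]
    if (ev$gene[i] == gene && ev$action[i] %in% c("produce", "decay")) {
      m <- ev$new_m[i]
    }
  }
  dt <- traj$duration - t_prev
  if (length(w) <= m) w <- c(w, numeric(m + 1 - length(w)))
  w[m + 1] <- w[m + 1] + dt
  setNames(w / sum(w), seq_along(w) - 1L)
}

#' Stationary distribution of the telegraph model (master-equation oracle)
#'
#' Solves the truncated chemical master equation of the two-state telegraph
#' model — state space (promoter OFF/ON) x (multiplicity 0..`m_max`) — for
#' its stationary distribution and marginalizes over the promoter state.
#' This is an independent analytic route to the same law the Gillespie
#' simulator samples, used as a test oracle and by the synthetic-data
#' generator.
#'
#' Locked promoters are handled in closed form: locked OFF gives a point mass
#' at 0; locked ON gives the constitutive Poisson law with mean
#' `tau_dec / tau_prod`.
#'
#' @param kin kinetics table; with several rows, select one with `gene`.
#' @param gene gene identifier (required for multi-gene tables).
#' @param m_max truncation bound on multiplicity.
#' @param tol maximum tolerated truncation mass (probability at `m_max`).
#' @return Named numeric vector of stationary probabilities over
#'   multiplicities `0..m_max`.
#' @export
stationary_oracle <- function(kin, gene = NULL, m_max = 256, tol = 1e-8) {
  kin <- as_kinetics(kin)
  if (nrow(kin) > 1) {
    if (is.null(gene)) stopf("multi-gene kinetics: specify gene")
    kin <- kin[kin$gene == gene, , drop = FALSE]
    if (nrow(kin) == 0) stopf("unknown gene '%s'", gene)
  }
  tact <- kin$tau_act; trep <- kin$tau_rep
  tprod <- kin$tau_prod; tdec <- kin$tau_dec
  if (is.infinite(tact)) {
    p <- setNames(c(1, numeric(m_max)), 0:m_max)  # locked OFF: all mass at 0
    return(p)
  }
  if (is.infinite(trep)) {
    mu <- tdec / tprod  # constitutive limit: Poisson birth-death
    p <- dpois(0:m_max, mu)
    if (1 - sum(p) > tol || p[m_max + 1] > tol) {
      stopf("truncation mass above tolerance; increase m_max")
    }
    return(setNames(p / sum(p), 0:m_max))
  }
  ka <- 1 / tact; kr <- 1 / trep; kp <- 1 / tprod; kd <- 1 / tdec
  n <- m_max + 1L
  # index: OFF states 1..n (m = 0..m_max), ON states n+1..2n
  Q <- matrix(0, 2 * n, 2 * n)
  for (m in 0:m_max) {
    i_off <- m + 1L
    i_on <- n + m + 1L
    Q[i_off, i_on] <- Q[i_off, i_on] + ka
    Q[i_on, i_off] <- Q[i_on, i_off] + kr
    if (m < m_max) Q[i_on, i_on + 1L] <- Q[i_on, i_on + 1L] + kp
    if (m > 0) {
      Q[i_off, i_off - 1L] <- Q[i_off, i_off - 1L] + m * kd
      Q[i_on, i_on - 1L] <- Q[i_on, i_on - 1L] + m * kd
    }
  }
  diag(Q) <- -rowSums(Q)
  A <- t(Q)
  A[2 * n, ] <- 1  # replace one balance equation with normalization
  b <- c(numeric(2 * n - 1), 1)
  pi_full <- solve(A, b)
  pi_full[pi_full < 0 & pi_full > -1e-12] <- 0
  marg <- pi_full[1:n] + pi_full[(n + 1):(2 * n)]
  if (marg[n] > tol) {
    stopf("truncation mass %.3g above tolerance %.3g; increase m_max",
          marg[n], tol)
  }
  setNames(marg / sum(marg), 0:m_max)
}

#' Closed-form stationary mean multiplicity
#'
#' The stationary mean of the telegraph model: ON-state occupancy
#' `tau_rep / (tau_rep + tau_act)` times the constitutive mean
#' `tau_dec / tau_prod`.
#'
#' @inheritParams stationary_oracle
#' @return Mean mRNA multiplicity.
#' @export
stationary_mean <- function(kin, gene = NULL) {
  kin <- as_kinetics(kin)
  if (nrow(kin) > 1) {
    if (is.null(gene)) stopf("multi-gene kinetics: specify gene")
    kin <- kin[kin$gene == gene, , drop = FALSE]
  }
  p_on <- if (is.infinite(kin$tau_rep)) 1
          else if (is.infinite(kin$tau_act)) 0
          else kin$tau_rep / (kin$tau_rep + kin$tau_act)
  p_on * kin$tau_dec / kin$tau_prod
}

#' Write a trajectory event log or occupancy table to TSV
#'
#' @param traj a `telegraph_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(traj, path) {
  if (is.null(traj$events)) stopf("trajectory has no recorded events")
  write.table(traj$events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
write_occupancy <- function(traj, path) {
  rows <- do.call(rbind, lapply(names(traj$occupancy), function(g) {
    frac <- occupancy(traj, g)
    data.frame(gene = g, m = as.integer(names(frac)), fraction = as.numeric(frac))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
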