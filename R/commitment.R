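#' Train the logistic commitment classifier
#'
#' Maximum-likelihood logistic regression separating self-renewing (class 0)
#' from early-committed (class 1) cells on the expression of the selected
#' genes, giving the probability-of-commitment model
#' `p(g) = 1 / (1 + exp(-(beta0 + sum_i beta_i g_i)))`.
#'
#' Under perfect separation the unpenalized likelihood has no maximum; the
#' fit then falls back to a small ridge penalty (`ridge * sum(beta^2)` on the
#' log-likelihood scale) with a warning, keeping coefficients bounded.
#'
#' @param table expression table (see [expression_table()]).
#' @param genes genes used as classifier inputs (default the consensus
#'   commitment-associated trio Gata1, Gata2, Mpo).
#' @param class0,class1 population labels coded 0 and 1 (defaults SR, CP1).
#' @param ridge ridge coefficient for the perfect-separation fallback.
#' @return A `commitment_classifier`: list with `beta0`, named `beta`,
#'   `genes`, `converged`, `separation` (logical), and training `auc`.
#' @export
train_logistic <- function(table, genes = c("Gata1", "Gata2", "Mpo"),
                           class0 = "SR", class1 = "CP1", ridge = 1e-4) {
  missing_genes <- setdiff(genes, names(table))
  if (length(missing_genes) > 0) {
    stopf("genes not in table: %s", paste(missing_genes, collapse = ", "))
  }
  keep <- table$population %in% c(class0, class1)
  tab <- table[keep, , drop = FALSE]
  y <- as.integer(tab$population == class1)
  if (length(unique(y)) < 2) stopf("both classes must be present")
  if (min(table(y)) < 2) stopf("need at least 2 cells per class")
  X <- as.matrix(tab[, genes, drop = FALSE])

  fit <- suppressWarnings(glm(y ~ X, family = binomial()))
  cf <- coef(fit)
  # under (quasi-)complete separation the fitted probabilities collapse onto
  # the class indicator and the unpenalized likelihood has no maximum
  separated <- !fit$converged || anyNA(cf) ||
    all(abs(fit$fitted.values - y) < 1e-4)
  if (separated) {
    warnf("perfect or quasi-perfect separation detected; refitting with ridge penalty %g", ridge)
    cf <- ridge_logistic(X, y, ridge)
  }
  beta0 <- unname(cf[1])
  beta <- setNames(unname(cf[-1]), genes)
  prob <- plogis(beta0 + drop(X %*% beta))
  clf <- structure(list(beta0 = beta0, beta = beta, genes = genes,
                        converged = isTRUE(fit$converged) || separated,
                        separation = separated,
                        auc = auc_midrank(prob, y)),
                   class = "commitment_classifier")
  clf
}

# penalized logistic log-likelihood maximized by BFGS; penalty on slopes only
ridge_logistic <- function(X, y, ridge) {
  negll <- function(par) {
    z <- par[1] + drop(X %*% par[-1])
    -sum(y * z - log1p(exp(z))) + ridge * sum(par[-1]^2)
  }
  opt <- optim(rep(0, ncol(X) + 1), negll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  opt$par
}

#' @export
print.commitment_classifier <- function(x, ...) {
  cat(sprintf("commitment classifier: beta0 = %.4g; training AUC = %.3f\n",
              x$beta0, x$auc))
  print(x$beta)
  invisible(x)
}

#' Commitment probability for an expression state
#'
#' Evaluates the trained logistic model `1/(1 + exp(-(beta0 + sum beta_i
#' g_i)))` at one or more expression vectors.
#'
#' @param clf a `commitment_classifier`.
#' @param g named numeric vector of expression values, or a matrix /
#'   data.frame with one column per gene (must cover `clf$genes`).
#' @return Probabilities in `[0, 1]`.
#' @export
classifier_probability <- function(clf, g) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
  g <- as.matrix(g)
  missing_genes <- setdiff(clf$genes, colnames(g))
  if (length(missing_genes) > 0) {
    stopf("expression vector lacks gene(s): %s", paste(missing_genes, collapse = ", "))
  }
  z <- clf$beta0 + drop(g[, clf$genes, drop = FALSE] %*% clf$beta)
  plogis(z)
}

#' Mean classifier probability under the thermalized expression process
#'
#' Time-weighted average of the commitment probability over a commitment-free
#' telegraph simulation, assuming expression has thermalized at the start of
#' observation. This expectation normalizes the expression-specific
#' commitment rate (see [expression_commitment_rate()]) so that the overall
#' rate equals the configured `c`.
#'
#' @param clf a `commitment_classifier`.
#' @param kin kinetics table covering the classifier genes.
#' @param duration averaging duration in hours (default 15000).
#' @param seed optional RNG seed.
#' @return Scalar `p_bar` with attributes `duration` and `seed`.
#' @export
mean_probability <- function(clf, kin, duration = 15000, seed = NULL) {
  kin <- as_kinetics(kin)
  beta <- classifier_beta_for(clf, kin)
  res <- with_seed(seed, run_core(kin, duration, do_therm = TRUE,
                                  record_events = FALSE, with_commit = FALSE,
                                  beta0 = clf$beta0, beta = beta,
                                  track_prob = TRUE))
  structure(res$prob_integral / duration, duration = duration, seed = seed)
}

# classifier weights aligned to the kinetics gene order (0 for unused genes)
classifier_beta_for <- function(clf, kin) {
  missing_genes <- setdiff(clf$genes, kin$gene)
  if (length(missing_genes) > 0) {
    stopf("kinetics table lacks classifier gene(s): %s",
          paste(missing_genes, collapse = ", "))
  }
  beta <- setNames(rep(0, nrow(kin)), kin$gene)
  beta[clf$genes] <- clf$beta
  unname(beta)
}

#' Expression-specific commitment rate
#'
#' The commitment hazard as a function of expression:
#' `lambda(g) = c * p(g) / p_bar`, proportional to the classifier probability
#' and normalized so that its average over the thermalized expression process
#' equals the overall commitment rate `c` inferred from culture kinetics.
#'
#' @param clf a `commitment_classifier`.
#' @param g expression vector or matrix (see [classifier_probability()]).
#' @param c overall commitment rate per hour (> 0).
#' @param p_bar mean classifier probability (see [mean_probability()]).
#' @return Commitment rate(s) per hour.
#' @export
expression_commitment_rate <- function(clf, g, c, p_bar) {
  if (!is.numeric(c) || c <= 0) stopf("overall commitment rate c must be positive")
  if (!is.numeric(p_bar) || p_bar <= 0 || p_bar > 1) {
    stopf("p_bar must lie in (0, 1]")
  }
  c * classifier_probability(clf, g) / as.numeric(p_bar)
}

#' Simulate telegraph dynamics with stochastic commitment
#'
#' Runs the first-reaction loop with an additional commitment channel whose
#' waiting time is exponential with the state-dependent rate
#' `lambda(g) = c * p(g) / p_bar`. The commitment clock is redrawn after
#' every executed event; because the hazard is piecewise constant between
#' events, the memoryless redraw samples the exact law. At each commitment
#' the state immediately before the event is recorded as an in-silico
#' committed cell and (by default) a fresh thermalized cell continues the
#' time-course, so one long run yields a population of committed-cell
#' snapshots. With `restart = FALSE` the run is absorbing and ends at the
#' first commitment.
#'
#' @param kin kinetics table.
#' @param clf a `commitment_classifier`.
#' @param c overall commitment rate per hour.
#' @param duration simulated time in hours.
#' @param p_bar mean classifier probability; computed via
#'   [mean_probability()] (at `p_bar_duration` hours, derived seed) when
#'   `NULL`.
#' @param seed optional RNG seed, recorded in the result.
#' @param restart restart a fresh thermalized cell after each commitment
#'   (default `TRUE`).
#' @param record_events keep the full event log (default `FALSE`).
#' @param p_bar_duration averaging duration for `p_bar` when computed here.
#' @return A `commitment_simulation`: list with `commitments` (data.frame:
#'   `time`, `probability_at_commit`, per-gene multiplicity `m_*`, expression
#'   `g_*` and promoter state `s_*` at the moment of transition),
#'   `n_events`, `frequency` (events per hour), `duration`, `occupancy`,
#'   `p_bar`, `c`, `events` (if recorded), `kinetics`, `seed`.
#' @export
simulate_commitment <- function(kin, clf, c, duration, p_bar = NULL,
                                seed = NULL, restart = TRUE,
                                record_events = FALSE,
                                p_bar_duration = 15000) {
  kin <- as_kinetics(kin)
  if (!is.numeric(c) || c <= 0) stopf("overall commitment rate c must be positive")
  if (is.null(p_bar)) {
    p_bar <- mean_probability(clf, kin, duration = p_bar_duration,
                              seed = derive_seed(seed, 1L) %||% NULL)
  }
  if (as.numeric(p_bar) <= 0) stopf("p_bar must be positive")
  beta <- classifier_beta_for(clf, kin)
  res <- with_seed(seed, run_core(kin, duration, do_therm = TRUE,
                                  record_events = record_events,
                                  with_commit = TRUE, beta0 = clf$beta0,
                                  beta = beta,
                                  rate_scale = c / as.numeric(p_bar),
                                  restart_on_commit = restart,
                                  track_prob = TRUE))
  k <- length(res$commit_time)
  gmat <- res$commit_m
  if (k > 0) {
    gmat <- vapply(seq_len(nrow(kin)),
                   function(i) multiplicity_to_g(res$commit_m[, i], kin$delta[i]),
                   numeric(k))
    gmat <- matrix(gmat, nrow = k)
  }
  commitments <- data.frame(time = res$commit_time,
                            probability_at_commit = res$commit_prob)
  for (i in seq_len(nrow(kin))) {
    commitments[[paste0("m_", kin$gene[i])]] <- res$commit_m[, i]
    commitments[[paste0("g_", kin$gene[i])]] <-
      if (k > 0) gmat[, i] else numeric(0)
    commitments[[paste0("s_", kin$gene[i])]] <- res$commit_s[, i]
  }
  structure(list(commitments = commitments,
                 n_events = k,
                 frequency = k / res$t_end,
                 duration = res$t_end,
                 occupancy = setNames(res$occupancy, kin$gene),
                 p_bar = as.numeric(p_bar),
                 c = c,
                 mean_probability_observed = res$prob_integral / res$t_end,
                 events = if (record_events) core_events(res, kin$gene) else NULL,
                 kinetics = kin,
                 seed = seed),
            class = "commitment_simulation")
}

#' @export
print.commitment_simulation <- function(x, ...) {
  cat(sprintf("commitment simulation: %d events in %.0f h (frequency %.3g/h; c = %.3g/h)\n",
              x$n_events, x$duration, x$frequency, x$c))
  invisible(x)
}

#' Commitment frequency
#'
#' Number of commitment events per hour of Gillespie time.
#'
#' @param events a `commitment_simulation`, its `commitments` data.frame, or
#'   an event count.
#' @param duration simulated duration in hours (taken from the simulation
#'   object if one is supplied).
#' @return Events per hour.
#' @export
commitment_frequency <- function(events, duration = NULL) {
  if (inherits(events, "commitment_simulation")) {
    duration <- duration %||% events$duration
    events <- events$n_events
  }
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  if (is.null(duration) || duration <= 0) stopf("duration must be positive")
  n / duration
}

#' Read or write a commitment classifier (JSON)
#'
#' JSON dialect: `{"genes": [...], "beta0": x, "beta": [...]}`.
#'
#' @param path file path.
#' @return `read_classifier()` returns a `commitment_classifier`.
#' @export
read_classifier <- function(path) {
  rec <- jsonlite::fromJSON(path)
  structure(list(beta0 = rec$beta0,
                 beta = setNames(as.numeric(rec$beta), rec$genes),
                 genes = rec$genes,
                 converged = TRUE, separation = FALSE,
                 auc = rec$auc %||% NA_real_),
            class = "commitment_classifier")
}

#' @rdname read_classifier
#' @param clf classifier to write.
#' @export
write_classifier <- function(clf, path) {
  jsonlite::write_json(list(genes = clf$genes, beta0 = clf$beta0,
                            beta = unname(clf$beta), auc = clf$auc),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write commitment-event snapshots to TSV
#'
#' @param sim a `commitment_simulation`.
#' @param path output file.
#' @export
write_commitment_events <- function(sim, path) {
  write.table(sim$commitments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
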