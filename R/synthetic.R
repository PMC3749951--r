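#' Default synthetic gene archetypes
#'
#' Three synthetic genes covering the qualitative regimes of transcriptional
#' bursting seen in hematopoietic progenitors, named after the genes whose
#' regimes they emulate (the numeric values are implementation choices for
#' fixture generation, not fitted values):
#'
#' * `Gata1` — short, infrequent bursts: long OFF dwell, short ON dwell;
#'   expression mostly undetected with bursty tails.
#' * `Gata2` — short but frequent bursts with high mRNA production.
#' * `Mpo` — very long ON dwell relative to OFF: near-constitutive
#'   expression, with OFF dwells long enough that expression occasionally
#'   decays below detection.
#'
#' Burst time scales are of order a few to tens of hours and mRNA lifetimes
#' about two hours, in the range reported for mammalian genes. Within each
#' regime the values were chosen so that burst durations are comparable to
#' or longer than the mRNA lifetime, which keeps all three fitted time
#' scales identifiable from a static expression histogram (the within-burst
#' expression level is then resolved, separating production time from burst
#' duration).
#'
#' @return A kinetics table with three rows.
#' @export
default_archetypes <- function() {
  rbind(
    gene_kinetics("Gata1", tau_act = 30, tau_rep = 5, tau_prod = 0.4,
                  tau_dec = 2, delta = 9),
    gene_kinetics("Gata2", tau_act = 6, tau_rep = 3, tau_prod = 0.25,
                  tau_dec = 2, delta = 7),
    gene_kinetics("Mpo", tau_act = 5, tau_rep = 15, tau_prod = 0.5,
                  tau_dec = 2.5, delta = 6.5))
}

#' Default kinetics shifts emulating the early-committed population
#'
#' Multiplicative changes applied to the self-renewal kinetics to generate
#' the early-committed (CP1) population: more frequent bursting of the
#' Gata factors (shorter `tau_act`) and reduced Mpo output (longer
#' `tau_prod`), mirroring the direction of expression change across the
#' commitment boundary (Gata2 and Gata1 up, Mpo down).
#'
#' @return Named list: per gene, a named vector of parameter multipliers.
#' @export
default_cp_shift <- function() {
  list(Gata1 = c(tau_act = 0.4),
       Gata2 = c(tau_act = 0.25),
       Mpo = c(tau_prod = 3))
}

apply_kinetics_shift <- function(kin, shift) {
  for (gene in names(shift)) {
    idx <- match(gene, kin$gene)
    if (is.na(idx)) stopf("shift refers to unknown gene '%s'", gene)
    for (par in names(shift[[gene]])) {
      kin[[par]][idx] <- kin[[par]][idx] * shift[[gene]][[par]]
    }
  }
  validate_kinetics(kin)
  kin
}

# draw n iid multiplicities from a gene's stationary law
sample_stationary <- function(kin, gene, n, m_max = 256) {
  p <- stationary_oracle(kin, gene = gene, m_max = m_max)
  sample(seq_along(p) - 1L, n, replace = TRUE, prob = p)
}

#' Generate a synthetic single-cell expression table
#'
#' Emulates a single-cell qPCR study of the commitment boundary: SR cells
#' are drawn per gene from the telegraph stationary distribution (via the
#' master-equation oracle, matching the thermalization assumption) and
#' mapped through the expression scale; CP1 cells are drawn from shifted
#' kinetics. Genes are sampled independently within each population,
#' matching the absence of detectable gene-gene correlation in the
#' self-renewing compartment.
#'
#' @param kin SR kinetics table (default [default_archetypes()]).
#' @param n_sr,n_cp1 population sizes (defaults 100 cells each, the scale of
#'   single-cell qPCR studies).
#' @param cp_shift kinetics shifts for the CP1 population (see
#'   [default_cp_shift()]); `NULL` for identically distributed populations.
#' @param seed RNG seed, recorded in the result's `seed` attribute.
#' @param m_max truncation bound for the stationary oracle.
#' @return Expression table (see [expression_table()]) with populations
#'   `SR` and `CP1`; attributes `seed` and `cp_kinetics`.
#' @export
gen_expression_table <- function(kin = default_archetypes(), n_sr = 100,
                                 n_cp1 = 100, cp_shift = default_cp_shift(),
                                 seed = NULL, m_max = 256) {
  kin <- as_kinetics(kin)
  kin_cp <- if (is.null(cp_shift)) kin else apply_kinetics_shift(kin, cp_shift)
  with_seed(seed, {
    draw_pop <- function(k, n) {
      vals <- vapply(k$gene, function(g) {
        m <- sample_stationary(k, g, n, m_max)
        multiplicity_to_g(m, k$delta[match(g, k$gene)])
      }, numeric(n))
      matrix(vals, nrow = n, dimnames = list(NULL, k$gene))
    }
    sr <- draw_pop(kin, n_sr)
    cp <- draw_pop(kin_cp, n_cp1)
    tab <- expression_table(rbind(sr, cp),
                            population = c(rep("SR", n_sr), rep("CP1", n_cp1)))
    attr(tab, "seed") <- seed
    attr(tab, "cp_kinetics") <- kin_cp
    tab
  })
}

#' Generate synthetic clonal culture counts
#'
#' Evaluates the closed-form compartment and dead-cell solutions at
#' 0/24/48 h for an SR-seeded assay (`R0 = n0`, `P0 = 0`) and a CP-seeded
#' assay (`P0 = n0`), applies multiplicative log-normal noise with the given
#' coefficient of variation, and rounds to integer counts.
#'
#' @param rates a [population_rates()] object.
#' @param noise_cv coefficient of variation of the multiplicative count
#'   noise (0 = noise-free).
#' @param seed RNG seed.
#' @param n0 seeded cell count per assay.
#' @param times observation times in hours.
#' @param integer_counts round to integers (default `TRUE`; disable for
#'   noise-free round-trip checks at solver precision).
#' @return data.frame with both assays stacked (columns `assay`, `time_h`,
#'   `live`, `dead`).
#' @export
gen_culture_counts <- function(rates, noise_cv = 0.05, seed = NULL, n0 = 100,
                               times = c(0, 24, 48), integer_counts = TRUE) {
  stopifnot(inherits(rates, "population_rates"))
  with_seed(seed, {
    noisy <- function(x) {
      if (noise_cv <= 0) return(x)
      sdlog <- sqrt(log(1 + noise_cv^2))
      x * rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    mk <- function(assay, R0, P0) {
      ev <- evolve_population(R0, P0, times, rates = rates)
      live <- ev$R + ev$P
      dead <- dead_cells(rates, R0, P0, D0 = 0, t = times)
      live[times > 0] <- noisy(live[times > 0])
      dead[times > 0] <- noisy(dead[times > 0])
      if (integer_counts) { live <- round(live); dead <- round(dead) }
      data.frame(assay = assay, time_h = times, live = live, dead = dead,
                 stringsAsFactors = FALSE)
    }
    rbind(mk("SR-seeded", n0, 0), mk("CP-seeded", 0, n0))
  })
}

#' Write the canonical synthetic test bundle
#'
#' Deterministically regenerates the package's reference fixtures in `dir`:
#' a synthetic expression table (`expression.tsv`), clonal culture counts
#' (`counts.tsv`), the generating kinetics (`kinetics.json`), a classifier
#' trained on the synthetic populations (`classifier.json`) and the
#' generating population rates (`rates.json`). Regeneration with the same
#' seed is bit-identical; all files carry their seed in a header or field.
#'
#' The generating population rates are anchored on clonal culture
#' observations of multipotent progenitors: mean SR division time of one
#' day, about 5% of SR cells committing per division time, and roughly 10%
#' CP among live cells at long times.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @return Named character vector of file paths, invisibly.
#' @export
reference_fixtures <- function(dir, seed = 4242) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kin <- default_archetypes()
  rates <- reference_population_rates()
  tab <- gen_expression_table(kin, seed = derive_seed(seed, 1L))
  counts <- gen_culture_counts(rates, noise_cv = 0.05,
                               seed = derive_seed(seed, 2L))
  clf <- train_logistic(tab, genes = kin$gene)
  hdr <- function(what) c(sprintf("telecommit synthetic fixture: %s", what),
                          sprintf("seed: %d", seed))
  paths <- c(expression = file.path(dir, "expression.tsv"),
             counts = file.path(dir, "counts.tsv"),
             kinetics = file.path(dir, "kinetics.json"),
             classifier = file.path(dir, "classifier.json"),
             rates = file.path(dir, "rates.json"))
  write_expression_table(tab, paths["expression"], header = hdr("expression table"))
  write_culture_counts(counts, paths["counts"], header = hdr("culture counts"))
  write_kinetics(kin, paths["kinetics"])
  write_classifier(clf, paths["classifier"])
  jsonlite::write_json(c(unclass(rates), list(seed = seed)), paths["rates"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# Population rates anchored on the printed culture observations: SR division
# time 1 day (s = 1/24), 5% of SR cells commit per division time
# (c = 0.05 s), 10% asymptotic CP fraction fixing rho - rho_p = 9 c, and a
# modest death load in both compartments.
reference_population_rates <- function() {
  s <- 1 / 24
  c <- 0.05 * s
  d <- 0.1 * s
  rho <- s - d - c
  rho_p <- rho - 9 * c
  d_p <- 0.15 * s
  population_rates(s = s, d = d, c = c, s_p = rho_p + d_p, d_p = d_p)
}
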