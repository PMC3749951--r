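# telecommit

Stochastic simulation of transcriptional bursting and lineage commitment in
multipotent hematopoietic progenitor cells.

Single-cell qPCR snapshots of a progenitor population show which expression
states exist, but not how cells move between them or which states precede the
rare, transient transition into lineage commitment. `telecommit` turns static
snapshots into dynamics: it simulates each gene as an independent random
telegraph unit (promoter switching OFF/ON with mean dwell times `tau_act`,
`tau_rep`; mRNA produced every `tau_prod` hours while ON; decaying with mean
lifetime `tau_dec`) with the first-reaction Gillespie algorithm, fits those
kinetic parameters to observed single-cell expression histograms by simulated
annealing plus local grid search, and layers on an expression-dependent
commitment hazard

    lambda(g) = c · p(g) / p̄ ,    p(g) = 1 / (1 + exp(−(β₀ + Σᵢ βᵢ gᵢ)))

where `p(g)` is a logistic classifier trained to separate self-renewing (SR)
from early-committed (CP1) cells, `p̄` is the time-average of `p` over the
thermalized expression process, and `c` is the overall commitment rate per
hour inferred from a two-compartment model of clonal culture counts (SR cells
divide, die, and commit; CP cells divide and die; closed-form solutions and
a ~10% long-time CP fraction pin the rates). Simulated cells are captured at
the instant of commitment, and perturbation protocols (parameter multipliers,
permanent promoter locks) predict how regulatory changes shift commitment
frequency.

The package is aimed at computational biologists studying stochastic cell
fate decisions who have static single-cell expression data and bulk culture
kinetics, and want a mechanistic, simulation-based bridge between the two.

## Worked example

Everything below is reproducible offline: the synthetic-data module generates
a study-shaped dataset (three gene archetypes mirroring the bursting regimes
of Gata1, Gata2 and Mpo; clonal culture counts from the compartment model).

```r
library(telecommit)

kin <- default_archetypes()
tab <- gen_expression_table(kin, seed = 1)        # 100 SR + 100 CP1 cells
counts <- gen_culture_counts(
  telecommit:::reference_population_rates(), noise_cv = 0.05, seed = 2)

## 1. overall commitment rate from culture kinetics
rates <- infer_population_rates(counts)
print(rates)
#> population rates (/h): s=0.04155 d=0.003892 c=0.002086 s'=0.0229 d'=0.006097 (rho=0.03558, rho'=0.0168)

## 2. commitment probability from the SR/CP1 classifier
clf <- train_logistic(tab)                        # genes Gata1, Gata2, Mpo
print(clf)
#> commitment classifier: beta0 = -1.896; training AUC = 0.849
#>       Gata1       Gata2         Mpo
#>  0.08232923  0.38703222 -0.22268005

## 3. commitment-capable simulation, normalized to c
p_bar <- mean_probability(clf, kin, duration = 15000, seed = 3)
sim <- simulate_commitment(kin, clf, c = rates$c, duration = 30000,
                           p_bar = as.numeric(p_bar), seed = 4)
print(sim)
#> commitment simulation: 68 events in 30000 h (frequency 0.00227/h; c = 0.00209/h)
head(sim$commitments[, c("time", "probability_at_commit", "g_Gata1", "g_Gata2", "g_Mpo")], 3)
#>         time probability_at_commit g_Gata1  g_Gata2    g_Mpo
#> 1   82.15362             0.8471419       0 9.321928 0.000000
#> 2  446.91365             0.4373045       0 9.321928 8.821928
#> 3 1018.52272             0.6113081       0 9.807355 6.500000
```

Reading the output: the inferred rates say an SR cell divides about once a
day (`1/s ≈ 24 h`) and commits at `c ≈ 0.002/h`, i.e. roughly 5% of SR cells
commit per division time, with the long-run CP fraction settling at 10%. The
classifier weights say commitment probability rises with Gata2 and falls
with Mpo expression. The simulation then realizes commitment as a stochastic
point process whose empirical frequency (0.00227 events per hour over
30000 h, 68 events) matches the configured rate, and `sim$commitments` holds the
expression state of each in-silico cell at its moment of transition —
the committed cells concentrate where the classifier probability is high,
but low-probability commitments still occur.

Fitting kinetics to a histogram and scanning perturbations:

```r
target <- build_histogram(tab$Gata2[tab$population == "SR"], bin_width = 0.5)
fit <- anneal_fit(target, tau_dec = 2, config = fit_config(seed = 5),
                  gene = "Gata2")
fit <- grid_refine(fit, target)

scan <- perturbation_scan(kin, clf, c = rates$c, p_bar = as.numeric(p_bar),
                          duration = 30000, seed = 6)   # Fig-style 0.2–3.5x scan
locked <- lock_promoter(kin, "Gata1", "ON")              # permanent activation
```

A command-line interface wraps the same functions
(`exec/telecommit simulate|commit-sim|infer-rates|fit|screen|synth`).

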