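# shared helpers for the telecommit test suite

# total variation distance between two probability vectors indexed from 0,
# padding the shorter with zeros
tv_dist <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(as.numeric(p), numeric(n - length(p)))
  q <- c(as.numeric(q), numeric(n - length(q)))
  0.5 * sum(abs(p - q))
}

# a fast-mixing single gene used where the test only needs "some" dynamics
toy_gene <- function(gene = "g", delta = 6) {
  gene_kinetics(gene, tau_act = 4, tau_rep = 4, tau_prod = 0.5, tau_dec = 2,
                delta = delta)
}

# small two-population expression table with a known separating gene
toy_table <- function() {
  expression_table(
    data.frame(A = c(0, 0, 1, 0.5, 9, 10, 10, 8.5),
               B = c(3, 4, 5, 3.5, 4, 3, 5, 4.5)),
    population = c(rep("SR", 4), rep("CP1", 4)))
}

# direct Spearman rho via the classical rank-difference formula (distinct
# ranks assumed): 1 - 6 sum d^2 / (n (n^2 - 1))
spearman_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# brute-force AUC by enumerating all class0 x class1 pairs (ties count 1/2)
auc_bruteforce <- function(x0, x1) {
  conc <- 0
  for (a in x0) for (b in x1) {
    conc <- conc + if (b > a) 1 else if (b == a) 0.5 else 0
  }
  conc / (length(x0) * length(x1))
}
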