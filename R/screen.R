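#' Filtered Spearman co-expression network
#'
#' For every gene pair within one population, restricts to cells expressing
#' both genes (`g > 0` in both), skips pairs with fewer than `min_cells` such
#' cells, computes the Spearman rank correlation and its p-value on the
#' co-expressing cells, and emits an edge when `|rho| > cutoff` at
#' significance `alpha`. With a small number of assayed genes and no true
#' interactions, the expected number of emitted edges is roughly
#' `alpha` times the number of tested pairs.
#'
#' P-values use the t-distribution approximation (two-sided); set
#' `exact = TRUE` for the exact permutation null on small samples.
#'
#' @param table expression table (see [expression_table()]).
#' @param population population label to analyze.
#' @param min_cells minimum number of co-expressing cells (default 10).
#' @param cutoff absolute correlation cutoff (default 0.3); applied to
#'   `|rho|` so negative interactions are retained.
#' @param alpha significance level (default 0.01, i.e. the 99% level).
#' @param exact use the exact permutation distribution for p-values.
#' @return data.frame of edges: `gene_a`, `gene_b`, `rho`, `p`,
#'   `n_coexpressing`; zero rows when no pair passes all three filters.
#' @export
spearman_network <- function(table, population, min_cells = 10, cutoff = 0.3,
                             alpha = 0.01, exact = FALSE) {
  tab <- table[table$population %in% population, , drop = FALSE]
  if (nrow(tab) == 0) stopf("population '%s' not present in table", population)
  genes <- table_genes(tab)
  if (length(genes) < 2) stopf("need at least 2 genes")
  pairs <- combn(genes, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    co <- tab[[a]] > 0 & tab[[b]] > 0
    n <- sum(co)
    if (n < min_cells) next
    ct <- suppressWarnings(
      cor.test(tab[[a]][co], tab[[b]][co], method = "spearman",
               exact = exact, alternative = "two.sided"))
    if (!is.finite(ct$estimate)) next
    if (abs(ct$estimate) > cutoff && ct$p.value < alpha) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, rho = unname(ct$estimate),
        p = ct$p.value, n_coexpressing = n, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      rho = numeric(0), p = numeric(0),
                      n_coexpressing = integer(0)))
  }
  do.call(rbind, rows)
}

# midrank AUC of `score` for predicting label == 1
auc_midrank <- function(score, label) {
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  r <- rank(score)  # midranks handle ties
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Single-gene ROC AUC between two populations
#'
#' Rank-based area under the ROC curve of one gene's expression as a score
#' for membership in `class1`, with ties handled by midranks: equal to the
#' probability that a random `class1` cell out-expresses a random `class0`
#' cell (ties counting one half). 1 is perfect separation, 0.5 no better
#' than random.
#'
#' @param table expression table.
#' @param gene gene to score.
#' @param class0,class1 population labels (defaults SR vs CP1).
#' @return AUC in `[0, 1]`; a gene constant across both classes returns 0.5
#'   with a warning.
#' @export
single_gene_auc <- function(table, gene, class0 = "SR", class1 = "CP1") {
  if (!gene %in% names(table)) stopf("unknown gene '%s'", gene)
  keep <- table$population %in% c(class0, class1)
  tab <- table[keep, , drop = FALSE]
  label <- as.integer(tab$population == class1)
  if (sum(label == 0) == 0 || sum(label == 1) == 0) {
    stopf("both classes must be non-empty")
  }
  x <- tab[[gene]]
  if (length(unique(x)) == 1) {
    warnf("gene '%s' is constant across both classes; AUC = 0.5", gene)
    return(0.5)
  }
  auc_midrank(x, label)
}

#' Write a correlation edge list to TSV
#'
#' @param edges data.frame from [spearman_network()].
#' @param path output file.
#' @export
write_edges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
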