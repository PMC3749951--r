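#' Map raw qPCR-style cycle values to the transformed expression scale
#'
#' Raw single-cell qPCR values (cycles to detection, relative to a reference)
#' decrease with transcript abundance; the transformed variable
#' `g = detection_limit - raw` (floored at 0) grows with abundance instead.
#' Values at or beyond the detection limit are undetected and map to `g = 0`.
#'
#' @param raw reference-normalized cycle values (non-negative).
#' @param detection_limit experimental detection limit in cycles (default 30).
#' @return Numeric vector of expression values on the `g` scale, in
#'   `[0, detection_limit]`.
#' @export
raw_to_g <- function(raw, detection_limit = 30) {
  if (any(raw < 0, na.rm = TRUE)) stopf("raw cycle values must be non-negative")
  pmax(detection_limit - raw, 0)
}

#' Map mRNA multiplicity to the expression scale
#'
#' Under ideal amplification, abundances double every cycle and a single
#' molecule is eventually detected, so `m` molecules read out as
#' `g = delta + log2(m)`, where `delta` is a gene-specific shift absorbing
#' detection threshold and amplification efficiency (fitted together with the
#' kinetic rates). `m = 0` is undetected (`g = 0`), as are mapped values that
#' fall at or below 0.
#'
#' @param m integer mRNA multiplicities (non-negative).
#' @param delta gene-specific shift in cycle units.
#' @return Numeric vector of expression values `g`.
#' @export
multiplicity_to_g <- function(m, delta) {
  if (any(m < 0, na.rm = TRUE)) stopf("multiplicities must be non-negative")
  g <- ifelse(m >= 1, delta + log2(m), 0)
  pmax(g, 0)
}

#' Bin expression values into a normalized histogram
#'
#' Builds the binned frequency distribution used by the fitting objective: an
#' explicit `undetected` bin (`g = 0`) plus uniform bins of width `bin_width`
#' covering `(0, span]`. Frequencies sum to 1. Values above `span` are
#' saturated into the top bin.
#'
#' @param g expression values on the transformed scale (0 = undetected).
#' @param bin_width bin width in cycle units (default 1, the natural unit of
#'   the doubling scale).
#' @param span detection span in cycle units (default 30).
#' @return A `g_histogram`: named numeric vector of frequencies with first
#'   element `undetected`, and attributes `bin_width` and `span`.
#' @export
build_histogram <- function(g, bin_width = 1, span = 30) {
  if (length(g) == 0) stopf("no expression values to histogram")
  if (!is.numeric(bin_width) || bin_width <= 0) stopf("bin_width must be positive")
  if (any(g < 0, na.rm = TRUE)) stopf("expression values must be non-negative")
  n_bins <- ceiling(span / bin_width)
  idx <- ifelse(g <= 0, 0L, pmin(ceiling(g / bin_width), n_bins))
  counts <- tabulate(idx + 1L, nbins = n_bins + 1L)
  freq <- counts / sum(counts)
  structure(setNames(freq, histogram_bin_names(bin_width, n_bins)),
            bin_width = bin_width, span = span, class = "g_histogram")
}

histogram_bin_names <- function(bin_width, n_bins) {
  upper <- bin_width * seq_len(n_bins)
  c("undetected", sprintf("(%g,%g]", upper - bin_width, upper))
}

# Push a multiplicity occupancy/probability vector (index m = 0, 1, ...)
# through the expression map onto the binned g scale.
occupancy_to_histogram <- function(occ, delta, bin_width = 1, span = 30) {
  m <- seq_along(occ) - 1L
  w <- as.numeric(occ) / sum(occ)
  g <- multiplicity_to_g(m, delta)
  n_bins <- ceiling(span / bin_width)
  idx <- ifelse(g <= 0, 0L, pmin(ceiling(g / bin_width), n_bins))
  freq <- vapply(0:n_bins, function(k) sum(w[idx == k]), numeric(1))
  structure(setNames(freq, histogram_bin_names(bin_width, n_bins)),
            bin_width = bin_width, span = span, class = "g_histogram")
}

#' Assemble a single-cell expression table
#'
#' The container for single-cell expression data: one row per cell, one
#' column per gene (values on the `g` scale, 0 = undetected), a `cell`
#' identifier column and a `population` label column with labels from
#' SR / CP1 / CP2 / Ediff (or `NA` for unlabeled cells).
#'
#' @param values numeric matrix or data.frame, cells x genes.
#' @param population character vector of population labels, one per cell.
#' @param cell optional cell identifiers (default `cell_1, ...`).
#' @return A data.frame with columns `cell`, `population`, then one per gene.
#' @export
expression_table <- function(values, population, cell = NULL) {
  values <- as.data.frame(values)
  if (is.null(colnames(values))) stopf("gene columns must be named")
  if (length(population) != nrow(values)) {
    stopf("population labels must match the number of cells")
  }
  allowed <- c("SR", "CP1", "CP2", "Ediff")
  bad <- setdiff(unique(population[!is.na(population)]), allowed)
  if (length(bad) > 0) {
    stopf("unknown population label(s): %s", paste(bad, collapse = ", "))
  }
  if (is.null(cell)) cell <- paste0("cell_", seq_len(nrow(values)))
  cbind(data.frame(cell = cell, population = population,
                   stringsAsFactors = FALSE),
        values)
}

table_genes <- function(table) setdiff(names(table), c("cell", "population"))

#' Read or write an expression table (TSV)
#'
#' TSV dialect: first column `cell`, optional `population` column, remaining
#' columns one per gene; 0 = undetected. Lines starting with `#` are header
#' comments (provenance) and are skipped on read.
#'
#' @param path file path.
#' @return `read_expression_table()` returns the expression data.frame.
#' @export
read_expression_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!"cell" %in% names(tab)) stopf("expression table must have a 'cell' column")
  if (!"population" %in% names(tab)) tab$population <- NA_character_
  tab[, c("cell", "population", setdiff(names(tab), c("cell", "population")))]
}

#' @rdname read_expression_table
#' @param table expression table to write.
#' @param header optional character vector of `#`-prefixed provenance lines.
#' @export
write_expression_table <- function(table, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  suppressWarnings(
    write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}
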