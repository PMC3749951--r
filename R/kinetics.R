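#' Telegraph-model kinetics for one gene
#'
#' Constructs a one-row kinetics table describing the random telegraph model
#' of transcriptional bursting for a single gene: the promoter alternates
#' between an OFF state (mean dwell `tau_act` hours before activation) and an
#' ON state (mean dwell `tau_rep` hours before repression); while ON, one mRNA
#' is produced every `tau_prod` hours on average, and each mRNA molecule lives
#' `tau_dec` hours on average regardless of promoter state. `delta` is the
#' gene-specific shift mapping mRNA multiplicity onto the measured expression
#' scale (see [multiplicity_to_g()]).
#'
#' `tau_act` or `tau_rep` may be `Inf`, describing a promoter locked ON or OFF
#' (see [lock_promoter()]); `tau_prod` and `tau_dec` must be finite. `tau_dec`
#' is treated as a fixed (literature-derived) parameter throughout the fitting
#' machinery; the `tau_dec_fixed` flag records this.
#'
#' @param gene gene identifier.
#' @param tau_act,tau_rep,tau_prod,tau_dec kinetic time scales in hours
#'   (all strictly positive; `tau_act`/`tau_rep` may be `Inf`).
#' @param delta expression shift in cycle units.
#' @param therm_exempt logical; waive the thermalization requirement for this
#'   gene (set automatically by [lock_promoter()]).
#' @param tau_dec_fixed logical flag recording that decay is not fitted.
#' @return A one-row `data.frame` of class `gene_kinetics`; rows can be
#'   combined with `rbind()` into a multi-gene kinetics table.
#' @examples
#' kin <- rbind(
#'   gene_kinetics("Gata1", tau_act = 9, tau_rep = 1, tau_prod = 0.4,
#'                 tau_dec = 3, delta = 9),
#'   gene_kinetics("Mpo", tau_act = 2, tau_rep = 200, tau_prod = 0.4,
#'                 tau_dec = 4, delta = 6))
#' @export
gene_kinetics <- function(gene, tau_act, tau_rep, tau_prod, tau_dec,
                          delta = 0, therm_exempt = FALSE,
                          tau_dec_fixed = TRUE) {
  kin <- data.frame(gene = as.character(gene),
                    tau_act = as.numeric(tau_act),
                    tau_rep = as.numeric(tau_rep),
                    tau_prod = as.numeric(tau_prod),
                    tau_dec = as.numeric(tau_dec),
                    delta = as.numeric(delta),
                    therm_exempt = as.logical(therm_exempt),
                    tau_dec_fixed = as.logical(tau_dec_fixed),
                    stringsAsFactors = FALSE)
  class(kin) <- c("gene_kinetics", "data.frame")
  validate_kinetics(kin)
  kin
}

# Checks the kinetics-table invariants; returns the table invisibly.
validate_kinetics <- function(kin) {
  req <- c("gene", "tau_act", "tau_rep", "tau_prod", "tau_dec", "delta")
  missing_cols <- setdiff(req, names(kin))
  if (length(missing_cols) > 0) {
    stopf("kinetics table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(kin$gene)) stopf("duplicated gene names in kinetics table")
  for (col in c("tau_act", "tau_rep")) {
    if (any(!(kin[[col]] > 0))) stopf("%s must be strictly positive (Inf allowed)", col)
  }
  for (col in c("tau_prod", "tau_dec")) {
    if (any(!(kin[[col]] > 0) | !is.finite(kin[[col]]))) {
      stopf("%s must be strictly positive and finite", col)
    }
  }
  if (any(!is.finite(kin$delta))) stopf("delta must be finite")
  invisible(kin)
}

# normalizes user input (data.frame with at least the required columns)
as_kinetics <- function(kin) {
  if (!is.data.frame(kin)) stopf("kinetics must be a data.frame (see gene_kinetics())")
  if (is.null(kin$therm_exempt)) kin$therm_exempt <- FALSE
  if (is.null(kin$tau_dec_fixed)) kin$tau_dec_fixed <- TRUE
  validate_kinetics(kin)
  kin
}

#' Lock a promoter permanently ON or OFF
#'
#' Sets the relevant dwell time to infinity so the promoter can never leave
#' the locked state: `state = "ON"` sets `tau_rep = Inf` (repression never
#' fires), `state = "OFF"` sets `tau_act = Inf`. The gene's thermalization
#' requirement is waived, since a locked promoter cannot complete an ON/OFF
#' cycle.
#'
#' @param kin kinetics table (see [gene_kinetics()]).
#' @param gene gene to lock.
#' @param state `"ON"` or `"OFF"`.
#' @return The modified kinetics table.
#' @export
lock_promoter <- function(kin, gene, state = c("ON", "OFF")) {
  kin <- as_kinetics(kin)
  state <- match.arg(state)
  idx <- match(gene, kin$gene)
  if (is.na(idx)) stopf("unknown gene '%s'", gene)
  if (state == "ON") kin$tau_rep[idx] <- Inf else kin$tau_act[idx] <- Inf
  kin$therm_exempt[idx] <- TRUE
  kin
}

#' Read or write a kinetics configuration
#'
#' Kinetics configurations are JSON or YAML arrays of records with keys
#' `gene`, `tau_act`, `tau_rep`, `tau_prod`, `tau_dec`, `delta`; the string
#' `"inf"` (any case) is accepted for locked promoter states. The format is
#' chosen from the file extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path file path.
#' @return `read_kinetics()` returns a kinetics table; `write_kinetics()`
#'   returns `path` invisibly.
#' @export
read_kinetics <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (!is.null(names(rec)) && "gene" %in% names(rec)) rec <- list(rec)
  to_num <- function(x) {
    if (is.character(x) && tolower(x) %in% c("inf", "+inf", "infinity")) Inf
    else as.numeric(x)
  }
  rows <- lapply(rec, function(r) {
    gene_kinetics(gene = r$gene,
                  tau_act = to_num(r$tau_act), tau_rep = to_num(r$tau_rep),
                  tau_prod = to_num(r$tau_prod), tau_dec = to_num(r$tau_dec),
                  delta = to_num(r$delta %||% 0),
                  therm_exempt = isTRUE(r$therm_exempt))
  })
  do.call(rbind, rows)
}

#' @rdname read_kinetics
#' @param kin kinetics table to write.
#' @export
write_kinetics <- function(kin, path) {
  kin <- as_kinetics(kin)
  rec <- lapply(seq_len(nrow(kin)), function(i) {
    r <- as.list(kin[i, c("gene", "tau_act", "tau_rep", "tau_prod",
                          "tau_dec", "delta", "therm_exempt")])
    for (f in c("tau_act", "tau_rep")) if (is.infinite(r[[f]])) r[[f]] <- "inf"
    r
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(rec, path)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
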