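#' Equivalent umami concentration (Yamaguchi synergy model)
#'
#' EUC (g MSG/100 g) = sum(a_i b_i) + k * sum(a_i b_i) * sum(a_j b_j), where
#' a_i are umami amino-acid concentrations (g/100 g) with potencies b_i
#' relative to MSG (Glu 1.000, Asp 0.077), a_j are flavor-nucleotide
#' concentrations with potencies b_j (AMP 0.18, IMP 1.0, GMP 2.3), and
#' k = 1218 is the empirical synergy constant. The score is the MSG
#' concentration giving the same umami intensity as the mixture; the synergy
#' term makes it unbounded (values far above 100 g/100 g are meaningful and
#' are not capped).
#'
#' @param amino named vector of umami amino-acid concentrations.
#' @param nucleotide named vector of flavor-nucleotide concentrations.
#' @param potency potency configuration, `$potency` of [read_taste_config()].
#' @param unit unit of the supplied concentrations (`"mg/100g"` default,
#'   converted internally to the g/100 g the model is stated in).
#' @return An `euc_result`: list with `euc`, `additive_term` (sum a_i b_i),
#'   `nucleotide_term` (sum a_j b_j) and `synergy_term`
#'   (k * additive * nucleotide), all in g/100 g.
#' @export
compute_euc <- function(amino, nucleotide = numeric(0),
                        potency = read_taste_config()$potency,
                        unit = "mg/100g") {
  amino <- .euc_prepare(amino, potency$amino, unit, "amino acid")
  nucleotide <- .euc_prepare(nucleotide, potency$nucleotide, unit, "nucleotide")
  additive <- sum(amino$conc * amino$b)
  nuc <- sum(nucleotide$conc * nucleotide$b)
  synergy <- potency$synergy_constant * additive * nuc
  structure(list(euc = additive + synergy,
                 additive_term = additive,
                 nucleotide_term = nuc,
                 synergy_term = synergy),
            class = "euc_result")
}

.euc_prepare <- function(conc, potencies, unit, what) {
  if (length(conc) == 0L) return(list(conc = numeric(0), b = numeric(0)))
  if (is.null(names(conc)) || any(names(conc) == "")) {
    stop("all ", what, " concentrations must be named by compound")
  }
  names(conc) <- canonicalize_compound(names(conc), quiet = TRUE)
  if (any(conc < 0)) stop("negative ", what, " concentration")
  b <- potencies[names(conc)]
  missing_b <- names(conc)[is.na(b)]
  if (length(missing_b)) {
    stop("no umami potency configured for ", what, "(s): ",
         paste(missing_b, collapse = ", "))
  }
  list(conc = convert_concentration(conc, unit, "g/100g"), b = unname(b))
}

#' @export
print.euc_result <- function(x, ...) {
  cat(sprintf("EUC = %.2f g MSG/100 g (additive %.4f + synergy %.2f)\n",
              x$euc, x$additive_term, x$synergy_term))
  invisible(x)
}

#' Per-species EUC table
#'
#' EUC evaluated on species-mean concentrations (the headline per-species
#' score; the model's nonlinearity makes EUC-of-means differ from
#' mean-of-EUCs, so a per-replicate path is offered separately via
#' [euc_by_replicate()]). Compounds absent from the data contribute 0.
#'
#' @param summary a `species_summary`.
#' @param potency potency configuration.
#' @return data.frame species, euc_g_msg_per_100g, additive_term,
#'   nucleotide_term, synergy_term.
#' @export
euc_table <- function(summary, potency = read_taste_config()$potency) {
  stopifnot(inherits(summary, "species_summary"))
  out <- do.call(rbind, lapply(split(summary, summary$species), function(d) {
    conc <- stats::setNames(d$mean, d$compound)
    amino <- conc[names(conc) %in% names(potency$amino)]
    nuc <- conc[names(conc) %in% names(potency$nucleotide)]
    res <- compute_euc(amino, nuc, potency = potency, unit = "mg/100g")
    data.frame(species = d$species[1L],
               euc_g_msg_per_100g = res$euc,
               additive_term = res$additive_term,
               nucleotide_term = res$nucleotide_term,
               synergy_term = res$synergy_term,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-replicate EUC with mean and SD
#'
#' @param tab a `concentration_table` with replicate rows.
#' @param potency potency configuration.
#' @return data.frame species, n, euc_mean, euc_sd (sample SD over replicate
#'   EUCs).
#' @export
euc_by_replicate <- function(tab, potency = read_taste_config()$potency) {
  stopifnot(inherits(tab, "concentration_table"))
  out <- do.call(rbind, lapply(split(tab, tab$species), function(d) {
    eucs <- vapply(split(d, d$replicate), function(r) {
      conc <- stats::setNames(r$concentration, r$compound)
      amino <- conc[names(conc) %in% names(potency$amino)]
      nuc <- conc[names(conc) %in% names(potency$nucleotide)]
      compute_euc(amino, nuc, potency = potency, unit = "mg/100g")$euc
    }, numeric(1))
    data.frame(species = d$species[1L], n = length(eucs),
               euc_mean = mean(eucs), euc_sd = stats::sd(eucs),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Decompose an EUC into percent contributions
#'
#' Shares of the direct amino-acid term versus the amino x nucleotide synergy
#' term, summing to 100.
#'
#' @param result an `euc_result` with euc > 0.
#' @return named numeric: `additive_pct`, `synergy_pct`.
#' @export
decompose_contributions <- function(result) {
  stopifnot(inherits(result, "euc_result"))
  if (result$euc <= 0) stop("EUC is zero; contribution shares undefined")
  c(additive_pct = 100 * result$additive_term / result$euc,
    synergy_pct = 100 * result$synergy_term / result$euc)
}
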