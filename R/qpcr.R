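#' Default reference (internal-control) genes per species
#'
#' Each species is normalized against its own validated housekeeping gene;
#' because the reference genes differ across species, cross-species fold
#' comparisons carry a caveat, which [relative_expression()] logs.
#'
#' @return named character vector species -> reference gene.
#' @export
default_reference_genes <- function() {
  c("R. philippinarum" = "RpL3",
    "C. sinensis" = "beta-actin",
    "M. meretrix" = "beta-actin",
    "C. sikamea" = "EF1a",
    "S. constricta" = "RS9",
    "M. mercenaria" = "EF1a")
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); per species x gene the
#' group dCt is the replicate mean; ddCt = group dCt - calibrator dCt; fold
#' change = 2^-ddCt, assuming a doubling per cycle (efficiency 2.0; measured
#' efficiencies from [fit_efficiency()] are validation-only and are not folded
#' into the formula).
#'
#' @param records data.frame with columns species, replicate, gene,
#'   ct_target, ct_reference (cycles, in (0, 45)).
#' @param calibrator species to normalize against, or `"auto"` (default):
#'   per gene, the species with the largest group dCt (lowest expression),
#'   so every displayed fold is >= 1.
#' @param quiet suppress the cross-species reference-gene caveat.
#' @return data.frame species, gene, n, delta_ct, delta_delta_ct, fold,
#'   calibrator.
#' @export
relative_expression <- function(records, calibrator = "auto", quiet = FALSE) {
  required <- c("species", "replicate", "gene", "ct_target", "ct_reference")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ct <- c(records$ct_target, records$ct_reference)
  if (anyNA(ct)) stop("missing Ct value(s)")
  if (any(ct <= 0 | ct >= 45)) stop("Ct values must lie in (0, 45)")
  if (!quiet && length(unique(records$species)) > 1L) {
    message("note: species are normalized to species-specific reference ",
            "genes; cross-species folds compare relative, not absolute, levels")
  }
  records$delta_ct <- records$ct_target - records$ct_reference
  out <- do.call(rbind, lapply(split(records, records$gene), function(g) {
    grp <- do.call(rbind, lapply(split(g, g$species), function(d) {
      data.frame(species = d$species[1L], gene = d$gene[1L], n = nrow(d),
                 delta_ct = mean(d$delta_ct), stringsAsFactors = FALSE)
    }))
    cal <- if (identical(calibrator, "auto")) {
      grp$species[which.max(grp$delta_ct)]
    } else {
      if (!calibrator %in% grp$species) {
        stop("calibrator species '", calibrator, "' not present for gene ",
             g$gene[1L])
      }
      calibrator
    }
    grp$delta_delta_ct <- grp$delta_ct - grp$delta_ct[grp$species == cal]
    grp$fold <- 2^(-grp$delta_delta_ct)
    grp$calibrator <- cal
    grp
  }))
  rownames(out) <- NULL
  out
}

#' Primer efficiency from a dilution-series standard curve
#'
#' OLS of Ct on log10(template dilution); amplification efficiency
#' = 10^(-1/slope) - 1, with 1.0 meaning perfect doubling (slope -3.3219).
#' Curves outside the acceptance window are flagged, not rejected.
#'
#' @param dilutions data.frame with columns `log10_dilution` and `ct`,
#'   at least 3 points.
#' @param window acceptable efficiency range, default c(0.9, 1.1).
#' @param gene optional gene label carried into the result.
#' @return list(gene, slope, efficiency, r_squared, acceptable).
#' @export
fit_efficiency <- function(dilutions, window = c(0.9, 1.1), gene = NULL) {
  if (!all(c("log10_dilution", "ct") %in% names(dilutions))) {
    stop("dilutions need columns 'log10_dilution' and 'ct'")
  }
  if (length(unique(dilutions$log10_dilution)) < 3L) {
    stop("need at least 3 distinct dilution points")
  }
  fit <- stats::lm(ct ~ log10_dilution, data = dilutions)
  slope <- unname(stats::coef(fit)["log10_dilution"])
  eff <- 10^(-1 / slope) - 1
  acceptable <- eff >= window[1] && eff <= window[2]
  if (!acceptable) {
    warning(sprintf("amplification efficiency %.3f outside window [%.2f, %.2f]",
                    eff, window[1], window[2]))
  }
  list(gene = gene, slope = slope, efficiency = eff,
       r_squared = suppressWarnings(summary(fit))$r.squared,
       acceptable = acceptable)
}
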