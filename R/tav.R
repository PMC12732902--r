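#' Taste activity value
#'
#' TAV = C / T: the ratio of a compound's concentration to its human taste
#' detection threshold, both in mg per 100 g. TAV >= 1 is the conventional
#' bound for a perceptible contribution to taste. Full precision is kept
#' internally; published tables round to 2 decimals ([round_half_up()]).
#'
#' @param concentration C, mg/100 g (>= 0). Vectorized.
#' @param threshold T, mg/100 g (> 0). Recycled against `concentration`.
#' @return dimensionless TAV.
#' @export
compute_tav <- function(concentration, threshold) {
  if (any(is.na(threshold)) || any(threshold <= 0)) {
    stop("threshold must be positive and present")
  }
  if (any(concentration < 0)) stop("concentration must be non-negative")
  concentration / threshold
}

#' TAV table over species means
#'
#' One TAV per species x compound, computed on species-mean concentrations.
#' Compounds are scored only where a detection threshold is registered;
#' explicitly requesting a threshold-less compound is an error (a missing
#' threshold never silently becomes 0).
#'
#' @param summary a `species_summary`.
#' @param registry threshold data.frame from [read_taste_config()].
#' @param compounds compounds to score; default every summarized compound
#'   that has a registered threshold.
#' @return data.frame species, compound, class, concentration, threshold, tav.
#' @export
tav_table <- function(summary, registry, compounds = NULL) {
  stopifnot(inherits(summary, "species_summary"))
  if (is.null(compounds)) {
    with_thr <- registry$compound[!is.na(registry$threshold)]
    compounds <- intersect(unique(summary$compound), with_thr)
  } else {
    compounds <- canonicalize_compound(compounds, quiet = TRUE)
  }
  rows <- lapply(compounds, function(cmp) {
    thr <- threshold_for(registry, cmp)
    cls <- registry$class[registry$compound == cmp]
    sub <- summary[summary$compound == cmp, , drop = FALSE]
    spp <- unique(summary$species)
    conc <- sub$mean[match(spp, sub$species)]
    conc[is.na(conc)] <- 0   # compound absent from the data scores 0
    data.frame(species = spp, compound = cmp, class = cls,
               concentration = conc, threshold = thr,
               tav = compute_tav(conc, thr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean TAV across species
#'
#' Arithmetic mean of per-species TAVs, the cross-species aggregate used to
#' rank a compound's overall contribution.
#'
#' @param tavs numeric vector of TAVs (non-empty).
#' @return mean TAV (full precision; round for reporting).
#' @export
mean_tav <- function(tavs) {
  if (length(tavs) == 0L) stop("empty TAV vector")
  mean(tavs)
}

#' Flavor-class composition per species
#'
#' Fraction of the considered concentration pool contributed by each taste
#' class (umami, sweet, bitter, unflavored, ...), per species. Only compounds
#' with a class in the registry are considered; fractions sum to 1.
#'
#' @param summary a `species_summary`.
#' @param registry threshold data.frame from [read_taste_config()].
#' @param classes classes to include; default every class present except
#'   `"nucleotide"` (composition plots are about the amino-acid pool).
#' @return data.frame species, class, concentration, fraction.
#' @export
class_proportions <- function(summary, registry,
                              classes = setdiff(unique(registry$class),
                                                "nucleotide")) {
  stopifnot(inherits(summary, "species_summary"))
  reg <- registry[registry$class %in% classes, , drop = FALSE]
  sub <- summary[summary$compound %in% reg$compound, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no classed compounds in summary")
  sub$class <- reg$class[match(sub$compound, reg$compound)]
  out <- do.call(rbind, lapply(split(sub, sub$species), function(d) {
    total <- sum(d$mean)
    if (total <= 0) stop("zero total classed concentration for species ",
                         d$species[1L])
    by_class <- tapply(d$mean, d$class, sum)
    data.frame(species = d$species[1L], class = names(by_class),
               concentration = as.numeric(by_class),
               fraction = as.numeric(by_class) / total,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
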