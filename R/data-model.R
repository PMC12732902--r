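#' Canonical compound codes
#'
#' Abbreviations used throughout the toolkit for the taste-relevant free amino
#' acids and 5'-nucleotides. Compound labels in input files are matched against
#' these case-insensitively; unknown labels pass through unchanged but are
#' flagged on stderr so typos do not silently drop a compound from scoring.
#'
#' @return Character vector of canonical codes.
#' @export
canonical_compounds <- function() {
  c("Glu", "Asp", "Ala", "Gly", "Thr", "Ser", "Arg", "His", "Val", "Lys",
    "Pro", "Tau", "GMP", "AMP", "IMP")
}

#' Canonicalize compound labels
#'
#' @param x character vector of compound labels.
#' @param quiet suppress the unknown-label message.
#' @return Character vector with known labels in canonical capitalization;
#'   unknown labels are returned as given.
#' @export
canonicalize_compound <- function(x, quiet = FALSE) {
  canon <- canonical_compounds()
  idx <- match(tolower(x), tolower(canon))
  out <- ifelse(is.na(idx), x, canon[idx])
  unknown <- unique(x[is.na(idx)])
  if (length(unknown) && !quiet) {
    message("unknown compound label(s) passed through: ",
            paste(unknown, collapse = ", "))
  }
  out
}

# multiplicative factors onto the canonical unit, mg per 100 g
.unit_factors <- c("mg/100g" = 1, "ug/g" = 0.1, "g/100g" = 1000)

.normalize_unit <- function(unit) {
  u <- gsub("[[:space:]]", "", tolower(unit))
  u <- gsub("µ|μ", "u", u)       # micro sign variants
  u[u %in% c("mg/100g", "mg/100gdw")] <- "mg/100g"
  u[u %in% c("ug/g", "ug/g dw")] <- "ug/g"
  u[u %in% c("g/100g", "g/100gdw")] <- "g/100g"
  u
}

#' Convert concentrations between supported units
#'
#' The canonical internal unit for every module boundary is mg per 100 g dry
#' weight; this helper converts to and from the other units that appear in
#' taste-chemistry reporting (ug/g and g/100 g).
#'
#' @param x numeric concentrations.
#' @param from,to unit strings: one of `"mg/100g"`, `"ug/g"`, `"g/100g"`.
#' @return numeric vector in the `to` unit.
#' @export
convert_concentration <- function(x, from, to = "mg/100g") {
  from <- .normalize_unit(from)
  to <- .normalize_unit(to)
  bad <- setdiff(unique(c(from, to)), names(.unit_factors))
  if (length(bad)) stop("unsupported unit(s): ", paste(bad, collapse = ", "))
  x * unname(.unit_factors[from]) / unname(.unit_factors[to])
}

#' Assemble and validate a concentration table
#'
#' The shared long-format container for per-replicate compound concentrations:
#' one row per (species, replicate, compound), concentration in mg per 100 g on
#' a single declared basis. A compound that was not detected is an absent row,
#' never a stored NA.
#'
#' @param df data.frame with columns `species`, `replicate`, `compound`,
#'   `concentration`, and optionally `unit` (default mg/100g) and `basis`
#'   (default `"dry"`).
#' @param quiet suppress unknown-compound messages.
#' @return A validated `concentration_table` (a data.frame) with columns
#'   species, replicate, compound, concentration (mg/100 g), basis.
#' @export
concentration_table <- function(df, quiet = FALSE) {
  required <- c("species", "replicate", "compound", "concentration")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$concentration <- as.numeric(df$concentration)
  if (anyNA(df$concentration)) {
    stop("non-numeric or missing concentration in row(s): ",
         paste(which(is.na(df$concentration)), collapse = ", "))
  }
  if (!is.null(df$unit)) {
    df$concentration <- convert_concentration(df$concentration, df$unit)
    df$unit <- NULL
  }
  if (is.null(df$basis)) df$basis <- "dry"
  if (length(unique(df$basis)) > 1L) {
    stop("mixed concentration basis: ", paste(unique(df$basis), collapse = ", "),
         " (all rows must share one basis)")
  }
  if (!all(df$basis %in% c("dry", "wet"))) {
    stop("basis must be 'dry' or 'wet'")
  }
  neg <- which(df$concentration < 0)
  if (length(neg)) {
    stop("negative concentration in row(s): ", paste(neg, collapse = ", "))
  }
  rep_num <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_num) || any(rep_num < 1L)) {
    stop("replicate ids must be positive integers")
  }
  df$replicate <- rep_num
  df$compound <- canonicalize_compound(as.character(df$compound), quiet = quiet)
  df$species <- as.character(df$species)
  key <- paste(df$species, df$replicate, df$compound, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (species, replicate, compound) in row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  out <- df[, c("species", "replicate", "compound", "concentration", "basis")]
  rownames(out) <- NULL
  class(out) <- c("concentration_table", "data.frame")
  out
}

#' Read a concentration table from CSV/TSV
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, otherwise CSV.
#' @param quiet suppress unknown-compound messages.
#' @return A `concentration_table`; see [concentration_table()].
#' @export
read_concentration_table <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  concentration_table(df, quiet = quiet)
}

#' Write a concentration table to CSV
#'
#' Written in the canonical unit with an explicit `unit` column so a written
#' table reads back value-identical.
#'
#' @param tab a `concentration_table`.
#' @param path output path.
#' @export
write_concentration_table <- function(tab, path) {
  stopifnot(inherits(tab, "concentration_table"))
  out <- as.data.frame(tab)
  out$unit <- "mg/100g"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize replicates to species x compound means
#'
#' @param tab a `concentration_table`.
#' @return A `species_summary` data.frame with columns species, compound,
#'   mean, sd (sample SD, n-1 denominator; NA when n = 1), n.
#' @export
summarize_concentrations <- function(tab) {
  stopifnot(inherits(tab, "concentration_table"))
  if (nrow(tab) == 0L) stop("empty concentration table")
  key <- interaction(tab$species, tab$compound, drop = TRUE)
  agg <- do.call(rbind, lapply(split(tab, key), function(d) {
    data.frame(species = d$species[1L], compound = d$compound[1L],
               mean = mean(d$concentration),
               sd = stats::sd(d$concentration),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$species, agg$compound), ]
  rownames(agg) <- NULL
  class(agg) <- c("species_summary", "data.frame")
  agg
}

#' Construct a species summary from keyed-in means
#'
#' For working directly from published species-mean tables when the raw
#' replicates are not available.
#'
#' @param df data.frame with columns `species`, `compound`, `mean` and
#'   optionally `sd`, `n`.
#' @return A `species_summary`.
#' @export
species_summary <- function(df) {
  required <- c("species", "compound", "mean")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$mean < 0, na.rm = TRUE)) stop("negative mean concentration")
  if (is.null(df$sd)) df$sd <- NA_real_
  if (is.null(df$n)) df$n <- 1L
  df$compound <- canonicalize_compound(as.character(df$compound), quiet = TRUE)
  out <- df[, c("species", "compound", "mean", "sd", "n")]
  rownames(out) <- NULL
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Read the threshold / potency configuration
#'
#' YAML with two top-level keys. `thresholds` maps each compound to its taste
#' class (umami, sweet, bitter, unflavored, nucleotide) and, when a human
#' detection threshold is established, `threshold_mg_per_100g`. `potencies`
#' holds the umami potency coefficients relative to MSG (`amino`,
#' `nucleotide`) and the `synergy_constant` of the EUC model.
#'
#' @param path YAML file; defaults to the configuration shipped with the
#'   package.
#' @return list with elements `thresholds` (data.frame compound, class,
#'   threshold) and `potency` (list amino, nucleotide, synergy_constant).
#' @export
read_taste_config <- function(path = default_taste_config()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$thresholds) || is.null(cfg$potencies)) {
    stop("config must contain 'thresholds' and 'potencies' keys")
  }
  th <- do.call(rbind, lapply(names(cfg$thresholds), function(cmp) {
    entry <- cfg$thresholds[[cmp]]
    data.frame(compound = canonicalize_compound(cmp, quiet = TRUE),
               class = entry$class,
               threshold = if (is.null(entry$threshold_mg_per_100g))
                 NA_real_ else as.numeric(entry$threshold_mg_per_100g),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(th$compound)) stop("duplicate compound in thresholds")
  if (any(!is.na(th$threshold) & th$threshold <= 0)) {
    stop("thresholds must be positive")
  }
  pot <- cfg$potencies
  amino <- unlist(pot$amino)
  nucleotide <- unlist(pot$nucleotide)
  names(amino) <- canonicalize_compound(names(amino), quiet = TRUE)
  names(nucleotide) <- canonicalize_compound(names(nucleotide), quiet = TRUE)
  if (any(c(amino, nucleotide) < 0)) stop("potencies must be non-negative")
  syn <- as.numeric(pot$synergy_constant)
  if (!isTRUE(syn > 0)) stop("synergy_constant must be positive")
  list(thresholds = th,
       potency = list(amino = amino, nucleotide = nucleotide,
                      synergy_constant = syn))
}

#' Path to the default shipped taste configuration
#' @return file path of the packaged YAML.
#' @export
default_taste_config <- function() {
  system.file("extdata", "taste_config.yaml", package = "umamikit",
              mustWork = TRUE)
}

#' Bundled reference species-mean dataset
#'
#' Species-mean concentrations (mg/100 g dry weight) for six commercial
#' bivalves, keyed in from a published comparative umami survey. Nucleotide
#' means carry printed SDs; several amino-acid means are recovered as
#' printed TAV x threshold (see the `provenance` column). Values that the
#' publication does not print (e.g. Asp for three species) are absent rows.
#'
#' @return A `species_summary` with an extra `provenance` column attribute
#'   available via `attr(x, "provenance")`.
#' @export
reference_means <- function() {
  path <- system.file("extdata", "reference_means.csv", package = "umamikit",
                      mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- species_summary(df[, c("species", "compound", "mean", "sd", "n")])
  attr(out, "provenance") <- df$provenance
  out
}

#' Look up a detection threshold
#'
#' @param registry threshold data.frame from [read_taste_config()].
#' @param compound single compound code.
#' @return threshold in mg/100 g.
#' @export
threshold_for <- function(registry, compound) {
  compound <- canonicalize_compound(compound, quiet = TRUE)
  row <- registry[registry$compound == compound, , drop = FALSE]
  if (nrow(row) == 0L) stop("no threshold registered for compound: ", compound)
  if (is.na(row$threshold)) {
    stop("compound '", compound,
         "' has no established detection threshold; TAV is undefined for it")
  }
  row$threshold
}

#' Round half away from zero
#'
#' Published taste tables round 2.625 to 2.63; base R's `round()` rounds to
#' even. Internal math is full precision; this is applied only at reporting.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
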