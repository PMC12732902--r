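#' Substream seed derivation
#'
#' One user-facing seed drives every generator; each generator draws from its
#' own derived substream so adding a new generator never perturbs the draws of
#' an existing one. Kept below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stream small integer stream id.
#' @return derived integer seed.
#' @keywords internal
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919) %% 2147483647)
}

#' Configuration for the synthetic-data generators
#'
#' Defines the study conditions the generators emulate: per-species compound
#' means/SDs (defaulting to the bundled reference table, with a 10% CV where
#' no SD is published), ten biological replicates per species, and a latent
#' gene-compound coupling (default: GLUD1 coupled to Glu at Pearson rho =
#' 0.90, the headline expression-metabolite association).
#'
#' @param compounds data.frame species, compound, mean, sd (mg/100 g).
#' @param n_replicates biological replicates per species (default 10).
#' @param coupling data.frame gene, compound, rho: the target *observed-scale*
#'   Pearson correlation between expression level and compound concentration
#'   across species-level units.
#' @param expression_cv between-unit coefficient of variation of expression
#'   folds (lognormal margin, median 1), default 0.5.
#' @param within_cv within-species replicate CV used when replicating
#'   unit-level concentrations, default 0.10.
#' @param ct_reference_mean,ct_noise_sd reference-gene Ct level (cycles) and
#'   Gaussian technical noise on Ct.
#' @param dct_baseline baseline dCt of a unit with expression fold 1.
#' @param seed master seed.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(compounds = NULL,
                             n_replicates = 10L,
                             coupling = data.frame(gene = "GLUD1",
                                                   compound = "Glu",
                                                   rho = 0.90),
                             expression_cv = 0.5,
                             within_cv = 0.10,
                             ct_reference_mean = 18,
                             ct_noise_sd = 0.15,
                             dct_baseline = 5,
                             seed = 1L) {
  if (is.null(compounds)) {
    ref <- reference_means()
    compounds <- data.frame(species = ref$species, compound = ref$compound,
                            mean = ref$mean,
                            sd = ifelse(is.na(ref$sd), 0.10 * ref$mean, ref$sd),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("species", "compound", "mean", "sd") %in% names(compounds)))
  if (any(compounds$mean < 0) || any(compounds$sd < 0)) {
    stop("compound means and SDs must be non-negative")
  }
  if (n_replicates < 2L) stop("need n_replicates >= 2")
  stopifnot(all(c("gene", "compound", "rho") %in% names(coupling)))
  if (any(abs(coupling$rho) > 1)) {
    stop("coupling rho outside [-1, 1]: not a valid correlation")
  }
  if (anyDuplicated(coupling[c("gene", "compound")])) {
    stop("duplicate gene-compound coupling")
  }
  structure(list(compounds = compounds, n_replicates = as.integer(n_replicates),
                 coupling = coupling, expression_cv = expression_cv,
                 within_cv = within_cv, ct_reference_mean = ct_reference_mean,
                 ct_noise_sd = ct_noise_sd, dct_baseline = dct_baseline,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# moment-matched lognormal parameters: mean m > 0, sd s >= 0
.lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# draw n lognormal values with exact target mean m and sd s (s = 0 -> constant)
.rlnorm_matched <- function(n, m, s) {
  if (m == 0) return(rep(0, n))
  if (s == 0) return(rep(m, n))
  p <- .lnorm_params(m, s)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

#' Generate a species x replicate compound table
#'
#' Replicate concentrations are lognormal (guaranteeing positivity) with
#' parameters moment-matched so each species x compound hits its configured
#' mean and SD in expectation. Deterministic under a fixed seed.
#'
#' @param config a `generator_config`.
#' @return a `concentration_table`.
#' @export
generate_compound_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(substream_seed(config$seed, 1L))
  cmp <- config$compounds
  rows <- do.call(rbind, lapply(seq_len(nrow(cmp)), function(i) {
    data.frame(species = cmp$species[i],
               replicate = seq_len(config$n_replicates),
               compound = cmp$compound[i],
               concentration = .rlnorm_matched(config$n_replicates,
                                               cmp$mean[i], cmp$sd[i]),
               stringsAsFactors = FALSE)
  }))
  concentration_table(rows, quiet = TRUE)
}

# latent normal correlation that yields observed-scale Pearson rho between
# two lognormal margins with log-scale SDs s1, s2 (bilognormal closed form)
.calibrate_rho <- function(rho, s1, s2) {
  if (rho == 0 || s1 == 0 || s2 == 0) return(rho)
  denom <- sqrt(expm1(s1^2) * expm1(s2^2))
  arg <- 1 + rho * denom
  if (arg <= 0) stop("target correlation not attainable for these margins")
  rho_z <- log(arg) / (s1 * s2)
  if (abs(rho_z) <= 1 + 1e-8) return(max(-1, min(1, rho_z)))
  if (abs(rho_z) > 1) {
    stop(sprintf(paste0("target Pearson rho = %.2f not attainable: the ",
                        "lognormal margins (log-SDs %.3f, %.3f) cap |r| at ",
                        "%.3f; reduce the margin mismatch"),
                 rho, s1, s2, expm1(s1 * s2) / denom))
  }
  rho_z
}

#' Generate coupled expression and compound data
#'
#' Gaussian-copula draws at the species level: for each configured
#' gene-compound pair, latent bivariate normals are transformed to a
#' lognormal expression fold (median 1) and a lognormal concentration whose
#' mean/SD match the between-species spread of the configured table. The
#' latent correlation is calibrated through the bilognormal closed form so the
#' population Pearson correlation of the *observed* pair equals the
#' configured rho. Ct records are then derived per replicate as
#' ct_target = ct_reference + dCt, with dCt = baseline - log2(fold) plus
#' technical noise, so the 2^-ddCt chain recovers the latent folds.
#'
#' @param config a `generator_config`.
#' @param n_units number of species-level units; defaults to the species in
#'   the configured compound table (use large values for calibration checks).
#' @return list with `latent` (unit, gene, compound, expression_fold,
#'   concentration), `ct` (species, replicate, gene, ct_target,
#'   ct_reference), and `compounds` (a `concentration_table` of replicate
#'   draws around each unit's concentration).
#' @export
generate_expression_and_compounds <- function(config, n_units = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(n_units)) n_units <- length(unique(config$compounds$species))
  set.seed(substream_seed(config$seed, 2L))
  s_expr <- sqrt(log(1 + config$expression_cv^2))
  units <- sprintf("S%d", seq_len(n_units))
  latent <- list(); ct <- list(); conc_rows <- list()
  for (i in seq_len(nrow(config$coupling))) {
    gene <- config$coupling$gene[i]
    cmp <- config$coupling$compound[i]
    rho <- config$coupling$rho[i]
    cmp_means <- config$compounds$mean[config$compounds$compound == cmp]
    if (length(cmp_means) < 2L) {
      stop("compound '", cmp, "' needs >= 2 configured species means to set ",
           "its between-species spread")
    }
    m <- mean(cmp_means); s <- stats::sd(cmp_means)
    pc <- .lnorm_params(m, s)
    rho_z <- .calibrate_rho(rho, pc$sdlog, s_expr)
    z1 <- stats::rnorm(n_units)
    z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n_units)
    concentration <- exp(pc$meanlog + pc$sdlog * z1)
    fold <- exp(-s_expr^2 / 2 + s_expr * z2)   # lognormal, mean 1
    latent[[i]] <- data.frame(unit = units, gene = gene, compound = cmp,
                              expression_fold = fold,
                              concentration = concentration,
                              stringsAsFactors = FALSE)
    nrep <- config$n_replicates
    ct_ref <- stats::rnorm(n_units * nrep, config$ct_reference_mean,
                           config$ct_noise_sd)
    dct <- rep(config$dct_baseline - log2(fold), each = nrep) +
      stats::rnorm(n_units * nrep, 0, config$ct_noise_sd)
    ct[[i]] <- data.frame(species = rep(units, each = nrep),
                          replicate = rep(seq_len(nrep), times = n_units),
                          gene = gene,
                          ct_target = ct_ref + dct,
                          ct_reference = ct_ref,
                          stringsAsFactors = FALSE)
    conc_rows[[i]] <- data.frame(
      species = rep(units, each = nrep),
      replicate = rep(seq_len(nrep), times = n_units),
      compound = cmp,
      concentration = .rlnorm_matched(
        n_units * nrep, 1, config$within_cv) *
        rep(concentration, each = nrep),
      stringsAsFactors = FALSE)
  }
  compounds <- do.call(rbind, conc_rows)
  # a unit can host several genes; compound draws must not duplicate rows
  compounds <- compounds[!duplicated(compounds[c("species", "replicate",
                                                 "compound")]), ]
  list(latent = do.call(rbind, latent),
       ct = do.call(rbind, ct),
       compounds = concentration_table(compounds, quiet = TRUE))
}

#' Generate an HPLC standard series
#'
#' Linear detector response with Gaussian noise over the usual nucleotide
#' calibration span (0.1-50 ug/mL).
#'
#' @param slope,intercept true response line.
#' @param noise_sd Gaussian area noise (>= 0).
#' @param levels standard concentrations, ug/mL.
#' @param seed integer seed.
#' @return data.frame conc, area.
#' @export
generate_hplc_standards <- function(slope = 100, intercept = 2, noise_sd = 0,
                                    levels = c(0.1, 0.5, 2, 10, 25, 50),
                                    seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(substream_seed(seed, 3L))
  data.frame(conc = levels,
             area = slope * levels + intercept +
               stats::rnorm(length(levels), 0, noise_sd))
}
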