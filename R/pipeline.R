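#' Run the end-to-end umami profiling pipeline
#'
#' Composes the stages — summarize replicates, TAV scoring, flavor-class
#' composition, EUC scoring, per-compound ANOVA + Tukey HSD letter grouping,
#' and (when Ct data are supplied) 2^-ddCt expression with the
#' expression-compound Pearson matrix — and writes each result as CSV plus a
#' Markdown report. The orchestration holds no hidden state: every table is
#' identical to what the stage functions return when called one by one.
#'
#' @param compounds_path CSV/TSV of replicate concentrations
#'   (see [read_concentration_table()]).
#' @param ct_path optional CSV of Ct records (species, replicate, gene,
#'   ct_target, ct_reference).
#' @param config_path taste configuration YAML; default the shipped one.
#' @param outdir output directory, created if needed.
#' @param alpha significance level for the letter grouping.
#' @param quiet suppress stage messages.
#' @return An `analysis_report` list: tav, proportions, euc, euc_replicate,
#'   stats (per-compound F, p and letters), correlations (or NULL), and
#'   provenance (input/config md5, package version).
#' @export
run_pipeline <- function(compounds_path, ct_path = NULL,
                         config_path = default_taste_config(),
                         outdir = NULL, alpha = 0.05, quiet = FALSE) {
  cfg <- read_taste_config(config_path)
  tab <- read_concentration_table(compounds_path, quiet = quiet)
  summ <- summarize_concentrations(tab)

  tav <- tav_table(summ, cfg$thresholds)
  props <- class_proportions(summ, cfg$thresholds)
  euc <- euc_table(summ, cfg$potency)
  euc_rep <- euc_by_replicate(tab, cfg$potency)

  stats_tab <- do.call(rbind, lapply(split(tab, tab$compound), function(d) {
    groups <- split(d$concentration, d$species)
    if (length(groups) < 2L || any(lengths(groups) < 2L)) return(NULL)
    aov_res <- anova_oneway(groups)
    cld <- compact_letter_display(tukey_hsd(groups), alpha = alpha,
                                  means = vapply(groups, mean, numeric(1)))
    data.frame(compound = d$compound[1L], species = names(cld),
               mean = vapply(groups, mean, numeric(1))[names(cld)],
               sd = vapply(groups, stats::sd, numeric(1))[names(cld)],
               f_statistic = aov_res$f_statistic,
               p_value = aov_res$p_value, letters = unname(cld),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(stats_tab)) rownames(stats_tab) <- NULL

  correlations <- NULL
  if (!is.null(ct_path)) {
    ct <- utils::read.csv(ct_path, stringsAsFactors = FALSE)
    expr <- relative_expression(ct, calibrator = "auto", quiet = quiet)
    expr_wide <- .long_to_wide(expr, "species", "gene", "fold")
    conc_wide <- .long_to_wide(summ, "species", "compound", "mean")
    shared <- intersect(rownames(expr_wide), rownames(conc_wide))
    if (length(shared) >= 3L) {
      correlations <- pearson_matrix(expr_wide[shared, , drop = FALSE],
                                     conc_wide[shared, , drop = FALSE])
    } else if (!quiet) {
      message("fewer than 3 species shared between Ct and compound data; ",
              "skipping correlation stage")
    }
  }

  report <- structure(list(
    tav = tav, proportions = props, euc = euc, euc_replicate = euc_rep,
    stats = stats_tab, correlations = correlations,
    provenance = list(
      compounds_md5 = unname(tools::md5sum(compounds_path)),
      ct_md5 = if (is.null(ct_path)) NA_character_ else
        unname(tools::md5sum(ct_path)),
      config_md5 = unname(tools::md5sum(config_path)),
      package_version = as.character(utils::packageVersion("umamikit")))
  ), class = "analysis_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

.long_to_wide <- function(df, row_col, col_col, value_col) {
  rows <- unique(df[[row_col]]); cols <- unique(df[[col_col]])
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(df[[row_col]], rows), match(df[[col_col]], cols))] <-
    df[[value_col]]
  as.data.frame(m)
}

#' Write an analysis report to disk
#'
#' CSVs for each stage plus a diffable Markdown summary with provenance.
#'
#' @param report an `analysis_report`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$tav, file.path(outdir, "tav.csv"), row.names = FALSE)
  utils::write.csv(report$proportions, file.path(outdir, "proportions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$euc, file.path(outdir, "euc.csv"), row.names = FALSE)
  utils::write.csv(report$euc_replicate,
                   file.path(outdir, "euc_replicate.csv"), row.names = FALSE)
  if (!is.null(report$stats)) {
    utils::write.csv(report$stats, file.path(outdir, "stats.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations,
                     file.path(outdir, "correlations.csv"), row.names = FALSE)
  }
  md <- c("# Umami profiling report", "",
          paste0("- package version: ", report$provenance$package_version),
          paste0("- compounds md5: ", report$provenance$compounds_md5),
          paste0("- ct md5: ", report$provenance$ct_md5),
          paste0("- config md5: ", report$provenance$config_md5), "",
          "## Per-species EUC (g MSG/100 g dry weight)", "",
          .md_table(within(report$euc,
                           euc_g_msg_per_100g <- round_half_up(
                             euc_g_msg_per_100g, 2))[,
                             c("species", "euc_g_msg_per_100g")]), "",
          "## TAV (2 dp)", "",
          .md_table(within(report$tav, tav <- round_half_up(tav, 2))[,
                    c("species", "compound", "class", "tav")]))
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}

.md_table <- function(df) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |"))
  c(header, sep, body)
}
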