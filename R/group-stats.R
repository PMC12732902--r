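#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test), the test
#' behind the per-row significance letters of comparative taste tables.
#' The degenerate case of zero variance everywhere with equal means is
#' reported as F = 0, p = 1 rather than NaN.
#'
#' @param groups named list of numeric replicate vectors (>= 2 groups,
#'   each >= 2 replicates).
#' @return list(f_statistic, df_between, df_within, p_value).
#' @export
anova_oneway <- function(groups) {
  .check_groups(groups)
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), lengths(groups)))
  if (max(value) == min(value)) {    # fully degenerate: nothing to test
    return(list(f_statistic = 0,
                df_between = nlevels(group) - 1L,
                df_within = length(value) - nlevels(group),
                p_value = 1))
  }
  tab <- suppressWarnings(stats::anova(stats::aov(value ~ group)))
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  if (is.nan(f) || is.na(f)) {       # 0/0: no between- or within-group variance
    f <- 0
    p <- 1
  }
  list(f_statistic = f,
       df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L],
       p_value = p)
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named")
  }
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 replicates")
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs studentized-range tests after one-way ANOVA (Tukey-Kramer
#' adjustment when group sizes differ). Returned as a symmetric matrix of
#' adjusted p values with unit diagonal — the input that
#' [compact_letter_display()] consumes.
#'
#' @inheritParams anova_oneway
#' @return symmetric p-value matrix with group names as dimnames.
#' @export
tukey_hsd <- function(groups) {
  .check_groups(groups)
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), lengths(groups)))
  k <- nlevels(group)
  p <- matrix(1, k, k, dimnames = list(levels(group), levels(group)))
  if (all(stats::ave(value, group, FUN = stats::var) == 0) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1L) {
    return(p)                        # identical groups: nothing to separate
  }
  tk <- stats::TukeyHSD(stats::aov(value ~ group))$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    p[a, b] <- p[b, a] <- tk[i, "p adj"]
  }
  p
}

#' Compact letter display from a pairwise p matrix
#'
#' Insert-and-absorb letter assignment: groups sharing at least one letter are
#' exactly the pairs whose p value is >= alpha. Starting from a single letter
#' covering all groups, each significant pair splits every letter containing
#' both, and redundant (subset) letters are absorbed. Minimal letter count is
#' not guaranteed, but the sharing invariant always holds. Letters are
#' ordered a, b, c, ... with "a" given to the group with the largest mean
#' when means are supplied (the convention of descending-mean tables).
#'
#' @param pairwise_p symmetric p matrix with group dimnames (e.g. from
#'   [tukey_hsd()]).
#' @param alpha significance level, default 0.05.
#' @param means optional named group means used only to order the letters.
#' @return named character vector group -> letter string (e.g. "a", "ab").
#' @export
compact_letter_display <- function(pairwise_p, alpha = 0.05, means = NULL) {
  if (!isTRUE(all.equal(pairwise_p, t(pairwise_p)))) {
    stop("pairwise p matrix must be symmetric")
  }
  g <- rownames(pairwise_p)
  if (is.null(g)) stop("pairwise p matrix must carry group names")
  k <- length(g)
  # columns are letters; entry TRUE = group belongs to that letter
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (pairwise_p[i, j] >= alpha) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          new_cols <- c(new_cols, list(a, b))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (u in seq_along(new_cols)) {
        for (v in seq_along(new_cols)) {
          if (u != v && keep[v] &&
              all(new_cols[[u]] <= new_cols[[v]]) &&
              !identical(new_cols[[u]], new_cols[[v]])) {
            keep[u] <- FALSE
            break
          }
        }
      }
      # deduplicate identical columns
      cols <- unique(new_cols[keep])
    }
  }
  # order letters so "a" belongs to the largest-mean group
  ord <- seq_len(k)
  if (!is.null(means)) {
    if (!all(g %in% names(means))) stop("means must be named by group")
    ord <- order(-means[g])
  }
  first_member <- vapply(cols, function(col) min(which(col[ord])), numeric(1))
  cols <- cols[order(first_member)]
  letters_out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  stats::setNames(letters_out, g)
}

#' Correlation significance stars
#'
#' @param p p values.
#' @return "" , "*", "**" or "***" at the 0.05 / 0.01 / 0.001 thresholds.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf), right = FALSE,
      labels = c("***", "**", "*", "")) |> as.character()
}

#' Pearson correlation matrix between expression and compound variables
#'
#' Product-moment r with a two-sided p value from the t transform on n - 2
#' degrees of freedom, per (gene, variable) pair across matched observations
#' (species, in the cross-species design). p values are reported unadjusted —
#' the exploratory convention for small candidate-gene panels — so stars mark
#' per-cell, not family-wise, significance.
#'
#' @param expression numeric matrix/data.frame, observations x genes.
#' @param compounds numeric matrix/data.frame, observations x variables
#'   (contents and/or TAVs), same row order as `expression`.
#' @return data.frame gene, variable, n, r, p_value, stars. Pairs where
#'   either side has zero variance get NA with a warning.
#' @export
pearson_matrix <- function(expression, compounds) {
  expression <- as.data.frame(expression)
  compounds <- as.data.frame(compounds)
  if (nrow(expression) != nrow(compounds)) {
    stop("expression and compounds must have matching rows")
  }
  if (nrow(expression) < 3L) stop("need >= 3 paired observations")
  grid <- expand.grid(gene = names(expression), variable = names(compounds),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- expression[[grid$gene[i]]]
    y <- compounds[[grid$variable[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      warning("undefined correlation (zero variance or <3 pairs) for ",
              grid$gene[i], " ~ ", grid$variable[i])
      return(data.frame(n = sum(ok), r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(n = sum(ok), r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$stars <- p_stars(out$p_value)
  rownames(out) <- NULL
  out
}

#' Filter a correlation table to the headline associations
#'
#' The reporting emphasis for exploratory expression-metabolite screens:
#' strong (|r| > r_min) and nominally significant (p < alpha) cells.
#'
#' @param corr output of [pearson_matrix()].
#' @param r_min absolute-correlation bound, default 0.8.
#' @param alpha significance bound, default 0.05.
#' @return filtered rows of `corr`.
#' @export
highlight_correlations <- function(corr, r_min = 0.8, alpha = 0.05) {
  keep <- !is.na(corr$r) & abs(corr$r) > r_min & corr$p_value < alpha
  corr[keep, , drop = FALSE]
}
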