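# Independent oracles used to cross-check the package implementations.
# These re-derive each quantity from first principles (closed forms, manual
# sums of squares, permutation), never by calling the function under test.

# OLS slope/intercept via the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}

# literal term-by-term evaluation of the synergistic umami model,
# concentrations in mg/100 g
euc_oracle <- function(amino_mg, nucleotide_mg, b_amino, b_nuc, k = 1218) {
  ai <- sum(amino_mg / 1000 * b_amino[names(amino_mg)])
  aj <- sum(nucleotide_mg / 1000 * b_nuc[names(nucleotide_mg)])
  ai + k * ai * aj
}

# spreadsheet-style ddCt chain: plain loops, no vectorized shortcuts
ddct_oracle <- function(records, calibrator) {
  genes <- unique(records$gene)
  out <- NULL
  for (g in genes) {
    sub <- records[records$gene == g, ]
    species <- unique(sub$species)
    dct <- numeric(length(species))
    for (i in seq_along(species)) {
      rows <- sub[sub$species == species[i], ]
      dct[i] <- mean(rows$ct_target - rows$ct_reference)
    }
    cal_dct <- dct[species == calibrator]
    for (i in seq_along(species)) {
      out <- rbind(out, data.frame(species = species[i], gene = g,
                                   fold = 2^(-(dct[i] - cal_dct))))
    }
  }
  out
}

# one-way ANOVA by manual sums-of-squares decomposition
anova_ss_oracle <- function(groups) {
  all_values <- unlist(groups)
  grand <- mean(all_values)
  ss_between <- sum(lengths(groups) *
                      (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- length(groups) - 1L
  df_w <- length(all_values) - length(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# permutation p value for the one-way F test (F recomputed via the SS oracle)
perm_anova_p <- function(groups, n_perm = 4000) {
  f_obs <- anova_ss_oracle(groups)$f
  values <- unlist(groups)
  sizes <- lengths(groups)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    shuffled <- sample(values)
    perm <- split(shuffled, rep(seq_along(sizes), sizes))
    if (anova_ss_oracle(perm)$f >= f_obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Tukey-Kramer pairwise p values straight from the studentized range
tukey_q_oracle <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  df_w <- sum(n) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    df_w
  p <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
      q <- abs(m[i] - m[j]) / se
      p[i, j] <- p[j, i] <- stats::ptukey(q, k, df_w, lower.tail = FALSE)
    }
  }
  p
}

# product-moment correlation and its t-transform p value
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# random symmetric p matrix with unit diagonal, for CLD property tests
random_p_matrix <- function(k) {
  p <- matrix(0, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  p[upper.tri(p)] <- stats::runif(k * (k - 1) / 2)
  p <- p + t(p)
  diag(p) <- 1
  p
}

# small replicate table written to a temp CSV
write_fixture_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
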