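test_that("one-way ANOVA matches the manual sums-of-squares oracle", {
  groups <- list(a = c(6.2, 5.9, 6.8), b = c(7.1, 7.4, 7.0),
                 c = c(5.1, 5.6, 5.3))
  res <- anova_oneway(groups)
  oracle <- anova_ss_oracle(groups)
  expect_equal(res$f_statistic, oracle$f)
  expect_equal(res$p_value, oracle$p)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 6L)
})

test_that("ANOVA degenerate and two-group identities hold", {
  identical_groups <- list(a = c(3, 3, 3), b = c(3, 3, 3))
  res <- anova_oneway(identical_groups)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)

  # two groups: F equals the squared pooled t statistic
  set.seed(41)
  g <- list(a = rnorm(6, 0), b = rnorm(7, 0.8))
  t_res <- t.test(g$a, g$b, var.equal = TRUE)
  res2 <- anova_oneway(g)
  expect_equal(res2$f_statistic, unname(t_res$statistic)^2)
  expect_equal(res2$p_value, t_res$p.value)

  expect_error(anova_oneway(list(a = 1:3)), ">= 2 groups")
  expect_error(anova_oneway(list(a = 1:3, b = 2)), ">= 2 replicates")
})

test_that("parametric and permutation ANOVA p values agree", {
  set.seed(43)
  groups <- list(a = rnorm(8, 0, 1), b = rnorm(8, 0.9, 1),
                 c = rnorm(8, 0.4, 1))
  p_param <- anova_oneway(groups)$p_value
  p_perm <- perm_anova_p(groups, n_perm = 4000)
  # Monte-Carlo error of the permutation estimate at 4000 shuffles
  expect_lt(abs(p_param - p_perm),
            0.02 + 3 * sqrt(p_param * (1 - p_param) / 4000))
})

test_that("Tukey HSD p matrix is symmetric and matches the q-range oracle", {
  set.seed(44)
  groups <- list(a = rnorm(5, 0), b = rnorm(5, 1.2), c = rnorm(5, 0.3))
  p <- tukey_hsd(groups)
  expect_equal(p, t(p))
  expect_equal(unname(diag(p)), rep(1, 3))
  oracle <- tukey_q_oracle(groups)
  expect_equal(p, oracle, tolerance = 1e-8)

  # Tukey-Kramer path: unbalanced groups still match the oracle
  groups_u <- list(a = rnorm(4, 0), b = rnorm(7, 1), c = rnorm(5, 0.5))
  expect_equal(tukey_hsd(groups_u), tukey_q_oracle(groups_u),
               tolerance = 1e-8)

  expect_equal(unname(tukey_hsd(list(a = c(2, 2), b = c(2, 2)))[1, 2]), 1)
  far <- list(a = rnorm(5, 0, 0.1), b = rnorm(5, 50, 0.1))
  expect_lt(tukey_hsd(far)["a", "b"], 1e-6)
})

test_that("letter display satisfies share-a-letter <=> non-significant", {
  # no significant pair: everything is "a"
  p_none <- matrix(1, 3, 3, dimnames = list(c("x", "y", "z"),
                                            c("x", "y", "z")))
  expect_equal(unname(compact_letter_display(p_none)), c("a", "a", "a"))

  # all pairs significant: three distinct letters
  p_all <- matrix(0.001, 3, 3, dimnames = dimnames(p_none)); diag(p_all) <- 1
  expect_equal(sort(unname(compact_letter_display(p_all))),
               c("a", "b", "c"))

  # the classic chain A != C, A ~ B, B ~ C -> a, ab, b
  p_chain <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C")))
  p_chain["A", "C"] <- p_chain["C", "A"] <- 0.01
  expect_equal(compact_letter_display(p_chain, means = c(A = 3, B = 2, C = 1)),
               c(A = "a", B = "ab", C = "b"))

  expect_error(compact_letter_display(matrix(c(1, 0.2, 0.4, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))), "symmetric")
})

test_that("letter-sharing invariant holds over random p matrices", {
  set.seed(45)
  alpha <- 0.05
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    p <- random_p_matrix(k)
    # spread thresholds so significant pairs actually occur
    p[p < 0.5] <- p[p < 0.5] / 10
    diag(p) <- 1
    cld <- compact_letter_display(p, alpha = alpha)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        share <- length(intersect(strsplit(cld[i], "")[[1]],
                                  strsplit(cld[j], "")[[1]])) > 0
        expect_equal(share, p[i, j] >= alpha,
                     info = sprintf("rep %d pair %d-%d p=%.4f", rep, i, j,
                                    p[i, j]))
      }
    }
  }
})

test_that("letters follow descending group means, 'a' to the largest", {
  set.seed(46)
  groups <- list(lo = rnorm(6, 0, 0.2), hi = rnorm(6, 10, 0.2),
                 mid = rnorm(6, 5, 0.2))
  cld <- compact_letter_display(tukey_hsd(groups),
                                means = vapply(groups, mean, numeric(1)))
  expect_equal(unname(cld["hi"]), "a")
  expect_equal(unname(cld["lo"]), "c")
})

test_that("Pearson matrix matches the product-moment oracle and conventions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_matrix(data.frame(g = x),
                              data.frame(v = 2 * x + 1))$r, 1)
  expect_equal(pearson_matrix(data.frame(g = x),
                              data.frame(v = -x))$r, -1)

  set.seed(47)
  for (rep in 1:5) {
    e <- data.frame(g1 = rnorm(6), g2 = rnorm(6))
    m <- data.frame(v1 = rnorm(6), v2 = rnorm(6))
    res <- pearson_matrix(e, m)
    for (i in seq_len(nrow(res))) {
      oracle <- pearson_oracle(e[[res$gene[i]]], m[[res$variable[i]]])
      expect_equal(res$r[i], oracle$r)
      expect_equal(res$p_value[i], oracle$p)
    }
  }

  # r invariant under positive affine transforms of either side
  e <- data.frame(g = rnorm(8)); m <- data.frame(v = rnorm(8))
  r0 <- pearson_matrix(e, m)$r
  expect_equal(pearson_matrix(e * 3.2 + 5, m)$r, r0)
  expect_equal(pearson_matrix(e, m * 0.1 - 2)$r, r0)

  expect_warning(res0 <- pearson_matrix(data.frame(g = rep(1, 5)),
                                        data.frame(v = rnorm(5))),
                 "zero variance")
  expect_true(is.na(res0$r))
  expect_error(pearson_matrix(data.frame(g = 1:2), data.frame(v = 1:2)),
               ">= 3")
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_equal(p_stars(c(0.2, 0.04, 0.004, 0.0004, 0.05)),
               c("", "*", "**", "***", ""))
})

test_that("highlight filter keeps only strong nominally-significant cells", {
  corr <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     variable = "Glu", n = 6,
                     r = c(0.9, 0.85, 0.5, NA),
                     p_value = c(0.01, 0.2, 0.01, NA))
  corr$stars <- p_stars(corr$p_value)
  kept <- highlight_correlations(corr)
  expect_equal(kept$gene, "g1")
})

test_that("estimated r converges to the generating correlation", {
  cfg <- generator_config(seed = 48)
  sim <- generate_expression_and_compounds(cfg, n_units = 2000)
  r_hat <- cor(sim$latent$expression_fold, sim$latent$concentration)
  expect_lt(abs(r_hat - 0.90), 3 / sqrt(2000))
})
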