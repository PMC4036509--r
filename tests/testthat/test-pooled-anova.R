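test_that("the worked balanced example decomposes exactly", {
  f <- fit_gene_anova(worked_example_matrix())
  expect_equal(f$SS_G, 32)
  expect_equal(f$SS_N, 2)
  expect_equal(f$SS_GxN, 0)
  expect_equal(f$SS_E, 8)
  expect_equal(f$df_E, 4L)
  expect_equal(f$s2, 2)
  # cross-check against the least-squares projection oracle
  o <- anova_oracle(worked_example_matrix())
  expect_equal(unname(o[1, ]), c(32, 2, 0, 8))
})

test_that("constant genes give all-zero sums of squares and p = 1", {
  m <- one_gene_matrix(rep(7, 3), rep(7, 3), rep(7, 3), rep(7, 3))
  f <- fit_gene_anova(m)
  expect_equal(f$SS_G + f$SS_N + f$SS_GxN + f$SS_E, 0)
  tab <- contrast_tests(f, list(sigma2 = 1))
  expect_equal(c(tab$p_G, tab$p_N, tab$p_GxN), c(1, 1, 1))
})

test_that("SS components match the projection oracle on random balanced instances", {
  set.seed(101)
  for (r in 2:5) {
    vals <- matrix(rnorm(20 * 4 * r, mean = 8, sd = 2), nrow = 20)
    m <- make_matrix(vals, r)
    f <- fit_gene_anova(m)
    o <- anova_oracle(m)
    for (cc in c("SS_G", "SS_N", "SS_GxN", "SS_E")) {
      expect_equal(f[[cc]], unname(o[, cc]), tolerance = 1e-9)
    }
    # conservation: parts sum to the total SS about the grand mean
    tot <- apply(vals, 1, function(y) sum((y - mean(y))^2))
    expect_equal(f$SS_G + f$SS_N + f$SS_GxN + f$SS_E, tot,
                 tolerance = 1e-9)
  }
})

test_that("global variance trimming follows the inclusive-quantile convention", {
  base <- fit_gene_anova(worked_example_matrix())
  fake_fits <- function(s2) {
    f <- base[rep(1, length(s2)), ]
    f$s2 <- s2
    f$SS_E <- s2 * f$df_E
    f$probe_id <- sprintf("p%d", seq_along(s2))
    rownames(f) <- NULL
    class(f) <- class(base)
    f
  }
  # identical variances are untouched by any trim
  gv <- estimate_global_variance(fake_fits(rep(1, 4)))
  expect_equal(gv$sigma2, 1)
  expect_equal(gv$n_retained, 4L)
  # hand-enumerated: {1,2,3,4,100}, trim (0, 0.8) keeps {1,2,3,4}
  gv2 <- estimate_global_variance(fake_fits(c(1, 2, 3, 4, 100)),
                                  trim_low_q = 0, trim_high_q = 0.8)
  expect_equal(gv2$sigma2, 2.5)
  expect_equal(gv2$n_retained, 4L)
  # no trimming: plain arithmetic mean
  gv3 <- estimate_global_variance(fake_fits(c(1, 2, 3, 4, 100)),
                                  trim_low_q = 0, trim_high_q = 1)
  expect_equal(gv3$sigma2, 22)
  expect_error(estimate_global_variance(fake_fits(1:4), 0.9, 0.1),
               "trim_low_q")
})

test_that("contrast statistics follow SS/sigma2 with a chi-square(1) tail", {
  f <- fit_gene_anova(worked_example_matrix())
  tab <- contrast_tests(f, list(sigma2 = 2))
  expect_equal(tab$T_G, 16)
  # frozen from direct numerical integration of the chi-square(1) density
  expect_equal(tab$p_G, 6.33424836662e-05, tolerance = 1e-9)
  expect_equal(tab$T_N, 1)
  # doubling sigma2 halves T and weakly increases p
  tab2 <- contrast_tests(f, list(sigma2 = 4))
  expect_equal(tab2$T_G, 8)
  expect_true(all(tab2[c("p_G", "p_N", "p_GxN")] >=
                    tab[c("p_G", "p_N", "p_GxN")]))
})

test_that("the F reference converges to the chi-square one at large pooled df", {
  f <- fit_gene_anova(worked_example_matrix())
  gv <- list(sigma2 = 2, df_pooled = 2000 * 8)
  expect_equal(contrast_tests(f, gv, reference = "f")$p_G,
               contrast_tests(f, gv, reference = "chisq")$p_G,
               tolerance = 1e-3)
})

test_that("Bonferroni adjustment multiplies, caps at 1 and is identity at m = 1", {
  f <- fit_gene_anova(worked_example_matrix())
  tab <- contrast_tests(f, list(sigma2 = 2))
  tab$p_G <- 0.001; tab$p_N <- 0.5
  a100 <- adjust_bonferroni(tab, m = 100)
  expect_equal(a100$padj_G, 0.1)
  expect_equal(a100$padj_N, 1)
  a1 <- adjust_bonferroni(tab, m = 1)
  expect_equal(a1$padj_G, tab$p_G)
  expect_error(adjust_bonferroni(tab, m = 0), "m must be")
})

test_that("null raw p-values are approximately uniform per contrast", {
  sim <- simulate_expression(expression_sim_config(
    n_genes = 2000, prop_G = 0, prop_N = 0, prop_GxN = 0,
    noise_sd = 0.5, n_replicates = 3, seed = 185))
  fit <- pooled_anova(sim$matrix, filter_threshold = -Inf)
  for (cc in c("p_G", "p_N", "p_GxN")) {
    p <- fit$contrasts[[cc]]
    expect_lt(abs(mean(p) - 0.5), 0.02)
    ks <- suppressWarnings(ks.test(p, "punif"))
    expect_lt(unname(ks$statistic), 0.03)
  }
})

test_that("declared-positive rate grows with planted effect size", {
  rates <- vapply(c(0, 0.5, 1, 2), function(e) {
    cfg <- expression_sim_config(n_genes = 600, prop_G = 0.3,
                                 effect_size_G = max(e, 1e-9),
                                 prop_N = 0, prop_GxN = 0,
                                 noise_sd = 0.5, seed = 77)
    sim <- simulate_expression(cfg)
    if (e == 0) sim$truth$has_G <- rep(TRUE, nrow(sim$truth))
    fit <- pooled_anova(sim$matrix, filter_threshold = -Inf)
    idx <- which(sim$truth$has_G)
    mean(fit$classification$flags$declared_G[idx])
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.01)
  expect_gt(rates[4], 0.9)
})
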