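#' Gene-wise two-way factorial ANOVA decomposition
#'
#' Fits, for every probe, the balanced two-way model
#' `Y_ijk = mu + G_i + N_j + GN_ij + E_ijk` (genotype i, nitrate supply j,
#' replicate k) and returns the closed-form balanced-design sums of squares:
#' \deqn{SS_G = 2r \sum_i (\bar y_{i..} - \bar y_{...})^2,\quad
#'       SS_N = 2r \sum_j (\bar y_{.j.} - \bar y_{...})^2,}
#' \deqn{SS_{GxN} = r \sum_{ij} (\bar y_{ij.} - \bar y_{i..} - \bar y_{.j.}
#'       + \bar y_{...})^2,\quad SS_E = \sum_{ijk} (y_{ijk} - \bar y_{ij.})^2,}
#' with r replicates per cell; on a balanced design these partition the
#' total sum of squares exactly and each factorial term carries 1 degree of
#' freedom, the residual `4(r-1)`.
#'
#' @param x an [expression_matrix()] with a balanced 2x2 design and at
#'   least 2 replicates per cell. Unbalanced designs are rejected (the
#'   Type-I/II/III ambiguity does not arise in the balanced study design
#'   this models).
#' @return data.frame of class `gene_anova` with one row per probe:
#'   cell means (`mean_WT_HN`, `mean_WT_LN`, `mean_MUT_HN`, `mean_MUT_LN`),
#'   marginal means (`mean_WT`, `mean_MUT`, `mean_HN`, `mean_LN`),
#'   `grand_mean`, sums of squares `SS_G`, `SS_N`, `SS_GxN`, `SS_E`,
#'   degrees of freedom and the per-gene residual variance `s2 = SS_E/df_E`.
#' @export
fit_gene_anova <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!is_balanced(x)) {
    stop_input("design is not a balanced 2x2 layout; refusing to fit")
  }
  r <- nrow(x$design) / 4
  if (r < 2) stop_input("need >= 2 replicates per cell (no residual df)")

  cell <- paste(x$design$genotype, x$design$nitrate, sep = "_")
  cell <- factor(cell, levels = c("WT_HN", "WT_LN", "MUT_HN", "MUT_LN"))
  Y <- x$values
  # samples x cells averaging operator
  M <- stats::model.matrix(~ 0 + cell)
  colnames(M) <- levels(cell)
  cm <- Y %*% M / r                       # genes x 4 cell means
  grand <- rowMeans(Y)
  m_wt <- (cm[, "WT_HN"] + cm[, "WT_LN"]) / 2
  m_mut <- (cm[, "MUT_HN"] + cm[, "MUT_LN"]) / 2
  m_hn <- (cm[, "WT_HN"] + cm[, "MUT_HN"]) / 2
  m_ln <- (cm[, "WT_LN"] + cm[, "MUT_LN"]) / 2

  ss_g <- 2 * r * ((m_wt - grand)^2 + (m_mut - grand)^2)
  ss_n <- 2 * r * ((m_hn - grand)^2 + (m_ln - grand)^2)
  inter <- cm - cbind(m_wt, m_wt, m_mut, m_mut) -
    cbind(m_hn, m_ln, m_hn, m_ln) + grand
  ss_gn <- r * rowSums(inter^2)
  fitted_cells <- cm[, as.integer(cell), drop = FALSE]
  ss_e <- rowSums((Y - fitted_cells)^2)

  df_e <- 4 * (r - 1)
  out <- data.frame(
    probe_id = rownames(Y),
    mean_WT_HN = cm[, "WT_HN"], mean_WT_LN = cm[, "WT_LN"],
    mean_MUT_HN = cm[, "MUT_HN"], mean_MUT_LN = cm[, "MUT_LN"],
    mean_WT = m_wt, mean_MUT = m_mut, mean_HN = m_hn, mean_LN = m_ln,
    grand_mean = grand,
    SS_G = ss_g, SS_N = ss_n, SS_GxN = ss_gn, SS_E = ss_e,
    df_G = 1L, df_N = 1L, df_GxN = 1L, df_E = df_e,
    s2 = ss_e / df_e,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("gene_anova", "data.frame")
  out
}

#' Pooled (global) residual variance after extreme-variance trimming
#'
#' With only a few replicates per cell, per-gene residual variances are too
#' unstable to test against; instead a single global residual variance is
#' pooled across genes after discarding genes with extreme per-gene
#' variance. Genes whose `s2` falls strictly below the `trim_low_q`
#' quantile or strictly above the `trim_high_q` quantile of the `s2`
#' distribution (inclusive linear-interpolation quantiles,
#' [stats::quantile()] type 7) are removed; the global variance is the mean
#' of the retained `s2` — equivalently pooled `SS_E` over pooled `df_E`,
#' since `df_E` is constant across genes.
#'
#' @param fits a [fit_gene_anova()] result.
#' @param trim_low_q,trim_high_q trimming quantiles, `0 <= low < high <= 1`
#'   (defaults 0.025 and 0.975; `c(0, 1)` disables trimming).
#' @return list of class `global_variance`: `sigma2`, `n_retained`,
#'   `trim_low_q`, `trim_high_q`, `df_E` (per gene) and `df_pooled`.
#' @export
estimate_global_variance <- function(fits, trim_low_q = 0.025,
                                     trim_high_q = 0.975) {
  stopifnot(inherits(fits, "gene_anova"))
  if (!nrow(fits)) stop_input("no gene fits supplied")
  if (!(trim_low_q >= 0 && trim_low_q < trim_high_q && trim_high_q <= 1)) {
    stop_input("need 0 <= trim_low_q < trim_high_q <= 1")
  }
  s2 <- fits$s2
  qs <- stats::quantile(s2, c(trim_low_q, trim_high_q), names = FALSE,
                        type = 7)
  keep <- s2 >= qs[1] & s2 <= qs[2]
  if (!any(keep)) stop_input("trimming removed every gene")
  structure(list(sigma2 = mean(s2[keep]), n_retained = sum(keep),
                 trim_low_q = trim_low_q, trim_high_q = trim_high_q,
                 df_E = fits$df_E[1],
                 df_pooled = sum(keep) * fits$df_E[1]),
            class = "global_variance")
}

#' @export
print.global_variance <- function(x, ...) {
  cat(sprintf("global residual variance: %.6g (log2^2)\n", x$sigma2))
  cat(sprintf("genes retained after trimming [%g, %g]: %d (pooled df %d)\n",
              x$trim_low_q, x$trim_high_q, x$n_retained, x$df_pooled))
  invisible(x)
}

#' Contrast test statistics against the global variance
#'
#' For each gene and each of the three factorial contrasts — genotype (G),
#' nitrate (N) and interaction (GxN) — the test statistic is the contrast
#' sum of squares scaled by the global residual variance,
#' `T_c = SS_c / sigma2`. Because the global variance is pooled over
#' thousands of genes its sampling error is negligible and it is treated as
#' known: under the null `T_c ~ chi-square(1)`, and the raw p-value is the
#' upper-tail probability. An F(1, pooled df) reference is available via
#' `reference = "f"`; at the pooled df of a genome-scale experiment the two
#' are numerically indistinguishable. Genes with `SS_c = 0` (including
#' zero-total-variance genes) get p = 1.
#'
#' @param fits a [fit_gene_anova()] result.
#' @param gv a [estimate_global_variance()] result (or any list with a
#'   positive `sigma2`).
#' @param reference `"chisq"` (default) or `"f"`.
#' @return data.frame of class `contrast_table` with columns `probe_id`,
#'   `T_G`, `p_G`, `T_N`, `p_N`, `T_GxN`, `p_GxN`.
#' @export
contrast_tests <- function(fits, gv, reference = c("chisq", "f")) {
  stopifnot(inherits(fits, "gene_anova"))
  reference <- match.arg(reference)
  if (!is.numeric(gv$sigma2) || gv$sigma2 <= 0) {
    stop_input("global variance must be > 0")
  }
  pfun <- if (reference == "chisq") {
    function(t) stats::pchisq(t, df = 1, lower.tail = FALSE)
  } else {
    df2 <- gv$df_pooled
    function(t) stats::pf(t, df1 = 1, df2 = df2, lower.tail = FALSE)
  }
  out <- data.frame(probe_id = fits$probe_id, stringsAsFactors = FALSE)
  for (c_ in c("G", "N", "GxN")) {
    t_ <- fits[[paste0("SS_", c_)]] / gv$sigma2
    out[[paste0("T_", c_)]] <- t_
    out[[paste0("p_", c_)]] <- pfun(t_)
  }
  attr(out, "reference") <- reference
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Bonferroni family-wise error adjustment
#'
#' Adjusts the raw p-values of each contrast independently:
#' `p_adj = min(1, m * p_raw)`, controlling the family-wise error rate over
#' the `m` genes tested for that contrast. The multiplicity universe `m`
#' defaults to the number of genes in the table (i.e. the expression-filtered
#' set), and may be set to the pre-filter probe count instead.
#'
#' @param table a [contrast_tests()] result.
#' @param m number of tests per contrast family (>= 1).
#' @return the table with added `padj_G`, `padj_N`, `padj_GxN` columns and
#'   attribute `m`.
#' @export
adjust_bonferroni <- function(table, m = nrow(table)) {
  stopifnot(inherits(table, "contrast_table"))
  if (!is_count(m, 1)) stop_input("m must be an integer >= 1")
  for (c_ in c("G", "N", "GxN")) {
    table[[paste0("padj_", c_)]] <- pmin(1, m * table[[paste0("p_", c_)]])
  }
  attr(table, "m") <- as.integer(m)
  table
}
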