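# Shared in-code fixtures: small balanced designs built programmatically.

balanced_design <- function(r = 3) {
  cells <- expand.grid(replicate = seq_len(r),
                       nitrate = c("HN", "LN"),
                       genotype = c("WT", "MUT"),
                       stringsAsFactors = FALSE)
  data.frame(sample_id = paste(cells$genotype, cells$nitrate,
                               cells$replicate, sep = "_"),
             genotype = cells$genotype, nitrate = cells$nitrate,
             replicate = cells$replicate, stringsAsFactors = FALSE)
}

# Build an expression_matrix from a genes x samples value matrix (columns
# ordered as balanced_design(r)).
make_matrix <- function(values, r = ncol(values) / 4) {
  des <- balanced_design(r)
  dimnames(values) <- list(
    if (is.null(rownames(values))) sprintf("g%03d", seq_len(nrow(values)))
    else rownames(values),
    des$sample_id
  )
  expression_matrix(values, des)
}

# One gene given as its four cell value sets, order WT-HN, WT-LN, MUT-HN,
# MUT-LN (replicates within cell).
one_gene_matrix <- function(wt_hn, wt_ln, mut_hn, mut_ln) {
  r <- length(wt_hn)
  des <- balanced_design(r)
  ord <- order(match(des$genotype, c("WT", "MUT")),
               match(des$nitrate, c("HN", "LN")), des$replicate)
  vals <- matrix(NA_real_, 1, 4 * r)
  vals[ord] <- c(wt_hn, wt_ln, mut_hn, mut_ln)
  make_matrix(vals, r)
}

# The reference worked example used throughout the ANOVA tests.
worked_example_matrix <- function() {
  one_gene_matrix(c(10, 12), c(9, 11), c(14, 16), c(13, 15))
}

# Brute-force least-squares oracle for the factorial SS decomposition:
# sequential projections via stats::anova on the balanced design.
anova_oracle <- function(x) {
  des <- x$design
  g <- factor(des$genotype, c("WT", "MUT"))
  n <- factor(des$nitrate, c("HN", "LN"))
  t(apply(x$values, 1, function(y) {
    a <- stats::anova(stats::lm(y ~ g * n))
    c(SS_G = a["g", "Sum Sq"], SS_N = a["n", "Sum Sq"],
      SS_GxN = a["g:n", "Sum Sq"], SS_E = a["Residuals", "Sum Sq"])
  }))
}
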