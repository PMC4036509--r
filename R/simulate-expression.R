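#' Configuration for the factorial expression simulator
#'
#' Describes a balanced 2 genotypes x 2 nitrate levels x `n_replicates`
#' microarray experiment on the normalized log2 scale. Fractions of genes
#' carry additive genotype, nitrate and interaction effects; the three gene
#' subsets are drawn independently, so overlaps (genes responsive to two or
#' three effects) arise naturally as they do in real factorial screens.
#'
#' Effect sizes are in log2 units and may be a single signed value (applied
#' to every affected gene) or a length-2 interval from which per-gene sizes
#' are drawn uniformly. Main effects are split +/- e/2 across the two levels
#' so the marginal-mean difference (MUT - WT, resp. LN - HN) equals the
#' nominal size; the interaction is planted as (+i/4, -i/4, -i/4, +i/4) on
#' the four cells so the classical 2x2 interaction contrast equals `i`.
#'
#' @param n_genes number of probes.
#' @param n_replicates biological replicates per genotype-by-nitrate cell
#'   (>= 2; the study design uses 3).
#' @param prop_G,prop_N,prop_GxN fractions in \[0,1\] of genes carrying each
#'   effect.
#' @param effect_size_G,effect_size_N,effect_size_GxN log2 effect, scalar or
#'   `c(lo, hi)` sampling interval.
#' @param baseline_range log2 interval for per-gene baseline means
#'   (default `c(2, 14)`, the span of normalized array intensities).
#' @param noise_sd residual Gaussian noise sd in log2 units (> 0).
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return an object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 2000, n_replicates = 3,
                                  prop_G = 0.05, prop_N = 0.05,
                                  prop_GxN = 0.01,
                                  effect_size_G = 2, effect_size_N = 2,
                                  effect_size_GxN = 2,
                                  baseline_range = c(2, 14),
                                  noise_sd = 0.5, seed = 1) {
  if (!is_count(n_genes, 1)) stop_input("n_genes must be a positive count")
  if (!is_count(n_replicates, 2)) {
    stop_input("n_replicates must be an integer >= 2")
  }
  for (p in c(prop_G = prop_G, prop_N = prop_N, prop_GxN = prop_GxN)) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop_input("effect fractions must lie in [0, 1]")
    }
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || !is.finite(noise_sd) ||
      noise_sd <= 0) {
    stop_input("noise_sd must be > 0")
  }
  if (length(baseline_range) != 2 || baseline_range[1] > baseline_range[2]) {
    stop_input("baseline_range must be c(lo, hi) with lo <= hi")
  }
  for (e in list(effect_size_G, effect_size_N, effect_size_GxN)) {
    if (!is.numeric(e) || !length(e) %in% 1:2 || any(!is.finite(e))) {
      stop_input("effect sizes must be a finite scalar or length-2 interval")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 prop_G = prop_G, prop_N = prop_N, prop_GxN = prop_GxN,
                 effect_size_G = effect_size_G,
                 effect_size_N = effect_size_N,
                 effect_size_GxN = effect_size_GxN,
                 baseline_range = baseline_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expression_sim_config")
}

draw_effect <- function(flag, size, n) {
  e <- numeric(n)
  if (!any(flag)) return(e)
  e[flag] <- if (length(size) == 1) size else
    stats::runif(sum(flag), size[1], size[2])
  e
}

#' Simulate a balanced factorial expression matrix with known ground truth
#'
#' Generates per-gene log2 cell means from the additive 2x2 factorial model
#' described in [expression_sim_config()], adds i.i.d. Gaussian noise, and
#' returns both the [expression_matrix()] and the planted truth. Sample
#' columns are ordered WT-HN, WT-LN, MUT-HN, MUT-LN, replicates within cell.
#'
#' @param config an [expression_sim_config()].
#' @return list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (data.frame: `probe_id`, logical `has_G`/`has_N`/`has_GxN`,
#'   signed `effect_G`/`effect_N`/`effect_GxN` in log2 units, zero wherever
#'   the flag is `FALSE`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  ng <- config$n_genes
  r <- config$n_replicates

  baseline <- with_seed(sub_seed(config$seed, 1), {
    stats::runif(ng, config$baseline_range[1], config$baseline_range[2])
  })
  flags <- with_seed(sub_seed(config$seed, 2), {
    list(G = stats::runif(ng) < config$prop_G,
         N = stats::runif(ng) < config$prop_N,
         GxN = stats::runif(ng) < config$prop_GxN)
  })
  effects <- with_seed(sub_seed(config$seed, 3), {
    list(G = draw_effect(flags$G, config$effect_size_G, ng),
         N = draw_effect(flags$N, config$effect_size_N, ng),
         GxN = draw_effect(flags$GxN, config$effect_size_GxN, ng))
  })

  cells <- expand.grid(replicate = seq_len(r),
                       nitrate = c("HN", "LN"),
                       genotype = c("WT", "MUT"),
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$genotype, c("WT", "MUT")),
                       match(cells$nitrate, c("HN", "LN")),
                       cells$replicate), ]
  sample_id <- paste(cells$genotype, cells$nitrate, cells$replicate, sep = "_")
  gcode <- ifelse(cells$genotype == "MUT", 0.5, -0.5)
  ncode <- ifelse(cells$nitrate == "LN", 0.5, -0.5)

  # gene x sample matrix of true means; interaction offset is gcode*ncode*i
  # (= +/- i/4 on the four cells)
  mu <- baseline +
    outer(effects$G, gcode) +
    outer(effects$N, ncode) +
    outer(effects$GxN, gcode * ncode)
  noise <- with_seed(sub_seed(config$seed, 4), {
    matrix(stats::rnorm(ng * length(sample_id), sd = config$noise_sd),
           nrow = ng)
  })
  values <- mu + noise
  dimnames(values) <- list(sprintf("probe_%05d", seq_len(ng)), sample_id)

  design <- data.frame(sample_id = sample_id,
                       genotype = cells$genotype,
                       nitrate = cells$nitrate,
                       replicate = cells$replicate,
                       stringsAsFactors = FALSE)
  truth <- data.frame(probe_id = rownames(values),
                      has_G = flags$G, has_N = flags$N, has_GxN = flags$GxN,
                      effect_G = effects$G, effect_N = effects$N,
                      effect_GxN = effects$GxN,
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(values, design), truth = truth)
}
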