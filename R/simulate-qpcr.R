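#' Simulate a qPCR validation plate with known fold changes
#'
#' Emulates a relative-standard-curve validation experiment: target genes
#' measured in two conditions (`A` = calibrator, `B` = treatment) with
#' `n_bio` biological and `n_tech` technical replicates, two reference
#' genes (`EF1`, `UBQ`, fold change 1 by construction), and a 5-point
#' 10-fold serial-dilution standard series per gene.
#'
#' CT values follow the standard-curve model
#' `CT = intercept - log(quantity) / log(E)` with per-gene amplification
#' efficiency `E` (1 < E <= 2), plus Gaussian technical noise on the CT
#' scale. A per-sample loading factor (shared by all genes of a sample,
#' lognormal on the log2 scale) emulates input-amount differences; the
#' dual-reference normalization must cancel it.
#'
#' @param n_genes number of target genes.
#' @param fold_changes per-target-gene true expression ratio B/A (> 0,
#'   recycled).
#' @param efficiencies per-target-gene amplification efficiency in (1, 2]
#'   (recycled). Reference genes amplify at E = 2.
#' @param n_bio,n_tech biological and technical replicates (defaults 3, 3).
#' @param ct_noise_sd technical CT noise sd in cycles (default 0.1; 0 gives
#'   noise-free plates).
#' @param loading_sd sd (log2) of per-sample loading factors (default 0.25).
#' @param seed integer seed.
#' @return a data.frame of wells (class `qpcr_dataset`) with columns
#'   `gene`, `sample_id`, `condition`, `biological_replicate`,
#'   `technical_replicate`, `role` (`"unknown"`/`"standard"`),
#'   `standard_quantity` (NA for unknowns), `CT`; the planted truth is in
#'   `attr(, "truth")` (`fold_changes`, `efficiencies`, `intercepts`).
#' @export
simulate_qpcr <- function(n_genes = 3, fold_changes = 2, efficiencies = 2,
                          n_bio = 3, n_tech = 3, ct_noise_sd = 0.1,
                          loading_sd = 0.25, seed = 1) {
  if (!is_count(n_genes, 1)) stop_input("n_genes must be a positive count")
  fold_changes <- rep_len(fold_changes, n_genes)
  efficiencies <- rep_len(efficiencies, n_genes)
  if (any(fold_changes <= 0)) stop_input("fold_changes must be > 0")
  if (any(efficiencies <= 1 | efficiencies > 2)) {
    stop_input("efficiencies must lie in (1, 2]")
  }
  if (ct_noise_sd < 0) stop_input("ct_noise_sd must be >= 0")

  targets <- sprintf("T%02d", seq_len(n_genes))
  refs <- c("EF1", "UBQ")
  genes <- c(targets, refs)
  eff <- c(efficiencies, 2, 2)
  fold <- c(fold_changes, 1, 1)
  names(eff) <- names(fold) <- genes

  intercepts <- with_seed(sub_seed(seed, 1), {
    stats::setNames(stats::runif(length(genes), 24, 32), genes)
  })

  samples <- expand.grid(biological_replicate = seq_len(n_bio),
                         condition = c("A", "B"),
                         stringsAsFactors = FALSE)
  samples$sample_id <- paste(samples$condition,
                             samples$biological_replicate, sep = "_")
  loading <- with_seed(sub_seed(seed, 2), {
    stats::setNames(2^stats::rnorm(nrow(samples), 0, loading_sd),
                    samples$sample_id)
  })

  wells_unknown <- expand.grid(gene = genes, s = seq_len(nrow(samples)),
                               technical_replicate = seq_len(n_tech),
                               stringsAsFactors = FALSE)
  q <- fold[wells_unknown$gene] ^
    (samples$condition[wells_unknown$s] == "B") *
    loading[samples$sample_id[wells_unknown$s]]
  unknown <- data.frame(
    gene = wells_unknown$gene,
    sample_id = samples$sample_id[wells_unknown$s],
    condition = samples$condition[wells_unknown$s],
    biological_replicate = samples$biological_replicate[wells_unknown$s],
    technical_replicate = wells_unknown$technical_replicate,
    role = "unknown", standard_quantity = NA_real_,
    CT = intercepts[wells_unknown$gene] -
      log(q) / log(eff[wells_unknown$gene]),
    stringsAsFactors = FALSE
  )

  std_q <- 10^(0:-4)
  standards <- expand.grid(gene = genes, standard_quantity = std_q,
                           stringsAsFactors = FALSE)
  standards <- data.frame(
    gene = standards$gene, sample_id = NA_character_,
    condition = NA_character_, biological_replicate = NA_integer_,
    technical_replicate = 1L, role = "standard",
    standard_quantity = standards$standard_quantity,
    CT = intercepts[standards$gene] -
      log(standards$standard_quantity) / log(eff[standards$gene]),
    stringsAsFactors = FALSE
  )

  wells <- rbind(unknown, standards)
  wells$CT <- wells$CT + with_seed(sub_seed(seed, 3), {
    stats::rnorm(nrow(wells), 0, ct_noise_sd)
  })
  rownames(wells) <- NULL
  structure(wells,
            class = c("qpcr_dataset", "data.frame"),
            truth = list(fold_changes = fold[targets],
                         efficiencies = eff, intercepts = intercepts,
                         reference_genes = refs))
}
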