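# Reproducible end-to-end runners. Each run_*() wires the corresponding
# analysis stages together, writes fixed-name TSV outputs plus a JSON run
# report under `outdir`, and returns the report invisibly. Identical
# configuration and inputs give byte-identical outputs.

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- format_full(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Generate and write a full synthetic study
#'
#' Runs all three simulators and writes their outputs: expression matrix +
#' sample metadata (+ ground-truth JSON), tidy phenotype records, and qPCR
#' wells.
#'
#' @param outdir output directory (created if missing).
#' @param expr_config an [expression_sim_config()].
#' @param growth_config a [growth_sim_config()].
#' @param qpcr_args list of arguments to [simulate_qpcr()].
#' @return invisibly, the run report (also written to `simulate_report.json`).
#' @export
run_simulate <- function(outdir,
                         expr_config = expression_sim_config(),
                         growth_config = growth_sim_config(),
                         qpcr_args = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  expr <- simulate_expression(expr_config)
  write_expression_matrix(expr$matrix,
                          file.path(outdir, "expression.tsv"),
                          file.path(outdir, "samples.tsv"))
  write_tsv(expr$truth, file.path(outdir, "expression_truth.tsv"))

  growth <- simulate_growth(growth_config)
  write_tsv(growth$records, file.path(outdir, "phenotypes.tsv"))
  jsonlite::write_json(growth$truth, file.path(outdir, "growth_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  wells <- do.call(simulate_qpcr, qpcr_args)
  write_tsv(as.data.frame(wells), file.path(outdir, "qpcr_wells.tsv"))
  jsonlite::write_json(attr(wells, "truth"),
                       file.path(outdir, "qpcr_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- list(
    stage = "simulate",
    seeds = list(expression = expr_config$seed, growth = growth_config$seed,
                 qpcr = if (is.null(qpcr_args$seed)) 1L else qpcr_args$seed),
    n_genes = expr_config$n_genes,
    n_replicates = expr_config$n_replicates,
    outputs = list.files(outdir)
  )
  write_report(report, file.path(outdir, "simulate_report.json"))
  invisible(report)
}

#' Run the differential-expression pipeline on files
#'
#' Reads an expression matrix and its metadata, fits [pooled_anova()] and
#' writes the per-gene results table (cell means, SS components, s2,
#' statistics, raw/adjusted p, declared flags, genotype/nitrate direction),
#' a Venn summary JSON, optional external-list overlaps, and a JSON run
#' report with every threshold used.
#'
#' @param matrix_path,metadata_path input TSVs
#'   (see [read_expression_matrix()]).
#' @param outdir output directory.
#' @param alpha,filter_threshold,trim_q,m,reference passed to
#'   [pooled_anova()].
#' @param magnitude_threshold log2 cutoff for the `strong` direction flag.
#' @param lists optional named list of paths to one-id-per-line gene lists
#'   for [overlap_with_lists()] against the declared N-or-GxN set.
#' @return invisibly, the run report (also written to `de_report.json`).
#' @export
run_de <- function(matrix_path, metadata_path, outdir, alpha = 0.05,
                   filter_threshold = 4, trim_q = c(0.025, 0.975),
                   m = NULL, reference = "chisq", magnitude_threshold = 1,
                   lists = NULL) {
  mat <- tryCatch(read_expression_matrix(matrix_path, metadata_path),
                  error = function(e) {
                    stop_input("stage expression_io: %s", conditionMessage(e))
                  })
  fit <- pooled_anova(mat, filter_threshold = filter_threshold,
                      trim_q = trim_q, m = m, alpha = alpha,
                      reference = reference)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  res <- merge(fit$fits, fit$contrasts, by = "probe_id", sort = FALSE)
  res <- merge(res, fit$classification$flags, by = "probe_id", sort = FALSE)
  dirs_g <- effect_direction(fit$fits, "G", magnitude_threshold)
  dirs_n <- effect_direction(fit$fits, "N", magnitude_threshold)
  res$direction_G <- dirs_g$direction[match(res$probe_id, dirs_g$probe_id)]
  res$strong_G <- dirs_g$strong[match(res$probe_id, dirs_g$probe_id)]
  res$direction_N <- dirs_n$direction[match(res$probe_id, dirs_n$probe_id)]
  res$strong_N <- dirs_n$strong[match(res$probe_id, dirs_n$probe_id)]
  write_tsv(res, file.path(outdir, "de_results.tsv"))

  venn <- fit$classification$venn
  jsonlite::write_json(list(totals = as.list(venn$totals),
                            cells = venn$cells, union = venn$union),
                       file.path(outdir, "venn.json"),
                       auto_unbox = TRUE, digits = NA)

  overlap <- NULL
  if (!is.null(lists)) {
    idsets <- lapply(lists, read_gene_list)
    declared <- fit$classification$flags
    target <- declared$probe_id[declared$declared_N | declared$declared_GxN]
    overlap <- overlap_with_lists(target, idsets)
    write_tsv(data.frame(list = names(overlap$overlaps),
                         overlap = as.integer(overlap$overlaps)),
              file.path(outdir, "overlaps.tsv"))
  }

  report <- list(
    stage = "de",
    inputs = list(matrix = matrix_path, metadata = metadata_path),
    filter_threshold = filter_threshold,
    n_probes = fit$n_probes, n_expressed = fit$n_expressed,
    n_removed = fit$n_removed,
    trim_q = trim_q, sigma2 = fit$global_variance$sigma2,
    n_retained = fit$global_variance$n_retained,
    reference = fit$reference, m = fit$m, alpha = alpha,
    declared = as.list(venn$totals), union = venn$union,
    overlaps = if (is.null(overlap)) NULL else as.list(overlap$overlaps)
  )
  write_report(report, file.path(outdir, "de_report.json"))
  invisible(report)
}

#' Run the ecophysiology stage on a phenotype file
#'
#' Reads tidy per-plant records, derives LRL/TDW/TotN/rdw_ratio, computes
#' interval NUR and NLA per genotype-by-nitrate group, and writes LSD
#' letter tables per variable and day.
#'
#' @param phenotype_path tidy TSV, one row per plant per day (columns as in
#'   [simulate_growth()] records).
#' @param outdir output directory.
#' @param alpha LSD significance level.
#' @param nur_basis `"area"` or `"rdw"` (see [interval_efficiencies()]).
#' @param lsd_variables record columns to letter-group (default the main
#'   state and derived variables).
#' @return invisibly, the run report (also written to `ecophys_report.json`).
#' @export
run_ecophys <- function(phenotype_path, outdir, alpha = 0.05,
                        nur_basis = "area",
                        lsd_variables = c("LRN", "LRL", "TRL", "SDW",
                                          "RDW", "rdw_ratio", "LeafA")) {
  if (!file.exists(phenotype_path)) {
    stop_input("stage ecophysiology: phenotype file not found: %s",
               phenotype_path)
  }
  records <- utils::read.delim(phenotype_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  records <- derive_plant_variables(records)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(records, file.path(outdir, "derived_variables.tsv"))

  eff <- interval_efficiencies(records, nur_basis = nur_basis)
  write_tsv(as.data.frame(eff), file.path(outdir, "efficiency_metrics.tsv"))

  lsd_rows <- NULL
  for (v in intersect(lsd_variables, names(records))) {
    by_day <- lsd_by_day(records, v, alpha = alpha)
    for (d in names(by_day)) {
      g <- by_day[[d]]$groups
      lsd_rows <- rbind(lsd_rows,
                        cbind(variable = v, day = as.numeric(d), g))
    }
  }
  write_tsv(lsd_rows, file.path(outdir, "lsd_letters.tsv"))

  report <- list(stage = "ecophys", input = phenotype_path,
                 alpha = alpha, nur_basis = nur_basis,
                 n_records = nrow(records),
                 n_groups = nrow(unique(records[c("genotype", "nitrate")])),
                 days = sort(unique(records$day)))
  write_report(report, file.path(outdir, "ecophys_report.json"))
  invisible(report)
}

#' Run the qPCR quantification stage on a wells file
#'
#' @param wells_path wells TSV (columns as in [simulate_qpcr()]).
#' @param outdir output directory.
#' @param ref_genes,combine passed to [quantify_qpcr()].
#' @return invisibly, the run report (also written to `qpcr_report.json`).
#' @export
run_qpcr <- function(wells_path, outdir, ref_genes = c("EF1", "UBQ"),
                     combine = "geomean") {
  if (!file.exists(wells_path)) {
    stop_input("stage qpcr: wells file not found: %s", wells_path)
  }
  wells <- utils::read.delim(wells_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  quant <- quantify_qpcr(wells, ref_genes = ref_genes, combine = combine)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(quant$expression, file.path(outdir, "relative_expression.tsv"))
  if (length(quant$curves)) {
    curves <- do.call(rbind, lapply(quant$curves, function(cv) {
      data.frame(gene = cv$gene, slope = cv$slope, intercept = cv$intercept,
                 efficiency = cv$efficiency, r_squared = cv$r_squared,
                 n_points = cv$n_points, stringsAsFactors = FALSE)
    }))
    write_tsv(curves, file.path(outdir, "standard_curves.tsv"))
  }
  report <- list(stage = "qpcr", input = wells_path,
                 ref_genes = ref_genes, combine = combine,
                 n_genes = length(unique(quant$expression$gene)),
                 n_samples = length(unique(quant$expression$sample_id)))
  write_report(report, file.path(outdir, "qpcr_report.json"))
  invisible(report)
}
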