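#' Declare differentially expressed genes and partition them Venn-wise
#'
#' A gene is declared responsive to a contrast when its Bonferroni-adjusted
#' p-value is strictly below `alpha`. The three declared sets (G, N, GxN)
#' overlap — genes may respond to two or three effects — so both the
#' overlapping totals and the seven disjoint Venn cells are reported.
#'
#' @param table a [contrast_tests()] result with adjusted p-values
#'   (see [adjust_bonferroni()]).
#' @param alpha declaration level in (0, 1), default 0.05.
#' @return list of class `de_classification`: `flags` (data.frame
#'   `probe_id`, `declared_G`, `declared_N`, `declared_GxN`), `venn`
#'   (list with `totals` = overlapping set sizes, `cells` = the 7 disjoint
#'   intersection counts, `union`) and `alpha`.
#' @export
classify_de <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "contrast_table"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_input("alpha must lie in (0, 1)")
  }
  need <- paste0("padj_", c("G", "N", "GxN"))
  if (!all(need %in% names(table))) {
    stop_input("adjusted p-values missing; run adjust_bonferroni() first")
  }
  g <- table$padj_G < alpha
  n <- table$padj_N < alpha
  i <- table$padj_GxN < alpha
  flags <- data.frame(probe_id = table$probe_id,
                      declared_G = g, declared_N = n, declared_GxN = i,
                      stringsAsFactors = FALSE)
  cells <- list(
    G_only = sum(g & !n & !i),
    N_only = sum(!g & n & !i),
    GxN_only = sum(!g & !n & i),
    G_N = sum(g & n & !i),
    G_GxN = sum(g & !n & i),
    N_GxN = sum(!g & n & i),
    G_N_GxN = sum(g & n & i)
  )
  venn <- list(totals = c(G = sum(g), N = sum(n), GxN = sum(i)),
               cells = cells,
               union = sum(g | n | i))
  structure(list(flags = flags, venn = venn, alpha = alpha),
            class = "de_classification")
}

#' @export
print.de_classification <- function(x, ...) {
  cat(sprintf("differential-expression classification at alpha = %g\n",
              x$alpha))
  cat(sprintf("  declared: G %d, N %d, GxN %d; union %d\n",
              x$venn$totals[["G"]], x$venn$totals[["N"]],
              x$venn$totals[["GxN"]], x$venn$union))
  invisible(x)
}

#' Direction and magnitude of a main-effect difference
#'
#' For the genotype contrast the direction is the sign of the MUT - WT
#' marginal mean difference (`up_in_MUT` / `down_in_MUT`); for the nitrate
#' contrast, LN - HN (`up_in_LN` / `down_in_LN`). A gene is flagged
#' `strong` when the absolute log2 difference exceeds
#' `magnitude_threshold`. The interaction has no single direction — use the
#' cell means instead — and is rejected. An exactly zero difference is
#' reported as "down" with `tie = TRUE` so the output stays deterministic.
#'
#' @param fits a [fit_gene_anova()] result (any subset of rows).
#' @param contrast `"G"` or `"N"`.
#' @param magnitude_threshold log2 magnitude cutoff for `strong`
#'   (default 1).
#' @return data.frame: `probe_id`, `difference` (log2), `direction`,
#'   `strong`, `tie`.
#' @export
effect_direction <- function(fits, contrast = c("G", "N"),
                             magnitude_threshold = 1) {
  stopifnot(inherits(fits, "gene_anova") || is.data.frame(fits))
  contrast <- tryCatch(match.arg(contrast), error = function(e) {
    stop_input("contrast must be \"G\" or \"N\" (the interaction has no single direction; report cell means instead)")
  })
  d <- if (contrast == "G") fits$mean_MUT - fits$mean_WT
  else fits$mean_LN - fits$mean_HN
  up <- if (contrast == "G") "up_in_MUT" else "up_in_LN"
  down <- if (contrast == "G") "down_in_MUT" else "down_in_LN"
  data.frame(probe_id = fits$probe_id,
             difference = d,
             direction = ifelse(d > 0, up, down),
             strong = abs(d) > magnitude_threshold,
             tie = d == 0,
             stringsAsFactors = FALSE)
}

#' Overlap of a declared gene set with external gene lists
#'
#' Computes exact intersection sizes between a declared set of probe ids
#' and any number of named external lists (e.g. previously published
#' nitrate-regulated gene sets), plus pairwise co-membership counts among
#' the declared genes. No identifier translation is attempted; ids must
#' share a namespace.
#'
#' @param declared_ids character vector of declared probe ids.
#' @param lists named list of character vectors.
#' @return list of class `overlap_report`: `overlaps` (named counts),
#'   `pairwise` (matrix of counts of declared ids in both lists),
#'   `in_any` (declared ids found in at least one list) and `members`
#'   (logical membership matrix, declared ids x lists).
#' @export
overlap_with_lists <- function(declared_ids, lists) {
  declared_ids <- unique(as.character(declared_ids))
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    stop_input("lists must be a named list of id vectors")
  }
  members <- vapply(lists, function(l) declared_ids %in% l,
                    logical(length(declared_ids)))
  members <- matrix(members, nrow = length(declared_ids),
                    ncol = length(lists),
                    dimnames = list(declared_ids, names(lists)))
  overlaps <- colSums(members)
  k <- length(lists)
  pairwise <- matrix(0L, k, k, dimnames = list(names(lists), names(lists)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    pairwise[a, b] <- sum(members[, a] & members[, b])
  }
  structure(list(overlaps = overlaps, pairwise = pairwise,
                 in_any = sum(rowSums(members) > 0), members = members),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap with external lists:\n")
  print(x$overlaps)
  cat(sprintf("declared ids in >= 1 list: %d\n", x$in_any))
  invisible(x)
}

#' Read a one-id-per-line gene list
#'
#' @param path text file, one probe id per line; blank lines ignored.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_input("gene list not found: %s", path)
  ids <- trimws(readLines(path, encoding = "UTF-8"))
  ids[nzchar(ids)]
}
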