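#' Fit a qPCR standard curve
#'
#' Least-squares regression of CT on log10(quantity) over a serial-dilution
#' standard series. The slope gives the amplification efficiency
#' `E = 10^(-1/slope)`; perfect doubling chemistry has slope -3.321928 and
#' E = 2.
#'
#' @param standards data.frame of standard wells for one gene with columns
#'   `CT` and `standard_quantity` (> 0); at least 3 distinct dilution
#'   points are required.
#' @return list of class `standard_curve`: `gene` (if present in the
#'   input), `slope` (cycles per log10 quantity), `intercept` (CT at
#'   quantity 1), `efficiency`, `r_squared`, `n_points`.
#' @export
fit_standard_curve <- function(standards) {
  if (!all(c("CT", "standard_quantity") %in% names(standards))) {
    stop_input("standards need columns CT and standard_quantity")
  }
  q <- standards$standard_quantity
  if (any(is.na(q)) || any(q <= 0)) {
    stop_input("standard quantities must be positive")
  }
  if (length(unique(q)) < 3) {
    stop_input("need >= 3 distinct dilution points, got %d",
               length(unique(q)))
  }
  fit <- stats::lm(CT ~ log10(q), data = data.frame(CT = standards$CT, q = q))
  sst <- sum((standards$CT - mean(standards$CT))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop_input("standard-curve slope must be negative (got %g): CT must fall with template quantity",
               slope)
  }
  eff <- 10^(-1 / slope)
  if (eff > 2.2) {
    warning(sprintf("implausible amplification efficiency %.3f (> 2.2)", eff))
  }
  structure(list(gene = if ("gene" %in% names(standards))
                   as.character(standards$gene[1]) else NA_character_,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = eff,
                 r_squared = r2,
                 n_points = length(unique(q))),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve%s: CT = %.4f %+.4f * log10(q); E = %.4f, r2 = %.4f\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$intercept, x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

#' Quantity from CT via a fitted standard curve
#'
#' Inverts the standard-curve model: `quantity = 10^((ct - intercept) /
#' slope)`, monotone decreasing in CT.
#'
#' @param ct CT value(s) in cycles.
#' @param curve a [fit_standard_curve()] result.
#' @return relative quantities (same units as the standard series).
#' @export
relative_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Relative expression by the standard-curve (delta-CT) method
#'
#' Full quantification of a well table: technical replicates are averaged
#' on the CT scale (the near-Gaussian measurement scale), per-gene standard
#' curves are fitted from the `role == "standard"` wells, CTs are converted
#' to quantities, and each sample's target quantities are divided by a
#' normalization factor built from the reference genes — by default the
#' geometric mean of the two reference quantities.
#'
#' @param wells data.frame of wells (layout of [simulate_qpcr()]): columns
#'   `gene`, `sample_id`, `technical_replicate`, `role`,
#'   `standard_quantity`, `CT`, plus any annotation columns (`condition`,
#'   `biological_replicate`) which are carried through.
#' @param ref_genes character vector of reference gene names (default
#'   `c("EF1", "UBQ")`); every sample must have every reference measured.
#' @param combine how to combine multiple reference quantities:
#'   `"geomean"` (default) or `"mean"`.
#' @param assume_e2 if `TRUE`, skip curve fitting and use the exact-doubling
#'   shortcut `quantity = 2^(-CT)` for every gene (quantities are then on
#'   an arbitrary common scale; ratios are unaffected).
#' @return list of class `qpcr_quantification`: `expression` (data.frame
#'   `gene`, `sample_id`, annotation columns, `mean_CT`, `quantity`,
#'   `normalized_expression`), `curves` (named list of
#'   [fit_standard_curve()] results, empty under `assume_e2`),
#'   `ref_genes`, `combine`.
#' @export
quantify_qpcr <- function(wells, ref_genes = c("EF1", "UBQ"),
                          combine = c("geomean", "mean"),
                          assume_e2 = FALSE) {
  combine <- match.arg(combine)
  req <- c("gene", "sample_id", "role", "CT")
  if (!all(req %in% names(wells))) {
    stop_input("wells need columns %s", paste(req, collapse = ", "))
  }
  unknowns <- wells[wells$role == "unknown", ]
  if (!nrow(unknowns)) stop_input("no unknown wells to quantify")
  genes <- unique(unknowns$gene)
  missing_ref <- setdiff(ref_genes, genes)
  if (length(missing_ref)) {
    stop_input("reference gene(s) never measured: %s",
               paste(missing_ref, collapse = ", "))
  }

  curves <- list()
  if (!assume_e2) {
    stds <- wells[wells$role == "standard", ]
    for (g in genes) {
      sg <- stds[stds$gene == g, ]
      if (!nrow(sg)) stop_input("no standard series for gene %s", g)
      curves[[g]] <- fit_standard_curve(sg)
    }
  }

  # technical replicates -> mean CT per (gene, sample)
  ann_cols <- intersect(c("condition", "biological_replicate"),
                        names(unknowns))
  agg <- stats::aggregate(unknowns["CT"],
                          by = unknowns[c("gene", "sample_id", ann_cols)],
                          FUN = mean)
  names(agg)[names(agg) == "CT"] <- "mean_CT"
  agg$quantity <- if (assume_e2) 2^(-agg$mean_CT) else {
    vapply(seq_len(nrow(agg)), function(i) {
      relative_quantity(agg$mean_CT[i], curves[[agg$gene[i]]])
    }, numeric(1))
  }

  samples <- unique(agg$sample_id)
  nf <- vapply(samples, function(s) {
    rq <- vapply(ref_genes, function(g) {
      v <- agg$quantity[agg$sample_id == s & agg$gene == g]
      if (!length(v)) {
        stop_input("sample %s lacks reference gene %s", s, g)
      }
      v[1]
    }, numeric(1))
    if (combine == "geomean") exp(mean(log(rq))) else mean(rq)
  }, numeric(1))
  names(nf) <- samples

  agg$normalized_expression <- agg$quantity / nf[agg$sample_id]
  agg <- agg[order(agg$gene, agg$sample_id), ]
  rownames(agg) <- NULL
  structure(list(expression = agg, curves = curves,
                 ref_genes = ref_genes, combine = combine,
                 normalization_factors = nf),
            class = "qpcr_quantification")
}

#' @export
print.qpcr_quantification <- function(x, ...) {
  cat(sprintf("qPCR quantification: %d genes x %d samples, references %s (%s)\n",
              length(unique(x$expression$gene)),
              length(unique(x$expression$sample_id)),
              paste(x$ref_genes, collapse = "+"), x$combine))
  invisible(x)
}

#' Condition fold changes from a qPCR quantification
#'
#' Mean normalized expression in the treatment condition over the mean in
#' the calibrator condition, per gene (reference genes excluded).
#'
#' @param quant a [quantify_qpcr()] result whose expression table carries a
#'   `condition` column.
#' @param treatment,calibrator condition labels (defaults `"B"` and `"A"`,
#'   the [simulate_qpcr()] convention).
#' @return named numeric vector of fold changes.
#' @export
qpcr_fold_changes <- function(quant, treatment = "B", calibrator = "A") {
  stopifnot(inherits(quant, "qpcr_quantification"))
  e <- quant$expression
  if (!"condition" %in% names(e)) {
    stop_input("quantification has no condition annotation")
  }
  targets <- setdiff(unique(e$gene), quant$ref_genes)
  out <- vapply(targets, function(g) {
    num <- mean(e$normalized_expression[e$gene == g & e$condition == treatment])
    den <- mean(e$normalized_expression[e$gene == g & e$condition == calibrator])
    num / den
  }, numeric(1))
  names(out) <- targets
  out
}
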