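#' Expression matrix with a factorial sample design
#'
#' Container for a probes-by-samples matrix of normalized log2 intensities
#' together with the 2 genotypes (`WT`, `MUT`) by 2 nitrate levels
#' (`HN`, `LN`) sample design. All downstream ANOVA machinery consumes this
#' class; values are assumed already normalized (e.g. GC-RMA scale) — no
#' normalization is performed here.
#'
#' @param values numeric matrix, probes in rows, samples in columns; must
#'   have unique, non-empty rownames (probe ids) and colnames (sample ids)
#'   and contain only finite values.
#' @param design data.frame with columns `sample_id`, `genotype`
#'   (`"WT"`/`"MUT"`), `nitrate` (`"HN"`/`"LN"`), `replicate` (positive
#'   integer). Every column of `values` must be described.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `design` (design rows ordered as the matrix columns).
#' @seealso [read_expression_matrix()], [filter_expressed()],
#'   [simulate_expression()]
#' @export
expression_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("`values` must be a numeric matrix")
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop_input("`values` must carry probe ids as rownames and sample ids as colnames")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values))) {
    stop_input("duplicate probe id: %s",
               rownames(values)[anyDuplicated(rownames(values))])
  }
  if (anyDuplicated(colnames(values))) {
    stop_input("duplicate sample id: %s",
               colnames(values)[anyDuplicated(colnames(values))])
  }
  if (any(!is.finite(values))) {
    stop_input("`values` contains non-finite entries")
  }
  design <- validate_design(design)
  missing <- setdiff(colnames(values), design$sample_id)
  if (length(missing)) {
    stop_input("no design metadata for sample(s): %s",
               paste(missing, collapse = ", "))
  }
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

validate_design <- function(design) {
  req <- c("sample_id", "genotype", "nitrate", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    stop_input("design must be a data.frame with columns %s",
               paste(req, collapse = ", "))
  }
  design$sample_id <- as.character(design$sample_id)
  design$genotype <- as.character(design$genotype)
  design$nitrate <- as.character(design$nitrate)
  if (anyDuplicated(design$sample_id)) {
    stop_input("duplicate sample_id in design: %s",
               design$sample_id[anyDuplicated(design$sample_id)])
  }
  bad_g <- setdiff(unique(design$genotype), c("WT", "MUT"))
  if (length(bad_g)) stop_input("unknown genotype level: %s", bad_g[1])
  bad_n <- setdiff(unique(design$nitrate), c("HN", "LN"))
  if (length(bad_n)) stop_input("unknown nitrate level: %s", bad_n[1])
  rep_num <- suppressWarnings(as.integer(design$replicate))
  if (any(is.na(rep_num)) || any(rep_num < 1)) {
    stop_input("replicate must be a positive integer")
  }
  design$replicate <- rep_num
  key <- paste(design$genotype, design$nitrate, design$replicate)
  if (anyDuplicated(key)) {
    stop_input("duplicate (genotype, nitrate, replicate) triple: %s",
               key[anyDuplicated(key)])
  }
  design
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$design$genotype, x$design$nitrate)
  cat("samples per cell:\n")
  print(tab)
  cat(sprintf("balanced 2x2 design: %s\n", is_balanced(x)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Check that all four genotype-by-nitrate cells have equal replicate counts
#'
#' @param x an [expression_matrix()].
#' @return `TRUE` if all four cells of the 2x2 design are present with the
#'   same number of samples, else `FALSE`.
#' @export
is_balanced <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- table(factor(x$design$genotype, c("WT", "MUT")),
               factor(x$design$nitrate, c("HN", "LN")))
  length(unique(as.vector(tab))) == 1 && tab[1] >= 1
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file is tab-separated with a header row of sample ids and a
#' first column of probe ids; the metadata file has columns `sample_id`,
#' `genotype`, `nitrate`, `replicate`. Parse failures report file, line and
#' column so malformed exports are easy to locate.
#'
#' @param matrix_path path to the probes-by-samples TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return a validated [expression_matrix()] with file order preserved.
#' @export
read_expression_matrix <- function(matrix_path, metadata_path) {
  if (!file.exists(matrix_path)) stop_input("matrix file not found: %s", matrix_path)
  if (!file.exists(metadata_path)) stop_input("metadata file not found: %s", metadata_path)

  lines <- readLines(matrix_path, encoding = "UTF-8")
  if (!length(lines)) stop_input("%s: empty file", matrix_path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 1) stop_input("%s: line 1: empty header", matrix_path)
  sample_ids <- header[-1]
  n_samp <- length(sample_ids)

  n_probe <- length(lines) - 1L
  probe_ids <- character(n_probe)
  values <- if (n_probe > 0) {
    fields <- strsplit(lines[-1], "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != n_samp + 1L)
    if (length(bad)) {
      stop_input("%s: line %d: expected %d fields, found %d",
                 matrix_path, bad[1] + 1L, n_samp + 1L, nf[bad[1]])
    }
    flat <- unlist(fields, use.names = FALSE)
    m <- matrix(flat, nrow = n_probe, byrow = TRUE)
    probe_ids <- m[, 1]
    num <- suppressWarnings(array(as.numeric(m[, -1, drop = FALSE]),
                                  dim = c(n_probe, n_samp)))
    na_pos <- which(is.na(num), arr.ind = TRUE)
    if (nrow(na_pos)) {
      i <- na_pos[1, 1]; j <- na_pos[1, 2]
      stop_input("%s: line %d, column %s: non-numeric value '%s'",
                 matrix_path, i + 1L, sample_ids[j], m[i, j + 1L])
    }
    num
  } else {
    matrix(numeric(0), nrow = 0, ncol = n_samp)
  }
  dimnames(values) <- list(probe_ids, sample_ids)

  meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            check.names = FALSE, fileEncoding = "UTF-8")
  tryCatch(
    expression_matrix(values, meta),
    error = function(e) {
      stop_input("%s / %s: %s", matrix_path, metadata_path, conditionMessage(e))
    }
  )
}

#' Write an expression matrix and its sample metadata to TSV
#'
#' Values are written at full double precision (17 significant digits, `.`
#' decimal separator, no quoting) so that `read_expression_matrix()`
#' round-trips bit-exactly.
#'
#' @param x an [expression_matrix()].
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, `c(matrix_path, metadata_path)`.
#' @export
write_expression_matrix <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "expression_matrix"))
  header <- paste(c("probe_id", colnames(x$values)), collapse = "\t")
  body <- if (nrow(x$values) > 0) {
    chr <- matrix(format_full(x$values), nrow = nrow(x$values))
    paste(rownames(x$values), apply(chr, 1, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  if (ncol(x$values) == 0 && nrow(x$values) > 0) {
    body <- rownames(x$values)
  }
  writeLines(c(header, body), matrix_path, useBytes = FALSE)
  utils::write.table(x$design, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(matrix_path, metadata_path))
}

#' Keep probes expressed above a detection threshold
#'
#' A probe is retained when its maximum normalized signal across all samples
#' is strictly greater than `threshold` — i.e. it shows signal above the
#' detection cutoff in at least one sample. The default cutoff of 4 (log2)
#' is the conventional "signal > 4" detection filter for normalized
#' Affymetrix intensities. Probes whose maximum ties the threshold exactly
#' are removed.
#'
#' @param x an [expression_matrix()].
#' @param threshold log2 intensity cutoff (default 4).
#' @return list with elements `matrix` (the filtered [expression_matrix()],
#'   probe order preserved) and `n_removed`.
#' @export
filter_expressed <- function(x, threshold = 4) {
  stopifnot(inherits(x, "expression_matrix"))
  if (nrow(x$values) == 0) {
    return(list(matrix = x, n_removed = 0L))
  }
  keep <- apply(x$values, 1, max) > threshold
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  list(matrix = out, n_removed = sum(!keep))
}
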