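#' Derived per-plant variables from raw phenotype records
#'
#' Adds the study's derived state variables to a table of per-plant
#' measurements:
#' * mean lateral root length `LRL = (TRL - PRL) / LRN` (cm; 0 by
#'   convention for a plant with no laterals and `TRL == PRL`);
#' * total dry weight `TDW = SDW + RDW` (g);
#' * total plant nitrogen
#'   `TotN = SDW * pct_shootN/100 + RDW * pct_rootN/100` (g N);
#' * root mass fraction `rdw_ratio = RDW / TDW`.
#'
#' @param records data.frame with columns `PRL`, `LRN`, `TRL`, `LeafA`,
#'   `SDW`, `RDW`, `pct_shootN`, `pct_rootN` (see [simulate_growth()] for
#'   the full record layout).
#' @return `records` with columns `LRL`, `TDW`, `TotN`, `rdw_ratio` added.
#' @export
derive_plant_variables <- function(records) {
  req <- c("PRL", "LRN", "TRL", "SDW", "RDW", "pct_shootN", "pct_rootN")
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop_input("records missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(records$LRN < 0)) stop_input("LRN must be >= 0")
  if (any(records$TRL < records$PRL)) {
    stop_input("TRL < PRL in %d record(s); total root length cannot be shorter than the primary root",
               sum(records$TRL < records$PRL))
  }
  no_lat <- records$LRN == 0
  bad <- no_lat & records$TRL > records$PRL
  if (any(bad)) {
    stop_input("LRN = 0 but TRL > PRL in %d record(s): lateral length without laterals",
               sum(bad))
  }
  lrl <- numeric(nrow(records))
  lrl[!no_lat] <- (records$TRL[!no_lat] - records$PRL[!no_lat]) /
    records$LRN[!no_lat]
  records$LRL <- lrl
  records$TDW <- records$SDW + records$RDW
  if (any(records$TDW == 0)) {
    stop_input("TDW = 0 in %d record(s); root mass fraction undefined",
               sum(records$TDW == 0))
  }
  records$TotN <- records$SDW * records$pct_shootN / 100 +
    records$RDW * records$pct_rootN / 100
  records$rdw_ratio <- records$RDW / records$TDW
  records
}

#' Interval N-uptake rate and N-to-leaf-area conversion efficiency
#'
#' Computes, per genotype-by-nitrate group and per consecutive sampling
#' interval, the two integrative N-acquisition efficiency variables from
#' group means per day (plants are destructively sampled, so there is no
#' within-plant time series):
#' * `NUR` — N-uptake rate per unit root surface area,
#'   `(TotN(t2) - TotN(t1)) / integral of root area over [t1, t2]`
#'   (g N cm^-2 day^-1), the integral taken by the trapezoid rule on the
#'   day-mean areas; a root-mass basis (`g N g^-1 day^-1`) is available
#'   via `nur_basis = "rdw"`;
#' * `NLA` — leaf area produced per unit N acquired,
#'   `(LeafA(t2) - LeafA(t1)) / (TotN(t2) - TotN(t1))` (cm^2 (g N)^-1),
#'   reported `NA` with `nla_undefined = TRUE` when the N increment is
#'   zero.
#'
#' @param records phenotype records; derived variables are added via
#'   [derive_plant_variables()] if absent.
#' @param nur_basis `"area"` (default) or `"rdw"`.
#' @return data.frame of class `efficiency_metrics`, one row per group and
#'   interval: `genotype`, `nitrate`, `t1`, `t2`, `dTotN`, `denom`
#'   (integrated area or RDW), `NUR`, `dLeafA`, `NLA`, `nla_undefined`,
#'   plus the per-day group-mean `rdw_ratio` trajectory in
#'   `attr(, "rdw_ratio")`.
#' @export
interval_efficiencies <- function(records, nur_basis = c("area", "rdw")) {
  nur_basis <- match.arg(nur_basis)
  if (!all(c("TotN", "TDW", "rdw_ratio") %in% names(records))) {
    records <- derive_plant_variables(records)
  }
  if (!"root_area" %in% names(records) && nur_basis == "area") {
    stop_input("records need a root_area column for the area NUR basis")
  }
  denom_var <- if (nur_basis == "area") "root_area" else "RDW"
  agg <- stats::aggregate(
    records[c("TotN", "LeafA", "rdw_ratio", denom_var)],
    by = records[c("genotype", "nitrate", "day")], FUN = mean
  )
  agg <- agg[order(agg$genotype, agg$nitrate, agg$day), ]
  groups <- unique(agg[c("genotype", "nitrate")])
  out <- NULL
  for (g in seq_len(nrow(groups))) {
    sub <- agg[agg$genotype == groups$genotype[g] &
                 agg$nitrate == groups$nitrate[g], ]
    if (nrow(sub) < 2) {
      stop_input("group %s/%s has < 2 sampling days",
                 groups$genotype[g], groups$nitrate[g])
    }
    for (i in seq_len(nrow(sub) - 1)) {
      t1 <- sub$day[i]; t2 <- sub$day[i + 1]
      d_totn <- sub$TotN[i + 1] - sub$TotN[i]
      denom <- (t2 - t1) * (sub[[denom_var]][i] + sub[[denom_var]][i + 1]) / 2
      d_leaf <- sub$LeafA[i + 1] - sub$LeafA[i]
      out <- rbind(out, data.frame(
        genotype = groups$genotype[g], nitrate = groups$nitrate[g],
        t1 = t1, t2 = t2, dTotN = d_totn, denom = denom,
        NUR = if (denom > 0) d_totn / denom else NA_real_,
        dLeafA = d_leaf,
        NLA = if (d_totn != 0) d_leaf / d_totn else NA_real_,
        nla_undefined = d_totn == 0,
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  attr(out, "rdw_ratio") <-
    agg[c("genotype", "nitrate", "day", "rdw_ratio")]
  attr(out, "nur_basis") <- nur_basis
  class(out) <- c("efficiency_metrics", "data.frame")
  out
}

#' Fisher's least significant difference letter grouping
#'
#' One-way ANOVA across groups pools the within-group error variance; two
#' group means differ significantly when their absolute difference exceeds
#' `LSD_ij = t(1 - alpha/2, df_E) * sqrt(MSE * (1/n_i + 1/n_j))`. Letters
#' are assigned by the insert-and-absorb algorithm on the means sorted in
#' descending order: means that do not differ by more than the LSD share at
#' least one letter, means that do share none. A degenerate `MSE = 0`
#' (identical values within every group) is floored at machine epsilon
#' times the squared grand mean so the letters stay well defined.
#'
#' @param values numeric response values.
#' @param group group labels, parallel to `values`; every group needs at
#'   least 2 observations.
#' @param alpha significance level (default 0.05).
#' @return list of class `lsd_grouping`: `groups` (data.frame `group`,
#'   `mean`, `n`, `letters`, sorted by descending mean), `MSE`, `df`,
#'   `alpha`, and `lsd` (pairwise LSD matrix in the sorted order).
#' @export
lsd_compare <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop_input("need >= 2 groups")
  if (length(values) != length(group)) {
    stop_input("values and group must have equal length")
  }
  n <- tapply(values, group, length)
  if (any(n < 2)) {
    stop_input("group(s) with < 2 observations: %s",
               paste(names(n)[n < 2], collapse = ", "))
  }
  means <- tapply(values, group, mean)
  vars <- tapply(values, group, stats::var)
  df <- sum(n) - nlevels(group)
  mse <- sum((n - 1) * vars) / df
  if (mse <= 0) {
    mse <- .Machine$double.eps * max(mean(values)^2, 1e-300)
  }
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]; n <- n[ord]
  k <- length(means)
  tcrit <- stats::qt(1 - alpha / 2, df)
  lsd <- outer(seq_len(k), seq_len(k), function(i, j) {
    tcrit * sqrt(mse * (1 / n[i] + 1 / n[j]))
  })
  dimnames(lsd) <- list(names(means), names(means))
  # insert-and-absorb: interval of group i extends to the furthest group
  # (in descending-mean order) it does not differ from
  reach <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && abs(means[i] - means[j + 1L]) <= lsd[i, j + 1L]) {
      j <- j + 1L
    }
    j
  }, integer(1))
  intervals <- unique(data.frame(from = seq_len(k), to = reach))
  # absorb intervals nested in an earlier, wider one
  keep <- rep(TRUE, nrow(intervals))
  for (a in seq_len(nrow(intervals))) {
    for (b in seq_len(nrow(intervals))) {
      if (a != b && keep[b] &&
          intervals$from[b] >= intervals$from[a] &&
          intervals$to[b] <= intervals$to[a] &&
          (intervals$from[b] > intervals$from[a] ||
             intervals$to[b] < intervals$to[a])) {
        keep[b] <- FALSE
      }
    }
  }
  intervals <- intervals[keep, , drop = FALSE]
  letters_out <- character(k)
  for (a in seq_len(nrow(intervals))) {
    idx <- intervals$from[a]:intervals$to[a]
    letters_out[idx] <- paste0(letters_out[idx], letters[a])
  }
  structure(list(groups = data.frame(group = names(means),
                                     mean = as.numeric(means),
                                     n = as.integer(n),
                                     letters = letters_out,
                                     stringsAsFactors = FALSE),
                 MSE = mse, df = df, alpha = alpha, lsd = lsd),
            class = "lsd_grouping")
}

#' @export
print.lsd_grouping <- function(x, ...) {
  cat(sprintf("LSD grouping at alpha = %g (MSE = %.4g, df = %d)\n",
              x$alpha, x$MSE, x$df))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' LSD letter tables for the four genotype-by-nitrate groups per day
#'
#' Convenience wrapper applying [lsd_compare()] to one phenotype variable
#' at every sampling day. The experimental unit defaults to the
#' biological-replicate mean (plants within a tank are subsamples); set
#' `unit = "plant"` to use individual plants.
#'
#' @param records phenotype records (see [derive_plant_variables()]).
#' @param variable column name to compare.
#' @param alpha significance level.
#' @param unit `"replicate"` (default) or `"plant"`.
#' @return named list of [lsd_compare()] results, one per day.
#' @export
lsd_by_day <- function(records, variable, alpha = 0.05,
                       unit = c("replicate", "plant")) {
  unit <- match.arg(unit)
  if (!variable %in% names(records)) {
    stop_input("no column '%s' in records", variable)
  }
  if (unit == "replicate") {
    records <- stats::aggregate(
      records[variable],
      by = records[c("genotype", "nitrate", "day", "replicate")],
      FUN = mean
    )
  }
  days <- sort(unique(records$day))
  out <- lapply(days, function(d) {
    sub <- records[records$day == d, ]
    lsd_compare(sub[[variable]],
                paste(sub$genotype, sub$nitrate, sep = "_"), alpha = alpha)
  })
  names(out) <- as.character(days)
  out
}
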