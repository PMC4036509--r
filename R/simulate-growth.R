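#' Configuration for the longitudinal growth and N-uptake simulator
#'
#' Emulates destructive phenotyping of hydroponically grown plants over a
#' series of sampling days (default days 7, 10, 14, 21 and 28 after
#' transfer), for the four genotype-by-nitrate groups. Each scenario follows
#' a deterministic growth core:
#'
#' * total dry weight grows exponentially at the scenario's relative growth
#'   rate, `TDW(t) = TDW0 * exp(rgr * t)`;
#' * `RDW = alloc * TDW`, `SDW = (1 - alloc) * TDW`;
#' * root surface area = `specific_root_area * RDW`;
#' * total plant N accumulates as `dTotN = u * area(t) dt`, with the area
#'   trajectory taken linear in time between sampling days (the scale on
#'   which the destructive measurements exist) and integrated by the
#'   trapezoid rule on a fine internal grid;
#' * `LeafA = leaf_area_per_sdw * SDW`; a fixed fraction `n_root_frac` of
#'   plant N resides in roots, from which `%ShootN` and `%RootN` are
#'   back-computed so that `SDW * %ShootN/100 + RDW * %RootN/100 = TotN`
#'   holds exactly in the noise-free records.
#'
#' Root architecture variables use simple allometry: the primary root
#' elongates linearly (`PRL = prl0 + prl_rate * day`), lateral root number
#' grows linearly (`LRN = lrn_rate * day`), and total lateral length is
#' proportional to RDW (`TRL = PRL + lateral_len_per_rdw * RDW`), keeping
#' `TRL >= PRL` by construction.
#'
#' Measurement noise is multiplicative lognormal with unit mean, split into
#' a per-replicate (tank) component shared by the plants of one biological
#' replicate and an independent per-plant component, both CV-parameterized.
#'
#' @param sampling_days strictly increasing sampling days (days after
#'   transfer).
#' @param scenarios data.frame with one row per genotype-by-nitrate group
#'   and columns `genotype`, `nitrate`, `rgr` (per day), `alloc` (root mass
#'   fraction, in (0,1)), `uptake` (specific N-uptake rate `u`, g N cm^-2
#'   day^-1), `specific_root_area` (cm^2 g^-1), `leaf_area_per_sdw`
#'   (cm^2 g^-1), `tdw0` (g at day 0), `totn0` (g N at day 0), `prl0` (cm),
#'   `prl_rate` (cm day^-1), `lrn_rate` (laterals day^-1),
#'   `lateral_len_per_rdw` (cm g^-1). Defaults emulate a slow-growing,
#'   root-allocating highly branched mutant against its wild type under
#'   high and low nitrate.
#' @param n_replicates biological replicates (tanks) per group (default 3).
#' @param plants_per_replicate plants sampled per tank per date (default 6).
#' @param cv_replicate,cv_plant lognormal measurement CVs for the shared
#'   replicate effect and the per-plant effect (defaults 0.05 and 0.10).
#' @param n_root_frac fraction of plant N in the root compartment
#'   (default 0.25).
#' @param seed integer seed.
#' @return an object of class `growth_sim_config`.
#' @export
growth_sim_config <- function(sampling_days = c(7, 10, 14, 21, 28),
                              scenarios = default_growth_scenarios(),
                              n_replicates = 3, plants_per_replicate = 6,
                              cv_replicate = 0.05, cv_plant = 0.10,
                              n_root_frac = 0.25, seed = 1) {
  if (!length(sampling_days)) stop_input("sampling_days must be non-empty")
  if (any(diff(sampling_days) <= 0)) {
    stop_input("sampling_days must be strictly increasing")
  }
  if (any(sampling_days <= 0)) stop_input("sampling_days must be positive")
  req <- c("genotype", "nitrate", "rgr", "alloc", "uptake",
           "specific_root_area", "leaf_area_per_sdw", "tdw0", "totn0",
           "prl0", "prl_rate", "lrn_rate", "lateral_len_per_rdw")
  if (!is.data.frame(scenarios) || !all(req %in% names(scenarios))) {
    stop_input("scenarios must contain columns: %s", paste(req, collapse = ", "))
  }
  if (any(scenarios$alloc <= 0 | scenarios$alloc >= 1)) {
    stop_input("allocation fraction must lie in (0, 1)")
  }
  rates <- c(scenarios$rgr, scenarios$uptake, scenarios$specific_root_area,
             scenarios$leaf_area_per_sdw, scenarios$tdw0, scenarios$totn0)
  if (any(rates <= 0)) stop_input("all scenario rates and initials must be > 0")
  if (n_root_frac <= 0 || n_root_frac >= 1) {
    stop_input("n_root_frac must lie in (0, 1)")
  }
  if (!is_count(n_replicates, 1) || !is_count(plants_per_replicate, 1)) {
    stop_input("replicate and plant counts must be positive integers")
  }
  structure(list(sampling_days = as.numeric(sampling_days),
                 scenarios = scenarios,
                 n_replicates = as.integer(n_replicates),
                 plants_per_replicate = as.integer(plants_per_replicate),
                 cv_replicate = cv_replicate, cv_plant = cv_plant,
                 n_root_frac = n_root_frac, seed = as.integer(seed)),
            class = "growth_sim_config")
}

#' Default genotype-by-nitrate growth scenarios
#'
#' Wild type grows faster and allocates less mass to roots than the highly
#' branched mutant; low nitrate slows growth and increases root allocation
#' in both genotypes; the mutant's specific uptake rate is depressed.
#'
#' @return data.frame of four scenarios, see [growth_sim_config()].
#' @export
default_growth_scenarios <- function() {
  data.frame(
    genotype = c("WT", "WT", "MUT", "MUT"),
    nitrate = c("HN", "LN", "HN", "LN"),
    rgr = c(0.20, 0.17, 0.15, 0.13),
    alloc = c(0.30, 0.35, 0.40, 0.45),
    uptake = c(2.0e-5, 1.5e-5, 1.0e-5, 0.8e-5),
    specific_root_area = c(500, 500, 550, 550),
    leaf_area_per_sdw = c(150, 160, 140, 150),
    tdw0 = c(0.002, 0.002, 0.002, 0.002),
    totn0 = c(8e-5, 8e-5, 8e-5, 8e-5),
    prl0 = c(2, 2, 2, 2),
    prl_rate = c(1.0, 1.1, 0.8, 0.8),
    lrn_rate = c(3.5, 3.0, 8.0, 8.0),
    lateral_len_per_rdw = c(2000, 2000, 1200, 1200),
    stringsAsFactors = FALSE
  )
}

# Deterministic per-scenario trajectory at the sampling days (plus day 0
# internally for the N integration).
growth_trajectory <- function(sc, days, n_root_frac, n_fine = 50) {
  tgrid <- c(0, days)
  tdw <- sc$tdw0 * exp(sc$rgr * tgrid)
  rdw <- sc$alloc * tdw
  sdw <- tdw - rdw
  area <- sc$specific_root_area * rdw
  # N pool: trapezoid on a fine grid of the piecewise-linear area trajectory
  totn <- numeric(length(tgrid))
  totn[1] <- sc$totn0
  for (i in seq_len(length(tgrid) - 1)) {
    tt <- seq(tgrid[i], tgrid[i + 1], length.out = n_fine)
    aa <- area[i] + (area[i + 1] - area[i]) *
      (tt - tgrid[i]) / (tgrid[i + 1] - tgrid[i])
    totn[i + 1] <- totn[i] + sc$uptake * trapezoid(tt, aa)
  }
  keep <- -1  # drop day 0
  data.frame(day = tgrid[keep], TDW = tdw[keep], SDW = sdw[keep],
             RDW = rdw[keep], root_area = area[keep],
             LeafA = sc$leaf_area_per_sdw * sdw[keep],
             TotN = totn[keep],
             shootN_pool = (1 - n_root_frac) * totn[keep],
             rootN_pool = n_root_frac * totn[keep],
             PRL = sc$prl0 + sc$prl_rate * tgrid[keep],
             LRN = sc$lrn_rate * tgrid[keep],
             lat_len = sc$lateral_len_per_rdw * rdw[keep])
}

#' Simulate longitudinal plant phenotype records with known ground truth
#'
#' One record per plant per sampling day (destructive sampling: plants are
#' independent across days), for every genotype-by-nitrate scenario in the
#' configuration. See [growth_sim_config()] for the generating model.
#'
#' @param config a [growth_sim_config()].
#' @return list with `records` — a data.frame with columns `genotype`,
#'   `nitrate`, `day`, `replicate`, `plant_id`, `PRL`, `LRN`, `TRL`,
#'   `root_area`, `LeafA`, `SDW`, `RDW`, `pct_shootN`, `pct_rootN` — and
#'   `truth` — a list with the scenario table (true rates) and the
#'   noise-free `trajectory` per scenario and day.
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "growth_sim_config"))
  days <- config$sampling_days
  scs <- config$scenarios
  nrep <- config$n_replicates
  nppr <- config$plants_per_replicate

  noisy_vars <- c("PRL", "LRN", "lat_len", "root_area", "LeafA",
                  "SDW", "RDW", "shootN_pool", "rootN_pool")
  records <- vector("list", nrow(scs))
  trajectories <- vector("list", nrow(scs))
  for (s in seq_len(nrow(scs))) {
    sc <- scs[s, ]
    traj <- growth_trajectory(sc, days, config$n_root_frac)
    trajectories[[s]] <- cbind(genotype = sc$genotype, nitrate = sc$nitrate,
                               traj, stringsAsFactors = FALSE)
    grid <- expand.grid(plant = seq_len(nppr), replicate = seq_len(nrep),
                        day_idx = seq_along(days))
    n <- nrow(grid)
    rec <- data.frame(
      genotype = sc$genotype, nitrate = sc$nitrate,
      day = days[grid$day_idx], replicate = grid$replicate,
      plant_id = sprintf("%s_%s_d%02d_r%d_p%d", sc$genotype, sc$nitrate,
                         days[grid$day_idx], grid$replicate, grid$plant),
      stringsAsFactors = FALSE
    )
    true_vals <- traj[grid$day_idx, noisy_vars]
    noise <- with_seed(sub_seed(config$seed, 100 + s), {
      rep_key <- interaction(grid$replicate, grid$day_idx, drop = TRUE)
      out <- matrix(1, n, length(noisy_vars),
                    dimnames = list(NULL, noisy_vars))
      for (v in noisy_vars) {
        rep_fac <- lognormal_factor(nlevels(rep_key), config$cv_replicate)
        out[, v] <- rep_fac[as.integer(rep_key)] *
          lognormal_factor(n, config$cv_plant)
      }
      out
    })
    meas <- as.matrix(true_vals) * noise
    rec$PRL <- meas[, "PRL"]
    rec$LRN <- round(meas[, "LRN"])
    rec$TRL <- meas[, "PRL"] + meas[, "lat_len"]
    rec$root_area <- meas[, "root_area"]
    rec$LeafA <- meas[, "LeafA"]
    rec$SDW <- meas[, "SDW"]
    rec$RDW <- meas[, "RDW"]
    rec$pct_shootN <- 100 * meas[, "shootN_pool"] / meas[, "SDW"]
    rec$pct_rootN <- 100 * meas[, "rootN_pool"] / meas[, "RDW"]
    records[[s]] <- rec
  }
  list(records = do.call(rbind, records),
       truth = list(scenarios = scs,
                    n_root_frac = config$n_root_frac,
                    trajectory = do.call(rbind, trajectories)))
}
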