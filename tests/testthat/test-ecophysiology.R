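plant_row <- function(PRL = 10, LRN = 30, TRL = 100, LeafA = 20,
                      SDW = 0.2, RDW = 0.1, pct_shootN = 4,
                      pct_rootN = 3, genotype = "WT", nitrate = "HN",
                      day = 7, replicate = 1) {
  data.frame(genotype = genotype, nitrate = nitrate, day = day,
             replicate = replicate, PRL = PRL, LRN = LRN, TRL = TRL,
             root_area = 10, LeafA = LeafA, SDW = SDW, RDW = RDW,
             pct_shootN = pct_shootN, pct_rootN = pct_rootN,
             stringsAsFactors = FALSE)
}

test_that("derived variables follow their defining arithmetic", {
  d <- derive_plant_variables(plant_row())
  expect_equal(d$LRL, 3)            # (100 - 10) / 30
  expect_equal(d$TDW, 0.3)
  expect_equal(d$TotN, 0.011)       # 0.2*4% + 0.1*3%
  expect_equal(d$rdw_ratio, 0.1 / 0.3)
})

test_that("lateral-root degenerate cases follow the stated conventions", {
  ok <- derive_plant_variables(plant_row(LRN = 0, TRL = 10, PRL = 10))
  expect_equal(ok$LRL, 0)
  expect_error(derive_plant_variables(plant_row(LRN = 0, TRL = 11)),
               "LRN = 0")
  expect_error(derive_plant_variables(plant_row(TRL = 5, PRL = 10)),
               "TRL < PRL")
  expect_error(derive_plant_variables(plant_row(SDW = 0, RDW = 0)),
               "TDW = 0")
})

test_that("TDW additivity, TotN linearity and ratio scale-invariance hold", {
  set.seed(21)
  rec <- plant_row(SDW = runif(20, 0.05, 0.5), RDW = runif(20, 0.02, 0.3),
                   pct_shootN = runif(20, 2, 5), pct_rootN = runif(20, 1, 4))
  d <- derive_plant_variables(rec)
  expect_equal(d$TDW, rec$SDW + rec$RDW)
  expect_equal(d$TotN,
               rec$SDW * rec$pct_shootN / 100 + rec$RDW * rec$pct_rootN / 100)
  scaled <- rec
  scaled$SDW <- rec$SDW * 3.7; scaled$RDW <- rec$RDW * 3.7
  expect_equal(derive_plant_variables(scaled)$rdw_ratio, d$rdw_ratio)
})

test_that("interval NUR and NLA match hand-computed values", {
  # constant area 10 cm^2, TotN step 0.001 g over 7 d; LeafA step 20 cm^2
  rec <- rbind(
    plant_row(day = 7, SDW = 0.2, pct_shootN = 4, RDW = 0.1, pct_rootN = 3,
              LeafA = 10, replicate = 1),
    plant_row(day = 7, SDW = 0.2, pct_shootN = 4, RDW = 0.1, pct_rootN = 3,
              LeafA = 10, replicate = 2),
    plant_row(day = 14, SDW = 0.25, pct_shootN = 4.4, RDW = 0.1,
              pct_rootN = 1, LeafA = 30, replicate = 1),
    plant_row(day = 14, SDW = 0.25, pct_shootN = 4.4, RDW = 0.1,
              pct_rootN = 1, LeafA = 30, replicate = 2)
  )
  eff <- interval_efficiencies(rec)
  expect_equal(nrow(eff), 1)
  expect_equal(eff$dTotN, 0.001)      # 0.012 - 0.011
  expect_equal(eff$NUR, 0.001 / 70)
  expect_equal(eff$NLA, 20 / 0.001)   # 20,000 cm^2 per g N
  expect_false(eff$nla_undefined)
})

test_that("zero N increment flags NLA undefined without throwing", {
  rec <- rbind(plant_row(day = 7, replicate = 1),
               plant_row(day = 7, replicate = 2),
               plant_row(day = 14, replicate = 1),
               plant_row(day = 14, replicate = 2))
  eff <- interval_efficiencies(rec)
  expect_true(eff$nla_undefined)
  expect_true(is.na(eff$NLA))
  expect_equal(eff$NUR, 0)
})

test_that("NUR sign tracks the sign of the N increment", {
  for (step in c(-0.5, 0.5)) {
    rec <- rbind(plant_row(day = 7, replicate = 1:2),
                 plant_row(day = 10, pct_shootN = 4 + step,
                           replicate = 1:2))
    eff <- interval_efficiencies(rec)
    expect_equal(sign(eff$NUR), sign(eff$dTotN))
  }
})

test_that("median NUR stays within 10% of truth under 10% measurement noise", {
  sc <- default_growth_scenarios()
  cfg <- growth_sim_config(scenarios = sc, cv_replicate = 0,
                           cv_plant = 0.10, n_replicates = 3,
                           plants_per_replicate = 6, seed = 185)
  g <- simulate_growth(cfg)
  eff <- interval_efficiencies(g$records)
  truth_u <- setNames(sc$uptake, paste(sc$genotype, sc$nitrate))
  rel_err <- abs(eff$NUR / truth_u[paste(eff$genotype, eff$nitrate)] - 1)
  expect_lt(median(rel_err), 0.10)
})

test_that("LSD letters separate clear groups and join identical ones", {
  same <- lsd_compare(c(1.0, 1.1, 0.9, 1.0, 1.1, 0.9),
                      rep(c("a", "b"), each = 3))
  expect_identical(same$groups$letters, c("a", "a"))

  sep <- lsd_compare(c(0, 0, 0, 10, 10, 10), rep(c("lo", "hi"), each = 3))
  expect_identical(sep$groups$letters[order(sep$groups$mean,
                                            decreasing = TRUE)][1], "a")
  expect_identical(sort(sep$groups$letters), c("a", "b"))

  expect_error(lsd_compare(c(1, 2, 3), c("a", "a", "b")), "< 2 observations")
})

test_that("the four-group worked example letters as {a, a, b, b}", {
  # means 10, 9.8, 5, 4.9 with within-group sd 0.2, n = 3:
  # LSD = t(0.975, 8) * sqrt(0.04 * 2/3) = 0.3766, so the two high and the
  # two low means pair up
  mk <- function(m) m + c(-0.2, 0, 0.2)
  vals <- c(mk(10), mk(9.8), mk(5), mk(4.9))
  grp <- rep(c("g1", "g2", "g3", "g4"), each = 3)
  res <- lsd_compare(vals, grp)
  expect_equal(res$MSE, 0.04)
  expect_equal(res$groups$group, c("g1", "g2", "g3", "g4"))
  expect_identical(res$groups$letters, c("a", "a", "b", "b"))
})

test_that("letter assignment satisfies the two pairwise LSD properties on random instances", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    n <- 4
    means <- runif(k, 0, 5)
    vals <- unlist(lapply(means, function(m) rnorm(n, m, 0.5)))
    grp <- rep(sprintf("g%d", seq_len(k)), each = n)
    res <- lsd_compare(vals, grp)
    gm <- setNames(res$groups$mean, res$groups$group)
    lt <- setNames(strsplit(res$groups$letters, ""), res$groups$group)
    lsd <- res$lsd
    for (a in names(gm)) for (b in names(gm)) {
      if (a == b) next
      shares <- length(intersect(lt[[a]], lt[[b]])) > 0
      if (abs(gm[a] - gm[b]) > lsd[a, b]) {
        expect_false(shares)
      } else {
        expect_true(shares)
      }
    }
  }
})

test_that("lsd_by_day letters replicate-mean groups for every sampling day", {
  g <- simulate_growth(growth_sim_config(seed = 10))
  rec <- derive_plant_variables(g$records)
  by_day <- lsd_by_day(rec, "LRN")
  expect_identical(names(by_day), as.character(c(7, 10, 14, 21, 28)))
  for (d in by_day) {
    expect_equal(nrow(d$groups), 4)
    expect_equal(unique(d$groups$n), 3L)   # replicate means, n = 3
  }
})
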