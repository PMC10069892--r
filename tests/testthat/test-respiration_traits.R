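test_that("the RuBisCO ratio window constrains oxygenation correctly", {
  tp <- toy_day()
  m <- tp$model
  rc <- rubisco_constraint("RBC_C", "RBC_O", 0.31, 0.55)
  cts <- constrain_rubisco(m, rc)
  # pin carboxylation at 1 and probe the feasible oxygenation range
  pin <- list(linear_constraint(c(RBC_C = 1), "=", 1))
  hi <- fba(m, c(cts, pin), objective = c(RBC_O = 1))
  lo <- fba(m, c(cts, pin), objective = c(RBC_O = -1))
  expect_equal(hi$flux[["RBC_O"]], 0.55, tolerance = 1e-6)
  expect_equal(lo$flux[["RBC_O"]], 0.31, tolerance = 1e-6)

  # a degenerate window forces the exact ratio
  rc2 <- rubisco_constraint("RBC_C", "RBC_O", 0.5, 0.5)
  sol <- pfba(m, constrain_rubisco(m, rc2))
  expect_equal(sol$flux[["RBC_O"]], 0.5 * sol$flux[["RBC_C"]],
               tolerance = 1e-6)

  # vc = 0 collapses the window to vo = 0
  zero <- list(linear_constraint(c(RBC_C = 1), "=", 0))
  sol0 <- fba(m, c(cts, zero), objective = c(RBC_O = 1))
  expect_equal(sol0$flux[["RBC_O"]], 0, tolerance = 1e-8)

  expect_error(constrain_rubisco(fix_heterotroph(),
                                 rubisco_constraint("BIO", "RBC_O")),
               "lacks photorespiration")
  expect_error(rubisco_constraint("a", "b", 0.6, 0.3))
})

test_that("net assimilation is direction-aware and thresholded", {
  tp <- toy_day()
  inv <- build_inventory(tp$model)
  rc <- tp$ground_truth$rubisco
  sol <- pfba(tp$model, constrain_rubisco(tp$model, rc))
  a <- net_assimilation(sol, inv)
  mu <- sol$flux[["BIOMASS"]]
  # carbon bookkeeping oracle: net CO2 fixed equals biomass carbon exported
  expect_equal(a, 6 * mu, tolerance = 1e-6)
  expect_gt(a, 0)

  # all-zero flux vector
  zero <- sol
  zero$flux[] <- 0
  expect_equal(net_assimilation(zero, inv), 0)

  # values below the solver-feasibility reporting cutoff collapse to zero
  tiny <- zero
  tiny$flux["PDH"] <- 3e-10
  expect_identical(net_assimilation(tiny, inv), 0)
  expect_false(net_assimilation(tiny, inv, threshold = 1e-11) == 0)

  # model mismatch is refused
  other <- build_inventory(fix_heterotroph())
  expect_error(net_assimilation(sol, other), "inventory")
})

test_that("the trait panel satisfies its algebraic identities", {
  tp <- toy_day()
  inv <- build_inventory(tp$model)
  tr <- compute_traits(tp$model, inv, tp$ground_truth$rubisco)
  expect_equal(tr$CUE, tr$A_net / tr$Vc, tolerance = 1e-9)
  expect_equal(tr$Rd, tr$Vc - 0.5 * tr$Vo - tr$A_net, tolerance = 1e-9)
  expect_equal(tr$Vo / tr$Vc, 0.31, tolerance = 1e-6)  # minimal oxygenation wins
  expect_equal(tr$Rg_scaled, tr$Rg / (tr$mu * 6), tolerance = 1e-9)
  expect_true(tr$growing)
  # maximization dominance at fixed optimal growth
  expect_gte(tr$Anetmax, tr$A_net - 1e-6)
  ex_flux <- tr$flux$flux[["EX_CO2"]]
  expect_gte(tr$Rnetmax, ex_flux - 1e-6)
})

test_that("a heterotroph still yields Rg but no CUE", {
  het <- fix_heterotroph()
  inv <- build_inventory(het)
  tr <- compute_traits(het, inv, rc = NULL)
  expect_true(is.na(tr$CUE))
  expect_true(is.na(tr$Vc))
  expect_gt(tr$Rg, 0)       # obligate respiration carries flux
  expect_gt(tr$mu, 0)
  # single CO2 producer holds the full share of release
  rk <- rank_contributors(tr$flux, inv, het)
  expect_equal(rk$entries$reaction[1], "RESP")
  expect_equal(rk$entries$share[1], 1)
})

test_that("with oxygenation silenced, day respiration equals growth respiration", {
  tp <- toy_day()
  m <- apply_knockout(tp$model, "RBC_O")
  inv <- build_inventory(m)
  tr <- compute_traits(m, inv,
                       rubisco_constraint("RBC_C", "RBC_O", 0, 1000))
  # only decarboxylation sources remain: A_net = Vc - Rg, hence Rd = Rg
  expect_equal(tr$Vo, 0, tolerance = 1e-9)
  expect_equal(tr$Rd, tr$Rg, tolerance = 1e-8)
})

test_that("contribution rankings match the designed day/night biology", {
  tp <- toy_day()
  inv <- build_inventory(tp$model)
  tr <- compute_traits(tp$model, inv, tp$ground_truth$rubisco)
  rk <- rank_contributors(tr$flux, inv, tp$model)
  expect_equal(rk$entries$reaction[1], tp$ground_truth$dominant_day_producer)
  expect_equal(rk$entries$ec[1], "1.4.4.2")
  expect_equal(sum(rk$entries$share), 1, tolerance = 1e-6)
  expect_true(all(diff(rk$entries$co2_flux) <= 1e-12))  # non-increasing

  tn <- toy_night()
  invn <- build_inventory(tn$model)
  trn <- compute_traits(tn$model, invn, tp$ground_truth$rubisco)
  rkn <- rank_contributors(trn$flux, invn, tn$model)
  expect_equal(rkn$entries$reaction[1], tn$ground_truth$dominant_night_producer)
  expect_equal(rkn$entries$ec[1], "1.1.1.44")

  # Rg = 0 gives an empty ranking with a note
  zero <- trn$flux
  zero$flux[] <- 0
  rk0 <- rank_contributors(zero, invn, tn$model)
  expect_equal(nrow(rk0$entries), 0)
  expect_match(rk0$note, "no CO2 release")
})

test_that("day/night comparison bounds night growth by the day optimum", {
  tp <- toy_day(); tn <- toy_night()
  inv <- build_inventory(tp$model); invn <- build_inventory(tn$model)
  rc <- tp$ground_truth$rubisco
  cc <- compare_conditions(tp$model, tn$model, inv, invn, rc)
  expect_lte(cc$night$mu, cc$day$mu + 1e-8)
  expect_gt(cc$day$Rg_scaled, cc$night$Rg_scaled)

  # identical models give identical traits
  cc2 <- compare_conditions(tp$model, tp$model, inv, inv, rc)
  for (f in c("A_net", "CUE", "Rg", "mu", "Rg_scaled")) {
    expect_equal(cc2$day[[f]], cc2$night[[f]], tolerance = 1e-6, label = f)
  }

  # night model without any carbon source is flagged non-growing
  dark <- generate_toyplant(toy_model_spec(night = TRUE, starch_bound = 0))
  invd <- build_inventory(dark$model)
  trd <- compute_traits(dark$model, invd, rc)
  expect_false(trd$growing)
  expect_true(is.na(trd$Rg_scaled))
})

test_that("trait responses move monotonically with the stated world", {
  tp <- toy_day()
  rc <- tp$ground_truth$rubisco
  mus <- rds <- numeric(0)
  for (pb in c(40, 70, 100)) {
    g <- generate_toyplant(toy_model_spec(photon_bound = pb))
    inv <- build_inventory(g$model)
    tr <- compute_traits(g$model, inv, rc, lexicographic = FALSE)
    mus <- c(mus, tr$mu)
    # tightening ratio_max cannot increase Rd (the optimum already sits at
    # the minimum oxygenation ratio)
    tr_tight <- compute_traits(g$model, inv,
                               rubisco_constraint("RBC_C", "RBC_O", 0.31, 0.31),
                               lexicographic = FALSE)
    expect_lte(tr_tight$Rd, tr$Rd + 1e-8)
  }
  expect_true(all(diff(mus) > 0))  # photons limit growth

  # homogeneity: scaling every bound by a common factor leaves scaled Rg fixed
  g1 <- generate_toyplant(toy_model_spec(photon_bound = 50))
  g2 <- generate_toyplant(toy_model_spec(photon_bound = 100))
  m2 <- g2$model
  inv1 <- build_inventory(g1$model)
  inv2 <- build_inventory(m2)
  t1 <- compute_traits(g1$model, inv1, rc, lexicographic = FALSE)
  t2 <- compute_traits(m2, inv2, rc, lexicographic = FALSE)
  expect_equal(t1$Rg_scaled, t2$Rg_scaled, tolerance = 1e-6)
})
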