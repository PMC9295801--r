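test_that("closed-form primitives: CV, Shannon, min-max, reversal", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(0, 20)), sqrt(2),
               tolerance = 1e-9)
  expect_equal(coefficient_of_variation(c(0, 0, 0)), 0)
  expect_error(coefficient_of_variation(5), "at least 2")

  expect_equal(shannon_diversity(rep(1, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(5)), 0)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_warning(h0 <- shannon_diversity(c(0, 0)), "all-zero")
  expect_equal(h0, 0)
  expect_error(shannon_diversity(c(-1, 2)), ">= 0")

  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(2, 4, 6), reverse = TRUE), c(1, 0.5, 0))
  expect_warning(z <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  expect_equal(minmax_normalize(c(1, NA, 3)), c(0, NA, 1))
  expect_error(minmax_normalize(c(NA_real_, NA_real_)), "missing")
})

test_that("supply weights are supply shares excluding exports", {
  w <- micro_world()
  led <- build_ledger(w, "on")
  # constructed check: domestic 50, FF 30, IMP 20 RNIs -> (0.3, 0.2, 0.5)
  fake <- led
  fake$table <- tidyr::expand_grid(nation = "A",
                                   nutrient = nutrient_names(),
                                   channel = c("domestic", "foreign_fished",
                                               "high_seas_share", "imported",
                                               "exported", "lost_to_foreign"))
  fake$table$rni_equiv <- c(domestic = 50, foreign_fished = 30,
                            high_seas_share = 0, imported = 20,
                            exported = 999, lost_to_foreign = 999)[
                              fake$table$channel]
  ww <- supply_weights(fake)
  expect_equal(c(ww$w_ff, ww$w_imp, ww$w_dc), c(0.3, 0.2, 0.5))
  # real ledger weights close to 1 and match the oracle
  sv <- vulnerability_subvariables(w, led)
  osv <- oracle_subvars(w, "on")
  expect_rel_equal(sv$w_ff + sv$w_imp + sv$w_dc, rep(1, 3))
  for (col in c("cv_ff", "cv_imp", "div_ff", "div_imp", "div_dc",
                "w_ff", "w_imp", "w_dc")) {
    expect_rel_equal(sv[[col]][match(osv$nation, sv$nation)], osv[[col]])
  }
})

test_that("sub-variables match the record-iterating oracle on a seeded world", {
  w <- generate_world(world_config(n_nations = 7, n_taxa = 25,
                                   foc_heavy_nations = 2, seed = 33))
  sv <- vulnerability_subvariables(w)
  osv <- oracle_subvars(w, "on")
  idx <- match(osv$nation, sv$nation)
  for (col in c("cv_ff", "cv_imp", "div_ff", "div_imp", "div_dc",
                "w_ff", "w_imp", "w_dc")) {
    expect_rel_equal(sv[[col]][idx], osv[[col]])
  }
})

test_that("scores are bounded and composed as documented", {
  w <- generate_world(world_config(n_nations = 12, n_taxa = 30,
                                   nd_frac = 0.1, seed = 41))
  sv <- vulnerability_subvariables(w)
  sc <- vulnerability_scores(sv, climate = FALSE)
  for (col in c("e_ff", "e_imp", "exposure", "sensitivity",
                "adaptive_capacity", "vulnerability")) {
    expect_true(all(sc[[col]] >= -1e-12 & sc[[col]] <= 1 + 1e-12))
  }
  expect_true(all(sc$v_raw >= -1 - 1e-12 & sc$v_raw <= 2 + 1e-12))
  # step-by-step recomposition with the independent min-max oracle
  e_ff <- (oracle_minmax(sv$cv_ff) + oracle_minmax(sv$div_ff, TRUE)) / 2
  e_imp <- (oracle_minmax(sv$cv_imp) + oracle_minmax(sv$div_imp, TRUE)) / 2
  expo <- oracle_minmax((sv$w_ff * e_ff + sv$w_imp * e_imp) / 2)
  sens_in <- rowMeans(cbind(oracle_minmax(sv$s_fd),
                            oracle_minmax(sv$s_pimii)), na.rm = TRUE)
  sens <- oracle_minmax(sens_in)
  ac_se <- (oracle_minmax(sv$ac_gdp) + oracle_minmax(sv$ac_s)) / 2
  ac <- oracle_minmax((ac_se + oracle_minmax(sv$ac_he) + (1 - sv$ac_imp)) / 3)
  expect_rel_equal(sc$exposure, expo)
  expect_rel_equal(sc$sensitivity, sens)
  expect_rel_equal(sc$adaptive_capacity, ac)
  expect_rel_equal(sc$v_raw, expo + sens - ac)
  expect_rel_equal(sc$vulnerability, oracle_minmax(sc$v_raw))
  # climate variant adds the weighted domestic-catch component
  scc <- vulnerability_scores(sv, climate = TRUE)
  ecc_core <- (oracle_minmax(sv$cpdc, TRUE) +
                 oracle_minmax(sv$div_dc, TRUE)) / 2
  expo_c <- oracle_minmax((sv$w_ff * e_ff + sv$w_imp * e_imp +
                             sv$w_dc * ecc_core) / 3)
  expect_rel_equal(scc$exposure, expo_c)
  expect_rel_equal(scc$e_cc, sv$w_dc * ecc_core)
})

test_that("raising a nation's intake inadequacy never lowers its raw score", {
  w <- generate_world(world_config(n_nations = 10, n_taxa = 25, seed = 55))
  sv <- vulnerability_subvariables(w)
  base <- vulnerability_scores(sv, renormalize = FALSE)
  withr::with_seed(7, {
    for (rep in 1:30) {
      i <- sample(which(!is.na(sv$s_pimii)), 1)
      bump <- runif(1, 0, 100 - sv$s_pimii[i])
      sv2 <- sv
      sv2$s_pimii[i] <- sv2$s_pimii[i] + bump
      pert <- vulnerability_scores(sv2, renormalize = FALSE)
      expect_gte(pert$v_raw[i], base$v_raw[i] - 1e-12)
    }
  })
})

test_that("correlations recover monotone relationships and handle ties", {
  w <- generate_world(world_config(n_nations = 6, n_taxa = 20, seed = 61))
  bt <- balance_table(build_ledger(w, "off"))
  ind <- w$indicators
  # force a strictly increasing relationship for one nutrient
  iron <- bt[bt$nutrient == "iron", ]
  ind$gdp_pc <- rank(iron$ffb[match(ind$nation, iron$nation)]) * 1000
  cors <- balance_correlations(bt, ind, metrics = "gdp_pc")
  expect_equal(cors$rho[cors$balance == "ffb" & cors$nutrient == "iron"], 1)
  ind$gdp_pc <- -ind$gdp_pc
  cors2 <- balance_correlations(bt, ind, metrics = "gdp_pc")
  expect_equal(cors2$rho[cors2$balance == "ffb" &
                           cors2$nutrient == "iron"], -1)
  # tie handling equals the rank-then-Pearson oracle
  x <- iron$tb
  y <- c(5, 5, 1, 9, 3, 7)[seq_along(x)]
  ind$hdi <- y[match(ind$nation, iron$nation)]
  cors3 <- balance_correlations(bt, ind, metrics = "hdi")
  expect_equal(cors3$rho[cors3$balance == "tb" & cors3$nutrient == "iron"],
               stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  # too few complete pairs -> NA with a warning
  ind$hdi <- c(1, 2, NA, NA, NA, NA)
  msgs <- capture_warnings(
    cors4 <- balance_correlations(bt, ind, metrics = "hdi"))
  expect_true(length(msgs) > 0 && all(grepl("fewer than 3", msgs)))
  expect_true(all(is.na(cors4$rho)))
})

test_that("the indicator screen reports both pruning correlations", {
  w <- generate_world(world_config(n_nations = 30, n_taxa = 20, seed = 71))
  sc <- indicator_screen(w$indicators)
  expect_equal(nrow(sc), 2)
  expect_true(all(abs(sc$rho) <= 1))
  # the generator builds adequacy up and prevalence down the wealth axis
  expect_lt(sc$rho[sc$pair == "s_pimii_vs_energy_adequacy"], 0)
  expect_gt(abs(sc$rho[sc$pair == "gdp_pc_vs_inequality_coef"]), 0.3)
})
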