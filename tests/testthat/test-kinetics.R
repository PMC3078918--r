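test_that("normalization maps the reference cell to ref_value per pmol", {
  rt <- data.frame(construct = "JAK2_JH1JH2_WT", control = "none",
                   enzyme_pmol = 2, atp_uM = 400, replicate = 1L,
                   peptide_id = c("STA5A_687_699", "EPOR_361_373"),
                   conc_uM = c(1000, 1000), v = c(40, 10),
                   stringsAsFactors = FALSE)
  norm <- normalize_activity(rt)
  expect_equal(norm$v[norm$peptide_id == "STA5A_687_699"], 100 / 2)
  expect_equal(norm$v[norm$peptide_id == "EPOR_361_373"], 25 / 2)
  # scale invariance: doubling every raw v changes nothing
  rt2 <- rt; rt2$v <- rt2$v * 2
  expect_equal(normalize_activity(rt2)$v, norm$v)
  # missing reference names the construct
  expect_error(normalize_activity(rt[rt$peptide_id != "STA5A_687_699", ]),
               "JAK2_JH1JH2_WT")
})

test_that("MM fit recovers exact model points and agrees with the grid oracle", {
  atp <- c(12.5, 25, 50, 100, 200, 400)
  fit <- fit_mm_atp(atp, 100 * atp / (50 + atp))
  expect_equal(fit$vmax_app, 100, tolerance = 1e-6)
  expect_equal(fit$km_uM, 50, tolerance = 1e-6)
  expect_false(fit$extrapolated)
  expect_error(fit_mm_atp(c(0, 100, 200), c(0, 1, 2)), ">= 4 distinct")

  # 20 random noisy instances: least-squares fit matches exhaustive search
  set.seed(2024)
  for (i in 1:20) {
    km <- runif(1, 20, 150)
    vmax <- runif(1, 50, 500)
    v <- vmax * atp / (km + atp) * (1 + rnorm(6, 0, 0.05))
    # the oracle minimises unweighted RSS, so compare on that objective
    fit <- fit_mm_atp(atp, v, weighting = "none")
    oracle <- mm_grid_oracle(atp, v)
    km_step <- diff(range(c(max(atp) / 100, 4 * max(atp)))) / 159
    vmax_step <- diff(range(c(max(v) / 2, 3 * max(v)))) / 159
    expect_equal(fit$km_uM, unname(oracle["km"]), tolerance = 2 * km_step /
                   unname(oracle["km"]) + 0.01)
    expect_equal(fit$vmax_app, unname(oracle["vmax"]),
                 tolerance = 2 * vmax_step / unname(oracle["vmax"]) + 0.01)
  }
})

test_that("non-saturating titrations are flagged as extrapolated", {
  atp <- c(1, 2, 4, 8, 16)
  fit <- fit_mm_atp(atp, 100 * atp / (500 + atp))
  expect_true(fit$extrapolated)
})

test_that("Km recovery from noisy simulated ATP titrations is unbiased", {
  prof <- reference_profile("JAK2_JH1JH2_WT")
  layout <- data.frame(peptide_id = "STA5A_687_699", conc_uM = 1000)
  ds <- simulate_experiment(atp_titration_design("JAK2_JH1JH2_WT", 2),
                            layout, prof, noise_model(), master_seed = 42)
  rates <- extract_rates(ds)
  fit <- fit_mm_atp(rates$atp_uM, rates$v)
  expect_lt(abs(fit$km_uM - 88), 2 * fit$km_se)

  # median relative bias over repeated noisy titrations stays under 5%
  kms <- vapply(1:60, function(i) {
    dsi <- simulate_experiment(atp_titration_design("JAK2_JH1JH2_WT", 2,
                                                    replicates = 1L),
                               layout, prof, noise_model(), master_seed = i)
    ri <- extract_rates(dsi)
    fit_mm_atp(ri$atp_uM, ri$v)$km_uM
  }, numeric(1))
  expect_lt(abs(median(kms) - 88) / 88, 0.05)
})

test_that("efficiency slope reproduces exact linear data and its invariances", {
  concs <- c(100, 300, 400, 600, 750, 1000)
  fit <- efficiency_from_linear(concs, 0.1 * concs)
  expect_equal(fit$vmax_km, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$conc_used, concs)
  # replicate order must not matter
  d <- data.frame(conc_uM = rep(concs, each = 3),
                  v = 0.2 * rep(concs, each = 3) + rep(c(-1, 0, 1), 6))
  shuffled <- d[rev(seq_len(nrow(d))), ]
  expect_equal(efficiency_from_linear(d)$vmax_km,
               efficiency_from_linear(shuffled)$vmax_km)
  # unit-preserving rescale of [S] reciprocally rescales the slope
  fit_mM <- efficiency_from_linear(concs / 1000, 0.1 * concs)
  expect_equal(fit_mM$vmax_km, 100, tolerance = 1e-9)
  # negative slope flags a non-substrate; too few levels error out
  expect_true(efficiency_from_linear(concs, -0.05 * concs)$non_substrate)
  expect_error(efficiency_from_linear(c(100, 300), c(1, 3)), ">= 3")
})

test_that("slope attenuation under peptide saturation matches the OLS oracle", {
  concs <- c(100, 300, 400, 600, 750, 1000)
  km_pep <- 1e4
  v <- concs / (1 + concs / km_pep)  # Vmax/Km = 1
  oracle <- ols_oracle(concs, v)
  fit <- efficiency_from_linear(concs, v)
  expect_equal(fit$vmax_km, unname(oracle["slope"]), tolerance = 1e-9)
  # the free-intercept slope under-reads Vmax/Km by the saturation bend
  expect_lt(fit$vmax_km, 1)
  # and converges to Vmax/Km as Km_pep grows
  v2 <- concs / (1 + concs / 1e5)
  expect_equal(efficiency_from_linear(concs, v2)$vmax_km, 1,
               tolerance = 0.02)
  expect_gt(efficiency_from_linear(concs, v2)$vmax_km, fit$vmax_km)
})

test_that("optional truncation drops the top level only when R2 gains", {
  concs <- c(100, 300, 400, 600, 750, 1000)
  v <- 0.1 * concs
  v[6] <- 40  # saturated top point
  fit <- efficiency_from_linear(concs, v, truncate = TRUE)
  expect_equal(fit$conc_used, concs[1:5])
  expect_equal(fit$vmax_km, 0.1, tolerance = 1e-9)
  # exact data never truncates
  fit2 <- efficiency_from_linear(concs, 0.1 * concs, truncate = TRUE)
  expect_equal(fit2$conc_used, concs)
})

test_that("calibrated zero-noise simulation returns the reference efficiencies", {
  cc <- "JAK2_JH1"
  prof <- reference_profile(cc)
  design <- data.frame(construct_id = cc,
                       enzyme_pmol = prof$pmol_per_reaction, atp_uM = 400,
                       replicate = 1L, control_type = "none",
                       stringsAsFactors = FALSE)
  ds <- simulate_experiment(design, custom_chip_layout(), prof, noise_off(),
                            master_seed = 9)
  rates <- extract_rates(ds)
  ref_value <- unname(prof$efficiency_by_peptide["STA5A_687_699"]) * 1000 *
    prof$pmol_per_reaction
  norm <- normalize_activity(rates, ref_value = ref_value)
  eff <- efficiency_table(norm)
  truth <- prof$efficiency_by_peptide[eff$peptide_id]
  expect_true(all(abs(eff$vmax_km - truth) / truth < 0.01))
  expect_equal(eff$vmax_km[eff$peptide_id == "STA5A_687_699"], 2.087,
               tolerance = 0.01)
})
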