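wt_profile <- reference_profile("JAK2_JH1JH2_WT")

test_that("true initial rate follows the first-order forward model", {
  cond <- run_condition("JAK2_JH1JH2_WT", enzyme_pmol = 1, atp_uM = 400)
  # hand evaluation: 0.106 * 100 * 400/(88 + 400)
  expect_equal(true_initial_rate(wt_profile, "STA5A_687_699", 100, cond),
               0.106 * 100 * 400 / 488, tolerance = 1e-12)
  # linear in enzyme and substrate
  cond2 <- run_condition("JAK2_JH1JH2_WT", 2, 400)
  expect_equal(true_initial_rate(wt_profile, "STA5A_687_699", 300, cond2),
               6 * true_initial_rate(wt_profile, "STA5A_687_699", 100, cond))
  # Michaelis half-saturation: v at [ATP] = Km is half the saturating limit
  at_km <- run_condition("JAK2_JH1JH2_WT", 1, 88)
  sat <- run_condition("JAK2_JH1JH2_WT", 1, 1e12)
  expect_equal(true_initial_rate(wt_profile, "STA5A_687_699", 100, at_km),
               true_initial_rate(wt_profile, "STA5A_687_699", 100, sat) / 2,
               tolerance = 1e-9)
  # decoys and negative concentrations
  expect_equal(true_initial_rate(wt_profile, "NOT_A_PEPTIDE", 100, cond), 0)
  expect_error(true_initial_rate(wt_profile, "STA5A_687_699", -1, cond),
               "negative")
})

test_that("inhibitor and artifact controls force a null reaction", {
  for (ct in c("staurosporine", "amp_pnp", "kinase_dead", "pre_activated")) {
    cond <- run_condition("JAK2_JH1JH2_WT", 2, 400, control_type = ct)
    expect_equal(true_initial_rate(wt_profile, "STA5A_687_699", 1000, cond),
                 0, info = ct)
  }
  no_e <- run_condition("JAK2_JH1JH2_WT", 0, 400, control_type = "no_enzyme")
  no_a <- run_condition("JAK2_JH1JH2_WT", 2, 0, control_type = "no_atp")
  expect_equal(true_initial_rate(wt_profile, "STA5A_687_699", 1000, no_e), 0)
  expect_equal(true_initial_rate(wt_profile, "STA5A_687_699", 1000, no_a), 0)
  expect_error(run_condition("X", 2, 400, control_type = "no_enzyme"),
               "enzyme_pmol = 0")
  expect_error(run_condition("X", 2, 100, control_type = "no_atp"),
               "atp_uM = 0")
})

test_that("simulated spots match the closed-form association curve", {
  s <- simulate_spot(50, 1000, noise_off())
  expect_equal(s$cycle, seq(2L, 60L, 2L))
  expect_equal(tail(s$signal, 1), 1000 * (1 - exp(-1.5)), tolerance = 1e-12)
  expect_equal(s$signal, 1000 * (1 - exp(-0.025 * s$cycle)),
               tolerance = 1e-12)
  expect_false(attr(s, "saturated"))
  # null reaction with all noise off is identically zero
  null <- simulate_spot(0, 1000, noise_off())
  expect_true(all(null$signal == 0))
  # near-instant saturation is flagged
  fast <- simulate_spot(2 * 1000 * 4, 1000, noise_off())
  expect_true(attr(fast, "saturated"))
})

test_that("experiment simulation is deterministic and key-unique", {
  prof <- screen_profile("JAK2_JH1JH2_WT")
  design <- screen_design("JAK2_JH1JH2_WT", enzyme_levels = c(0, 2),
                          atp_levels = c(0, 100))
  layout <- screen_layout(c("STA5A_687_699", "EPOR_361_373"))
  ds1 <- simulate_experiment(design, layout, prof, noise_model(),
                             master_seed = 11)
  ds2 <- simulate_experiment(design, layout, prof, noise_model(),
                             master_seed = 11)
  expect_identical(ds1, ds2)
  ds3 <- simulate_experiment(design, layout, prof, noise_model(),
                             master_seed = 12)
  expect_false(identical(ds1$signal, ds3$signal))
  # each (condition, spot) appears exactly once, 30 time points each
  key <- with(ds1, paste(control, enzyme_pmol, atp_uM, replicate,
                         peptide_id, conc_uM))
  expect_true(all(table(key) == 30L))
  expect_error(simulate_experiment(rbind(design, design[1, ]), layout, prof,
                                   noise_model(), 1),
               "duplicate run conditions")
  expect_error(simulate_experiment(design, rbind(layout, layout[1, ]), prof,
                                   noise_model(), 1),
               "duplicate \\(peptide")
})

test_that("noiseless endpoint signal is monotone in enzyme and ATP", {
  prof <- reference_profile("JAK2_JH1JH2_WT")
  layout <- data.frame(peptide_id = "STA5A_687_699", conc_uM = 1000)
  end_signal <- function(enzyme, atp) {
    d <- data.frame(construct_id = "JAK2_JH1JH2_WT", enzyme_pmol = enzyme,
                    atp_uM = atp, replicate = 1L, control_type = "none",
                    stringsAsFactors = FALSE)
    ds <- simulate_experiment(d, layout, prof, noise_off(), 1)
    tail(ds$signal, 1)
  }
  by_enzyme <- vapply(c(0.5, 1, 2, 4, 8), end_signal, numeric(1), atp = 100)
  expect_true(all(diff(by_enzyme) > 0))
  by_atp <- vapply(c(25, 50, 100, 200, 400), end_signal, numeric(1),
                   enzyme = 2)
  expect_true(all(diff(by_atp) > 0))
})

test_that("first-order default keeps v/[S] exactly constant; finite Km bends it", {
  cond <- run_condition("JAK2_JH1JH2_WT", 1, 400)
  concs <- c(10, 50, 100, 500, 1000)
  ratios <- vapply(concs, function(s)
    true_initial_rate(wt_profile, "STA5A_687_699", s, cond) / s, numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-3)
  with_km <- vapply(concs, function(s)
    true_initial_rate(wt_profile, "STA5A_687_699", s, cond,
                      km_pep_uM = 1e4) / s, numeric(1))
  expect_true(all(diff(with_km) < 0))
})

test_that("dataset write/read round trip preserves values and sidecar", {
  prof <- screen_profile("JAK2_JH1JH2_WT")
  ds <- simulate_experiment(
    screen_design("JAK2_JH1JH2_WT", enzyme_levels = 2, atp_levels = 100),
    screen_layout("STA5A_687_699"), prof, noise_model(), 5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, tmp)
  expect_true(file.exists(paste0(tmp, ".truth.yaml")))
  back <- read_dataset(tmp)
  expect_equal(back$signal, ds$signal)
  expect_equal(back$peptide_id, ds$peptide_id)
  truth <- yaml::read_yaml(paste0(tmp, ".truth.yaml"))
  expect_equal(truth$master_seed, 5)
})
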