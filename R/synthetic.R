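CONTROL_TYPES <- c("none", "no_enzyme", "no_atp", "staurosporine", "amp_pnp",
                   "kinase_dead", "pre_activated")

#' Describe one incubation run
#'
#' @param construct_id kinase construct identifier.
#' @param enzyme_pmol enzyme amount per reaction (pmol), >= 0.
#' @param atp_uM ATP concentration (uM), >= 0.
#' @param replicate technical replicate index, >= 1.
#' @param control_type `"none"` for a reaction run, or one of the negative /
#'   artifact controls: `"no_enzyme"`, `"no_atp"`, `"staurosporine"` (10 uM),
#'   `"amp_pnp"` (100 uM, non-hydrolysable ATP analogue), `"kinase_dead"`
#'   (catalytically inactive K882D), `"pre_activated"` (enzyme pre-incubated
#'   with ATP then stopped, probing binding artifacts).
#' @return list of class `run_condition`.
#' @export
run_condition <- function(construct_id, enzyme_pmol, atp_uM, replicate = 1L,
                          control_type = "none") {
  control_type <- match.arg(control_type, CONTROL_TYPES)
  stopifnot(enzyme_pmol >= 0, atp_uM >= 0, replicate >= 1)
  if (control_type == "no_enzyme" && enzyme_pmol != 0) {
    stop("no_enzyme control requires enzyme_pmol = 0", call. = FALSE)
  }
  if (control_type == "no_atp" && atp_uM != 0) {
    stop("no_atp control requires atp_uM = 0", call. = FALSE)
  }
  structure(list(construct_id = construct_id, enzyme_pmol = enzyme_pmol,
                 atp_uM = atp_uM, replicate = as.integer(replicate),
                 control_type = control_type),
            class = "run_condition")
}

#' Measurement noise model for simulated arrays
#'
#' Additive plus proportional Gaussian noise on spot signals and a Gaussian
#' local-background channel. The assay description gives no noise model, so
#' these are explicit simulation assumptions; defaults are calibrated so
#' that technical-replicate CVs land in the 5-10% range typical of the
#' reported slope standard errors.
#'
#' @param sigma_add additive signal SD (fluorescence units).
#' @param sigma_prop proportional noise coefficient (SD = sigma_prop * signal).
#' @param bg_mean,bg_sd local background mean and SD (fluorescence units).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(sigma_add = 5, sigma_prop = 0.05,
                        bg_mean = 200, bg_sd = 20) {
  stopifnot(sigma_add >= 0, sigma_prop >= 0, bg_sd >= 0)
  structure(list(sigma_add = sigma_add, sigma_prop = sigma_prop,
                 bg_mean = bg_mean, bg_sd = bg_sd), class = "noise_model")
}

#' Noise-free measurement model
#' @return a [noise_model()] with every variance and the background zeroed.
#' @export
noise_off <- function() noise_model(0, 0, 0, 0)

#' Ground-truth initial phosphorylation rate of one spot
#'
#' Forward model of the assay in its working regime: rate first-order in
#' peptide (the Vmax/Km regime), linear in enzyme amount, Michaelis-saturating
#' in ATP:
#' \deqn{v = E \cdot (V_{max}/K_m)_{pep} \cdot [S]_{eff} \cdot
#'       \frac{[ATP]}{K_m^{ATP} + [ATP]} \cdot u}
#' where `[S]_eff = [S] / (1 + [S]/Km_pep)` introduces peptide-level
#' saturation when a finite `km_pep_uM` is supplied (default: purely
#' first-order). Inhibitor, kinase-dead, no-substrate and pre-activated
#' controls force v = 0; peptides absent from the profile are decoys with
#' v = 0.
#'
#' @param profile a [construct_profile()].
#' @param peptide_id peptide identifier.
#' @param spot_conc_uM spotted peptide concentration (uM), >= 0.
#' @param cond a [run_condition()].
#' @param signal_gain fluorescence units per relative-activity unit.
#' @param km_pep_uM peptide Michaelis constant (uM); `Inf` keeps the model
#'   first-order in peptide.
#' @return true initial velocity (signal units / min), >= 0.
#' @export
#' @examples
#' wt <- reference_profile("JAK2_JH1JH2_WT")
#' cond <- run_condition("JAK2_JH1JH2_WT", enzyme_pmol = 1, atp_uM = 400)
#' true_initial_rate(wt, "STA5A_687_699", 100, cond)
true_initial_rate <- function(profile, peptide_id, spot_conc_uM, cond,
                              signal_gain = 1, km_pep_uM = Inf) {
  stopifnot(inherits(profile, "construct_profile"),
            inherits(cond, "run_condition"))
  if (spot_conc_uM < 0) stop("negative peptide concentration", call. = FALSE)
  if (cond$control_type %in% c("staurosporine", "amp_pnp", "kinase_dead",
                               "pre_activated")) {
    return(0)
  }
  eff <- profile$efficiency_by_peptide[peptide_id]
  if (is.na(eff)) return(0)
  s_eff <- spot_conc_uM / (1 + spot_conc_uM / km_pep_uM)
  f_atp <- if (cond$atp_uM == 0) 0 else
    cond$atp_uM / (profile$km_atp_uM + cond$atp_uM)
  unname(cond$enzyme_pmol * eff * s_eff * f_atp * signal_gain)
}

#' Simulate one spot's real-time progress curve
#'
#' Inverts the exponential-association model used downstream: the clean
#' curve is `y(c) = y0 + ymax * (1 - exp(-k c))` with the rate constant
#' chosen so that the initial tangent, in minutes, equals `v_true`
#' (`k = v_true / (cycles_per_min * ymax)` per cycle). Background and noise
#' per [noise_model()] are then added; the recorded `signal` includes the
#' spot's local background, which is reported in `background` exactly as a
#' local-background quantifier would, so background subtraction cancels it
#' and leaves only the spot's measurement noise.
#'
#' @param v_true true initial velocity (signal units / min).
#' @param plateau_ymax saturation plateau of the clean signal (> 0).
#' @param noise a [noise_model()].
#' @param cycles imaged pump cycles (default: every second cycle of a
#'   60-cycle run, i.e. 30 images over 30 min).
#' @param cycles_per_min pumping rate (cycles / min).
#' @param y0 clean signal offset at cycle 0.
#' @return data.frame with columns `cycle`, `signal`, `background` and
#'   attribute `saturated` (`TRUE` when the curve reaches > 99.9% of plateau
#'   within 2 cycles, making the fit degenerate).
#' @export
#' @examples
#' s <- simulate_spot(50, 1000, noise_off())
#' tail(s, 1)  # 1000 * (1 - exp(-1.5)) = 776.87 at cycle 60
simulate_spot <- function(v_true, plateau_ymax, noise = noise_model(),
                          cycles = seq(2L, 60L, by = 2L),
                          cycles_per_min = 2, y0 = 0) {
  stopifnot(plateau_ymax > 0, v_true >= 0, inherits(noise, "noise_model"))
  k <- v_true / (cycles_per_min * plateau_ymax)
  clean <- y0 + plateau_ymax * (1 - exp(-k * cycles))
  n <- length(cycles)
  # the reported background channel is the spot's own local background
  # (quantified from the surrounding pixels), so subtraction cancels it;
  # what survives is the spot's measurement noise
  bg <- noise$bg_mean + stats::rnorm(n, 0, noise$bg_sd)
  eps <- stats::rnorm(n, 0, noise$sigma_add) +
    clean * stats::rnorm(n, 0, noise$sigma_prop)
  out <- data.frame(cycle = cycles, signal = clean + bg + eps,
                    background = bg)
  attr(out, "saturated") <- (1 - exp(-k * 2)) > 0.999
  out
}

#' Default custom-array layout: peptide concentration series
#'
#' @param peptide_ids peptides to spot (default: the 24 peptides of the
#'   packaged catalytic-efficiency table).
#' @param concs_uM spotted concentration series (uM).
#' @return data.frame with one row per (peptide, concentration) spot.
#' @export
custom_chip_layout <- function(peptide_ids = NULL,
                               concs_uM = c(100, 300, 400, 600, 750, 1000)) {
  if (is.null(peptide_ids)) peptide_ids <- load_peptides(TRUE)$peptide_id
  expand.grid(peptide_id = peptide_ids, conc_uM = concs_uM,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Screening-array layout: one spot per peptide at a single concentration
#'
#' @param peptide_ids peptides to spot (default: the 63 screen peptides).
#' @param conc_uM spotted concentration (uM).
#' @param n_decoys number of additional never-phosphorylated decoy peptides
#'   appended to emulate a full 144-spot array.
#' @return data.frame with `peptide_id` and `conc_uM`.
#' @export
screen_layout <- function(peptide_ids = NULL, conc_uM = 1000, n_decoys = 0) {
  if (is.null(peptide_ids)) peptide_ids <- load_screen_calls()$table$peptide_id
  if (n_decoys > 0) {
    peptide_ids <- c(peptide_ids, sprintf("DECOY_%03d_%03d", seq_len(n_decoys),
                                          seq_len(n_decoys) + 12L))
  }
  data.frame(peptide_id = peptide_ids, conc_uM = conc_uM,
             stringsAsFactors = FALSE)
}

#' Default screening design: enzyme and ATP titrations plus all controls
#'
#' Emulates the screening protocol: enzyme titrated 0-8 pmol at fixed ATP,
#' ATP titrated 0-400 uM at fixed enzyme, and the full set of negative /
#' artifact controls.
#'
#' @param construct_id construct being screened.
#' @param enzyme_levels enzyme titration (pmol) at `atp_fixed`.
#' @param atp_levels ATP titration (uM) at `enzyme_fixed`.
#' @param atp_fixed,enzyme_fixed the fixed co-substrate levels.
#' @param replicates technical replicates per condition.
#' @return data.frame of run conditions (one row per run).
#' @export
screen_design <- function(construct_id, enzyme_levels = c(0, 2, 4, 8),
                          atp_levels = c(0, 100, 400), atp_fixed = 100,
                          enzyme_fixed = 2, replicates = 1L) {
  rows <- list()
  add <- function(enzyme, atp, control) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        construct_id = construct_id, enzyme_pmol = enzyme, atp_uM = atp,
        replicate = r, control_type = control, stringsAsFactors = FALSE)
    }
  }
  for (e in enzyme_levels) add(e, atp_fixed, if (e == 0) "no_enzyme" else "none")
  for (a in setdiff(atp_levels, atp_fixed)) {
    add(enzyme_fixed, a, if (a == 0) "no_atp" else "none")
  }
  add(enzyme_fixed, 400, "staurosporine")
  add(enzyme_fixed, 400, "amp_pnp")
  add(enzyme_fixed, 400, "kinase_dead")
  add(enzyme_fixed, 400, "pre_activated")
  do.call(rbind, rows)
}

#' Simulate a complete peptide-microarray experiment
#'
#' Generates the full long-format dataset: one background-corrected-ready
#' time series per (run condition, spot). Every spot draws its own RNG
#' stream from a stable hash of the condition/spot key and the master seed,
#' so datasets are bit-reproducible and independent of row order.
#'
#' @param design data.frame of run conditions with columns `construct_id`,
#'   `enzyme_pmol`, `atp_uM`, `replicate`, `control_type`
#'   (e.g. from [screen_design()]).
#' @param layout data.frame of spots with columns `peptide_id`, `conc_uM`
#'   (e.g. from [custom_chip_layout()]).
#' @param profiles a single [construct_profile()] or a named list of them
#'   keyed by construct id.
#' @param noise a [noise_model()].
#' @param master_seed master RNG seed (integer).
#' @param signal_gain,km_pep_uM forwarded to [true_initial_rate()].
#' @param ymax_per_uM clean-signal plateau per uM of spotted peptide; the
#'   plateau is proportional to the spotted amount.
#' @param cycles,cycles_per_min assay geometry, see [simulate_spot()].
#' @return long data.frame with columns `construct`, `control`,
#'   `enzyme_pmol`, `atp_uM`, `replicate`, `peptide_id`, `conc_uM`, `cycle`,
#'   `signal`, `background`, plus attribute `truth` (a list with the
#'   profiles and all generator parameters).
#' @export
simulate_experiment <- function(design, layout, profiles,
                                noise = noise_model(), master_seed = 1L,
                                signal_gain = 1, km_pep_uM = Inf,
                                ymax_per_uM = 300,
                                cycles = seq(2L, 60L, by = 2L),
                                cycles_per_min = 2) {
  stopifnot(nrow(design) > 0, nrow(layout) > 0)
  if (inherits(profiles, "construct_profile")) {
    profiles <- stats::setNames(list(profiles), profiles$construct_id)
  }
  cond_key <- with(design, paste(construct_id, control_type, enzyme_pmol,
                                 atp_uM, replicate, sep = "|"))
  if (anyDuplicated(cond_key)) {
    stop("duplicate run conditions in design", call. = FALSE)
  }
  if (anyDuplicated(paste(layout$peptide_id, layout$conc_uM))) {
    stop("duplicate (peptide, concentration) spots in layout", call. = FALSE)
  }
  chunks <- vector("list", nrow(design) * nrow(layout))
  idx <- 0L
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    cond <- run_condition(d$construct_id, d$enzyme_pmol, d$atp_uM,
                          d$replicate, d$control_type)
    profile <- profiles[[d$construct_id]]
    if (is.null(profile)) {
      stop("no profile supplied for construct ", d$construct_id,
           call. = FALSE)
    }
    for (j in seq_len(nrow(layout))) {
      sp <- layout[j, ]
      v <- true_initial_rate(profile, sp$peptide_id, sp$conc_uM, cond,
                             signal_gain = signal_gain, km_pep_uM = km_pep_uM)
      key <- paste(cond_key[i], sp$peptide_id, sp$conc_uM, sep = "|")
      seed <- stable_hash(key, master_seed)
      series <- with_local_seed(seed, simulate_spot(
        v, ymax_per_uM * sp$conc_uM, noise, cycles, cycles_per_min))
      idx <- idx + 1L
      chunks[[idx]] <- data.frame(
        construct = d$construct_id, control = d$control_type,
        enzyme_pmol = d$enzyme_pmol, atp_uM = d$atp_uM,
        replicate = d$replicate, peptide_id = sp$peptide_id,
        conc_uM = sp$conc_uM, cycle = series$cycle, signal = series$signal,
        background = series$background, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    profiles = profiles, noise = noise, master_seed = master_seed,
    signal_gain = signal_gain, km_pep_uM = km_pep_uM,
    ymax_per_uM = ymax_per_uM, cycles = cycles,
    cycles_per_min = cycles_per_min)
  out
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Write a simulated dataset and its ground-truth sidecar
#'
#' @param dataset long data.frame from [simulate_experiment()].
#' @param path output CSV path; the generator parameters are written next to
#'   it as `<path>.truth.yaml`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) {
    truth$profiles <- lapply(truth$profiles, unclass)
    truth$noise <- unclass(truth$noise)
    yaml::write_yaml(truth, paste0(path, ".truth.yaml"))
  }
  invisible(path)
}

#' Read a simulated dataset written by [write_dataset()]
#' @param path CSV path.
#' @return long data.frame (without the `truth` attribute).
#' @export
read_dataset <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
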