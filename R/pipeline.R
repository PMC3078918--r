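#' Default pipeline configuration
#'
#' All knobs of the end-to-end analysis in one list: assay geometry, noise,
#' the velocity convention, the normalization reference, and the comparison
#' reference construct. Every output written by [run_pipeline()] carries
#' this configuration (and its hash) in a sidecar, so a run is fully
#' reproducible from config plus inputs.
#'
#' @param master_seed master RNG seed for simulation.
#' @param constructs constructs to simulate and analyse.
#' @param replicates technical replicates per run.
#' @param atp_uM ATP concentration of the efficiency runs (uM).
#' @param sigma_add,sigma_prop,bg_mean,bg_sd noise model, see
#'   [noise_model()].
#' @param sd_mult background-SD multiplier for substrate calling.
#' @param second_point_cycle tangent cycle for the initial velocity.
#' @param cycles_per_min pumping rate.
#' @param n_cycles total pump cycles; imaged every `image_stride` cycles.
#' @param image_stride imaging stride in cycles.
#' @param reference_peptide,reference_conc_uM normalization reference spot.
#' @param reference_construct comparison reference (fold change = 1).
#' @param normalization `"calibrated"` anchors each construct's normalized
#'   scale to its known reference activity from the packaged profiles, so
#'   recovered efficiencies and cross-construct fold changes are on the
#'   reference scale; `"percent"` uses the plain percent-of-reference scale
#'   (reference spot = 100 per pmol), under which only within-construct
#'   quantities (percent of total, motifs) are comparable across constructs.
#' @param ymax_per_uM,signal_gain simulator scale parameters.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1L,
                            constructs = c("JAK2_JH1", "JAK2_JH1JH2_WT",
                                           "JAK2_JH1JH2_V617F", "JAK3_JH1"),
                            replicates = 3L, atp_uM = 400,
                            sigma_add = 5, sigma_prop = 0.05,
                            bg_mean = 200, bg_sd = 20, sd_mult = 2,
                            second_point_cycle = 4, cycles_per_min = 2,
                            n_cycles = 60L, image_stride = 2L,
                            reference_peptide = "STA5A_687_699",
                            reference_conc_uM = 1000,
                            reference_construct = "JAK2_JH1JH2_WT",
                            normalization = c("calibrated", "percent"),
                            ymax_per_uM = 300, signal_gain = 1) {
  normalization <- match.arg(normalization)
  cfg <- as.list(environment())
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of a [pipeline_config()]; serialize-parse-serialize is
#' idempotent.
#'
#' @param path file path.
#' @param config a `pipeline_config`.
#' @return `read_config()` returns the configuration; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  stable_hash(paste(yaml::as.yaml(unclass(config)), collapse = "\n"))
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates (or accepts) a custom-array concentration-series experiment
#' for each configured construct, extracts initial velocities, normalizes
#' them to the reference spot, estimates per-peptide catalytic
#' efficiencies, applies the fold-change and percent-of-total transforms,
#' builds the efficiency-weighted motif for every construct, and writes
#' all results as TSV plus a configuration sidecar and MANIFEST.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param dataset optional long-format dataset; when `NULL` one is
#'   simulated from the packaged reference profiles under `config`.
#' @return invisibly, a list with `rates`, `normalized`, `efficiency`,
#'   `comparison`, `motifs` and `files` (paths written).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cycles <- seq(config$image_stride, config$n_cycles,
                by = config$image_stride)
  noise <- noise_model(config$sigma_add, config$sigma_prop,
                       config$bg_mean, config$bg_sd)

  if (is.null(dataset)) {
    message("simulating custom arrays for ",
            length(config$constructs), " construct(s)")
    profiles <- lapply(config$constructs, reference_profile)
    names(profiles) <- config$constructs
    design <- do.call(rbind, lapply(config$constructs, function(cc) {
      expand.grid(construct_id = cc,
                  enzyme_pmol = profiles[[cc]]$pmol_per_reaction,
                  atp_uM = config$atp_uM,
                  replicate = seq_len(config$replicates),
                  control_type = "none",
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
    dataset <- simulate_experiment(design, custom_chip_layout(), profiles,
                                   noise, config$master_seed,
                                   signal_gain = config$signal_gain,
                                   ymax_per_uM = config$ymax_per_uM,
                                   cycles = cycles,
                                   cycles_per_min = config$cycles_per_min)
  }
  if (nrow(dataset) == 0L) stop("empty dataset: nothing to analyse",
                                call. = FALSE)

  message("fitting ", length(unique(paste(dataset$construct,
                                          dataset$peptide_id,
                                          dataset$conc_uM,
                                          dataset$replicate))),
          " progress curves")
  rates <- extract_rates(dataset,
                         second_point_cycle = config$second_point_cycle,
                         cycles_per_min = config$cycles_per_min)
  normalized <- do.call(rbind, lapply(unique(rates$construct), function(cc) {
    rv <- if (config$normalization == "calibrated") {
      prof <- reference_profile(cc)
      eff_ref <- unname(prof$efficiency_by_peptide[config$reference_peptide])
      if (is.na(eff_ref) || eff_ref <= 0) {
        stop("no reference efficiency for construct ", cc,
             "; use normalization = \"percent\"", call. = FALSE)
      }
      eff_ref * config$reference_conc_uM * prof$pmol_per_reaction
    } else 100
    normalize_activity(rates[rates$construct == cc, , drop = FALSE],
                       reference_peptide = config$reference_peptide,
                       reference_conc_uM = config$reference_conc_uM,
                       ref_value = rv)
  }))
  rownames(normalized) <- NULL
  eff <- efficiency_table(normalized, atp_uM = config$atp_uM)
  comp <- comparison_table(eff, config$reference_construct)

  peps <- load_peptides()
  motifs <- list()
  for (cc in unique(eff$construct_id)) {
    sub <- pct_total(eff)
    sub <- sub[sub$construct_id == cc & sub$vmax_km > 0, , drop = FALSE]
    aln <- align_on_central_tyr(
      peps[peps$peptide_id %in% sub$peptide_id, , drop = FALSE])
    motifs[[cc]] <- weighted_motif(
      aln, stats::setNames(sub$pct_total, sub$peptide_id))
  }

  wtsv <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  files <- c(wtsv(rates, "rates.tsv"),
             wtsv(normalized, "normalized_rates.tsv"),
             wtsv(eff, "efficiency.tsv"),
             wtsv(comp, "comparison.tsv"))
  for (cc in names(motifs)) {
    f <- file.path(out_dir, paste0("motif_", cc, ".tsv"))
    write_motif(motifs[[cc]], f,
                meme_path = file.path(out_dir, paste0("motif_", cc, ".meme")),
                name = cc)
    files <- c(files, f, file.path(out_dir, paste0("motif_", cc, ".meme")))
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- data.frame(
    file = c(basename(files), "config.yaml"),
    complete = TRUE,
    package_version = as.character(utils::packageVersion("pamkin")),
    config_hash = config_hash(config))
  wtsv(manifest, "MANIFEST.tsv")
  message("wrote ", length(files) + 2L, " files to ", out_dir)
  invisible(list(rates = rates, normalized = normalized, efficiency = eff,
                 comparison = comp, motifs = motifs,
                 files = c(files, cfg_path,
                           file.path(out_dir, "MANIFEST.tsv"))))
}
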