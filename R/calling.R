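#' Estimate the array background level and spread
#'
#' Pools the local-background channel at the quality-control image (20 min
#' by default) across all spots, optionally together with the signals of
#' tyrosine-free control peptides, and returns the pooled mean and SD. The
#' SD uses the population (divide-by-n) estimator, so duplicating every
#' background observation leaves the estimate unchanged.
#'
#' @param dataset long-format dataset (see [extract_rates()]).
#' @param qc_time_min time (min) of the image used.
#' @param cycles_per_min pumping rate.
#' @param no_tyr_peptides ids of tyrosine-free control peptides whose
#'   signals are pooled with the background channel.
#' @return list with `bg_mean` and `bg_sd`.
#' @export
estimate_background_sd <- function(dataset, qc_time_min = 20,
                                   cycles_per_min = 2,
                                   no_tyr_peptides = character()) {
  qc_cycle <- qc_time_min * cycles_per_min
  at_qc <- dataset[dataset$cycle == qc_cycle, , drop = FALSE]
  if (nrow(at_qc) == 0L) {
    cyc <- unique(dataset$cycle)
    at_qc <- dataset[dataset$cycle == cyc[which.min(abs(cyc - qc_cycle))], ,
                     drop = FALSE]
  }
  pool <- at_qc$background
  if (length(no_tyr_peptides)) {
    pool <- c(pool, at_qc$signal[at_qc$peptide_id %in% no_tyr_peptides])
  }
  pool <- pool[is.finite(pool)]
  if (!length(pool)) {
    stop("no background information in dataset; supply bg_sd explicitly",
         call. = FALSE)
  }
  n <- length(pool)
  m <- mean(pool)
  s <- sqrt(sum((pool - m)^2) / n)
  if (s == 0) {
    stop("background channel has zero spread; supply bg_sd explicitly",
         call. = FALSE)
  }
  list(bg_mean = m, bg_sd = s)
}

# replicate-mean background-subtracted QC signal per grouping
s20_table <- function(dataset, qc_time_min, cycles_per_min) {
  qc_cycle <- qc_time_min * cycles_per_min
  d <- dataset[dataset$cycle == qc_cycle, , drop = FALSE]
  if (nrow(d) == 0L) {
    cyc <- unique(dataset$cycle)
    d <- dataset[dataset$cycle == cyc[which.min(abs(cyc - qc_cycle))], ,
                 drop = FALSE]
  }
  d$s20 <- d$signal - d$background
  stats::aggregate(s20 ~ construct + control + enzyme_pmol + atp_uM +
                     peptide_id + conc_uM, data = d, FUN = mean)
}

#' Call substrates from a screening dataset
#'
#' Reproduces the screening rule: a peptide is a substrate of a construct
#' when (i) its background-subtracted signal at 20 min exceeds `sd_mult`
#' times the background SD, (ii) its 20-min signal increases strictly with
#' enzyme amount across the enzyme titration, with the top level exceeding
#' the bottom by more than `sd_mult * bg_sd`, (iii) likewise for the ATP
#' titration, and (iv) it shows no above-threshold signal in any negative
#' or artifact control (no enzyme, no ATP, staurosporine, AMP-PNP,
#' kinase-dead, pre-activated). When a titration has fewer than two levels
#' the corresponding evidence flag is `NA` and the peptide is not called.
#'
#' @param dataset long-format screening dataset containing the titration
#'   runs (`control == "none"`, plus the zero-level `no_enzyme` / `no_atp`
#'   runs) and the control runs.
#' @param sd_mult background-SD multiplier for the intensity threshold and
#'   the dose-dependence margin.
#' @param bg_sd background SD override; estimated from the data when `NULL`.
#' @param qc_time_min,cycles_per_min QC-image timing.
#' @param no_tyr_peptides forwarded to [estimate_background_sd()].
#' @return data.frame with one row per (construct, peptide): `called`,
#'   evidence flags `above_threshold`, `increases_with_enzyme`,
#'   `increases_with_atp`, `nonspecific`, plus `s20_mean` and `bg_sd_used`.
#' @export
call_substrates <- function(dataset, sd_mult = 2, bg_sd = NULL,
                            qc_time_min = 20, cycles_per_min = 2,
                            no_tyr_peptides = character()) {
  stopifnot(nrow(dataset) > 0)
  if (is.null(bg_sd)) {
    bg_sd <- estimate_background_sd(dataset, qc_time_min, cycles_per_min,
                                    no_tyr_peptides)$bg_sd
  }
  thr <- sd_mult * bg_sd
  s20 <- s20_table(dataset, qc_time_min, cycles_per_min)
  ctrl_types <- setdiff(CONTROL_TYPES, "none")

  # the enzyme titration runs at the fixed ATP level with the most enzyme
  # levels; zero-enzyme rows are the no_enzyme control at that ATP level
  main <- s20[s20$control == "none", , drop = FALSE]
  out <- list()
  for (construct in unique(dataset$construct)) {
    mc <- main[main$construct == construct, , drop = FALSE]
    sc <- s20[s20$construct == construct, , drop = FALSE]
    enz_atp <- if (nrow(mc)) {
      tab <- tapply(mc$enzyme_pmol, mc$atp_uM, function(x) length(unique(x)))
      as.numeric(names(tab)[which.max(tab)])
    } else NA_real_
    atp_enz <- if (nrow(mc)) {
      tab <- tapply(mc$atp_uM, mc$enzyme_pmol, function(x) length(unique(x)))
      as.numeric(names(tab)[which.max(tab)])
    } else NA_real_

    for (pep in unique(sc$peptide_id)) {
      pp <- sc[sc$peptide_id == pep, , drop = FALSE]
      mp <- pp[pp$control == "none", , drop = FALSE]

      # headline intensity: strongest reaction condition present
      s20_main <- if (nrow(mp)) {
        top <- mp[order(mp$enzyme_pmol, mp$atp_uM), ]
        mean(top$s20[top$enzyme_pmol == max(top$enzyme_pmol) &
                       top$atp_uM == max(top$atp_uM[top$enzyme_pmol ==
                                                      max(top$enzyme_pmol)])])
      } else NA_real_
      above <- if (is.na(s20_main)) NA else s20_main > thr

      dose_ok <- function(levels_df, level_col) {
        if (nrow(levels_df) < 2L) return(NA)
        means <- tapply(levels_df$s20, levels_df[[level_col]], mean)
        means <- means[order(as.numeric(names(means)))]
        if (length(means) < 2L) return(NA)
        all(diff(means) > 0) && (means[length(means)] - means[1L] > thr)
      }
      # enzyme series includes the matched no_enzyme control as the 0 level
      enz_rows <- pp[(pp$control == "none" | pp$control == "no_enzyme") &
                       pp$atp_uM == enz_atp, , drop = FALSE]
      inc_enz <- dose_ok(enz_rows, "enzyme_pmol")
      atp_rows <- pp[(pp$control == "none" | pp$control == "no_atp") &
                       pp$enzyme_pmol == atp_enz, , drop = FALSE]
      inc_atp <- dose_ok(atp_rows, "atp_uM")

      ctrl_rows <- pp[pp$control %in% ctrl_types, , drop = FALSE]
      nonspec <- if (nrow(ctrl_rows)) any(ctrl_rows$s20 > thr) else FALSE

      called <- isTRUE(above) && isTRUE(inc_enz) && isTRUE(inc_atp) &&
        !nonspec
      out[[length(out) + 1L]] <- data.frame(
        construct_id = construct, peptide_id = pep, called = called,
        above_threshold = above, increases_with_enzyme = inc_enz,
        increases_with_atp = inc_atp, nonspecific = nonspec,
        s20_mean = s20_main, bg_sd_used = bg_sd, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wide-format call table
#'
#' Mirrors the published screen layout: one row per peptide, one `X`-marked
#' column per construct.
#'
#' @param calls data.frame from [call_substrates()].
#' @return wide data.frame, `peptide_id` plus one column per construct with
#'   `"X"` for called substrates.
#' @export
calls_to_wide <- function(calls) {
  constructs <- sort(unique(calls$construct_id))
  peps <- sort(unique(calls$peptide_id))
  out <- data.frame(peptide_id = peps, stringsAsFactors = FALSE)
  for (cc in constructs) {
    sub <- calls[calls$construct_id == cc, ]
    out[[cc]] <- ifelse(peps %in% sub$peptide_id[sub$called], "X", "")
  }
  out
}
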