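#' Fold change of catalytic efficiency relative to a reference construct
#'
#' For every peptide, divides each construct's Vmax/Km by the reference
#' construct's value, so the reference column is 1 everywhere. The
#' reporting column rounds half away from zero, matching the published
#' convention (19.7 -> 20, 32.4 -> 32).
#'
#' @param eff_table long data.frame with `construct_id`, `peptide_id`,
#'   `vmax_km` (e.g. [load_efficiency_ref()] or [efficiency_table()]).
#' @param reference_construct construct whose efficiency is set to 1.
#' @return `eff_table` with added `fold_change` and `fold_change_rounded`
#'   columns; peptides whose reference efficiency is zero or missing are
#'   dropped with a warning.
#' @export
#' @examples
#' eff <- load_efficiency_ref()
#' fc <- fold_change(eff)
#' subset(fc, peptide_id == "EPOR_361_373" & construct_id == "JAK2_JH1")
fold_change <- function(eff_table, reference_construct = "JAK2_JH1JH2_WT") {
  stopifnot(all(c("construct_id", "peptide_id", "vmax_km") %in%
                  names(eff_table)))
  ref <- eff_table[eff_table$construct_id == reference_construct, ]
  if (!nrow(ref)) {
    stop("reference construct absent: ", reference_construct, call. = FALSE)
  }
  refmap <- stats::setNames(ref$vmax_km, ref$peptide_id)
  rv <- refmap[eff_table$peptide_id]
  bad <- is.na(rv) | rv <= 0
  if (any(bad)) {
    warning("dropping ", length(unique(eff_table$peptide_id[bad])),
            " peptide(s) with zero/missing reference efficiency")
    eff_table <- eff_table[!bad, , drop = FALSE]
    rv <- rv[!bad]
  }
  eff_table$fold_change <- eff_table$vmax_km / unname(rv)
  eff_table$fold_change_rounded <- round_half_up(eff_table$fold_change)
  attr(eff_table, "reference_construct") <- reference_construct
  eff_table
}

#' Percent of total catalytic efficiency within each construct
#'
#' Expresses each peptide's Vmax/Km as a percentage of the construct's
#' summed Vmax/Km. This transform averages out overall activity differences
#' between constructs while preserving peptide-specificity differences;
#' unrounded percentages sum to exactly 100 per construct.
#'
#' @param eff_table long data.frame with `construct_id`, `peptide_id`,
#'   `vmax_km`.
#' @return `eff_table` with added `pct_total` and `pct_total_rounded`
#'   columns.
#' @export
pct_total <- function(eff_table) {
  stopifnot(all(c("construct_id", "peptide_id", "vmax_km") %in%
                  names(eff_table)))
  sums <- tapply(eff_table$vmax_km, eff_table$construct_id, sum)
  if (any(sums <= 0)) {
    stop("construct(s) with all-zero efficiency: ",
         paste(names(sums)[sums <= 0], collapse = ", "), call. = FALSE)
  }
  eff_table$pct_total <-
    100 * eff_table$vmax_km / unname(sums[eff_table$construct_id])
  eff_table$pct_total_rounded <- round_half_up(eff_table$pct_total)
  eff_table
}

#' Full comparison table: fold change and percent of total
#'
#' @inheritParams fold_change
#' @return `eff_table` with `fold_change`, `fold_change_rounded`,
#'   `pct_total`, `pct_total_rounded` columns and a `reference_construct`
#'   attribute. Percentages are computed before any peptide is dropped for
#'   a missing reference value.
#' @export
comparison_table <- function(eff_table,
                             reference_construct = "JAK2_JH1JH2_WT") {
  fold_change(pct_total(eff_table), reference_construct)
}
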