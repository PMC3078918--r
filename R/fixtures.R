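#' Load the JAK2 substrate screening calls
#'
#' Reads the packaged substrate-identification table from the 144-peptide
#' tyrosine-kinase array screen: 63 peptides phosphorylated by the isolated
#' JAK2 kinase domain (JH1), with the subsets also phosphorylated by the
#' JH1-JH2 wild-type and V617F constructs marked. Calls are nested: every
#' wild-type or V617F substrate is also a JH1 substrate.
#'
#' @return An object of class `screen_truth`: a list with
#'   \describe{
#'     \item{table}{data.frame with columns `peptide_id`, `sequence`,
#'       `protein_description` and one logical column per construct.}
#'     \item{calls}{named list mapping construct id to the character vector of
#'       called peptide ids.}
#'   }
#' @export
#' @examples
#' truth <- load_screen_calls()
#' lengths(truth$calls)
load_screen_calls <- function() {
  path <- pamkin_extdata("screen_calls.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  constructs <- c("JAK2_JH1JH2_WT", "JAK2_JH1JH2_V617F", "JAK2_JH1")
  if (!all(constructs %in% names(tab))) {
    stop("corrupt fixture (missing construct columns): ", path, call. = FALSE)
  }
  for (cc in constructs) tab[[cc]] <- tab[[cc]] == "X"
  calls <- lapply(constructs, function(cc) tab$peptide_id[tab[[cc]]])
  names(calls) <- constructs
  nested <- all(calls$JAK2_JH1JH2_WT %in% calls$JAK2_JH1) &&
    all(calls$JAK2_JH1JH2_V617F %in% calls$JAK2_JH1)
  if (!nested) {
    stop("corrupt fixture (nestedness violated): ", path, call. = FALSE)
  }
  structure(list(table = tab, calls = calls), class = "screen_truth")
}

#' Load the catalytic-efficiency reference table
#'
#' Packaged per-peptide catalytic efficiencies (Vmax/Km at 400 uM ATP, with
#' slope standard errors and regression R-squared) for 24 peptides measured
#' with four kinase constructs, together with the published rounded
#' fold-change (wild type = 1) and percent-of-total columns.
#'
#' @return data.frame with columns `peptide_id`, `construct_id`, `vmax_km`,
#'   `vmax_km_se`, `r_squared`, `fold_change_printed`, `pct_total_printed`;
#'   24 peptides x 4 constructs = 96 rows.
#' @export
#' @examples
#' eff <- load_efficiency_ref()
#' subset(eff, peptide_id == "STA5A_687_699")
load_efficiency_ref <- function() {
  path <- pamkin_extdata("catalytic_efficiency.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (length(unique(tab$peptide_id)) != 24L || nrow(tab) != 96L) {
    stop("corrupt fixture (expected 24 peptides x 4 constructs): ", path,
         call. = FALSE)
  }
  stopifnot(all(tab$vmax_km >= 0),
            all(tab$r_squared > 0 & tab$r_squared <= 1))
  tab
}

#' Load per-construct kinetic constants
#'
#' Michaelis constants for ATP, apparent Vmax (relative activity per pmol
#' enzyme on 1000 uM STA5A_687_699) and the enzyme amount used per reaction,
#' for each kinase construct. The kinase-dead K882D control has Vmax,app = 0.
#'
#' @return data.frame with columns `construct_id`, `km_atp_uM`, `km_atp_se`,
#'   `vmax_app_per_pmol`, `vmax_app_se`, `pmol_per_reaction`.
#' @export
load_construct_kinetics <- function() {
  path <- pamkin_extdata("construct_kinetics.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(tab$km_atp_uM > 0), all(tab$pmol_per_reaction > 0))
  tab$vmax_app_per_pmol <- as.numeric(tab$vmax_app_per_pmol)
  stopifnot(tab$vmax_app_per_pmol[tab$construct_id == "JAK2_K882D"] == 0)
  tab
}

#' Peptide library of the screening array
#'
#' @param table2_only if `TRUE`, restrict to the 24 peptides of the custom
#'   concentration-series array (those with measured catalytic efficiencies).
#' @return data.frame with `peptide_id`, `sequence` and `central_tyr_index`
#'   (1-based position of the alignment-anchor tyrosine, the Tyr closest to
#'   the sequence midpoint).
#' @export
load_peptides <- function(table2_only = FALSE) {
  tab <- load_screen_calls()$table[, c("peptide_id", "sequence")]
  if (table2_only) {
    keep <- unique(load_efficiency_ref()$peptide_id)
    tab <- tab[tab$peptide_id %in% keep, , drop = FALSE]
    stopifnot(nrow(tab) == 24L)
  }
  tab$central_tyr_index <- vapply(tab$sequence, central_tyr_index, integer(1))
  rownames(tab) <- NULL
  tab
}

#' Construct a peptide specification
#'
#' @param peptide_id identifier in `NAME_start_end` form (UniProt numbering).
#' @param sequence amino-acid string (13-15 residues on the arrays used here;
#'   other lengths are allowed).
#' @param spotted_concs_uM spotted concentration series in uM, ascending.
#' @param no_tyr_control flag for the tyrosine-free antibody control peptide.
#' @return list of class `peptide_spec`.
#' @export
peptide_spec <- function(peptide_id, sequence, spotted_concs_uM = 1000,
                         no_tyr_control = FALSE) {
  stopifnot(is.character(sequence), nchar(sequence) >= 1)
  if (!no_tyr_control && !grepl("Y", sequence)) {
    stop("peptide ", peptide_id, " contains no Tyr and is not flagged as a ",
         "no-Tyr control", call. = FALSE)
  }
  if (any(spotted_concs_uM <= 0) || is.unsorted(spotted_concs_uM)) {
    stop("spotted_concs_uM must be positive and ascending", call. = FALSE)
  }
  idx <- if (no_tyr_control) NA_integer_ else central_tyr_index(sequence)
  structure(list(peptide_id = peptide_id, sequence = sequence,
                 central_tyr_index = idx,
                 spotted_concs_uM = spotted_concs_uM,
                 no_tyr_control = no_tyr_control),
            class = "peptide_spec")
}

#' Construct a kinase activity profile
#'
#' A `construct_profile` is the ground truth driving the synthetic assay:
#' the construct's Km for ATP, its apparent Vmax per pmol enzyme, the enzyme
#' amount used per reaction, and a map from peptide id to catalytic
#' efficiency (Vmax/Km, relative activity per pmol per uM peptide). Peptides
#' absent from the map are non-substrates (efficiency 0).
#'
#' @param construct_id construct identifier.
#' @param km_atp_uM Michaelis constant for ATP (uM), > 0.
#' @param vmax_app_per_pmol apparent Vmax (relative activity / pmol), >= 0.
#' @param pmol_per_reaction enzyme amount per reaction (pmol).
#' @param efficiency_by_peptide named numeric vector, peptide id -> Vmax/Km.
#' @return list of class `construct_profile`.
#' @export
construct_profile <- function(construct_id, km_atp_uM, vmax_app_per_pmol,
                              pmol_per_reaction, efficiency_by_peptide) {
  stopifnot(km_atp_uM > 0, vmax_app_per_pmol >= 0, pmol_per_reaction > 0,
            all(efficiency_by_peptide >= 0),
            !is.null(names(efficiency_by_peptide)))
  structure(list(construct_id = construct_id, km_atp_uM = km_atp_uM,
                 vmax_app_per_pmol = vmax_app_per_pmol,
                 pmol_per_reaction = pmol_per_reaction,
                 efficiency_by_peptide = efficiency_by_peptide),
            class = "construct_profile")
}

#' Reference profile for a construct, built from the packaged fixtures
#'
#' Combines the construct's kinetic constants with its measured catalytic
#' efficiencies over the 24-peptide custom array.
#'
#' @param construct_id one of the constructs in [load_construct_kinetics()].
#' @return a [construct_profile()].
#' @export
#' @examples
#' wt <- reference_profile("JAK2_JH1JH2_WT")
#' wt$km_atp_uM
reference_profile <- function(construct_id) {
  kin <- load_construct_kinetics()
  row <- kin[kin$construct_id == construct_id, ]
  if (nrow(row) != 1L) stop("unknown construct: ", construct_id, call. = FALSE)
  eff <- load_efficiency_ref()
  eff <- eff[eff$construct_id == construct_id, ]
  effmap <- if (nrow(eff)) stats::setNames(eff$vmax_km, eff$peptide_id) else
    stats::setNames(numeric(0), character(0))
  if (construct_id == "JAK2_K882D") {
    effmap <- stats::setNames(numeric(0), character(0))
  }
  vmax <- row$vmax_app_per_pmol
  if (is.na(vmax)) vmax <- 0
  construct_profile(construct_id, row$km_atp_uM, vmax,
                    row$pmol_per_reaction, effmap)
}

#' Screening-truth profile for a construct
#'
#' Builds a `construct_profile` whose substrates are exactly the peptides
#' called for `construct_id` in the packaged screen, all at a common
#' catalytic efficiency. Used to drive synthetic screening arrays with a
#' known answer.
#'
#' @param construct_id screen construct (`JAK2_JH1`, `JAK2_JH1JH2_WT` or
#'   `JAK2_JH1JH2_V617F`).
#' @param efficiency catalytic efficiency assigned to every called substrate.
#' @return a [construct_profile()].
#' @export
screen_profile <- function(construct_id, efficiency = 0.5) {
  truth <- load_screen_calls()
  if (!construct_id %in% names(truth$calls)) {
    stop("construct not in the screen fixture: ", construct_id, call. = FALSE)
  }
  kin <- load_construct_kinetics()
  row <- kin[kin$construct_id == construct_id, ]
  peps <- truth$calls[[construct_id]]
  construct_profile(construct_id, row$km_atp_uM, row$vmax_app_per_pmol,
                    row$pmol_per_reaction,
                    stats::setNames(rep(efficiency, length(peps)), peps))
}

#' Export a peptide library as FASTA
#'
#' Record ids are peptide ids; sequences are the spotted peptides.
#'
#' @param peptides data.frame with `peptide_id` and `sequence`
#'   (e.g. from [load_peptides()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(peptides, path) {
  stopifnot(all(c("peptide_id", "sequence") %in% names(peptides)))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::AAStringSet(stats::setNames(peptides$sequence,
                                                  peptides$peptide_id))
    Biostrings::writeXStringSet(aa, path)
  } else {
    writeLines(paste0(">", peptides$peptide_id, "\n", peptides$sequence), path)
  }
  invisible(path)
}
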