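#' Position of a peptide's central (anchor) tyrosine
#'
#' The anchor is the tyrosine closest to the sequence midpoint; ties go to
#' the N-terminal-most candidate. Multi-tyrosine peptides are common on
#' phosphosite arrays, so the rule is deterministic by construction.
#'
#' @param sequence amino-acid string.
#' @return 1-based anchor position, or `NA_integer_` when the sequence has
#'   no tyrosine.
#' @export
#' @examples
#' central_tyr_index("LAKAVDGYVKPQI")   # 8
#' central_tyr_index("GMSRDVYSTDYYR")   # 7 (Tyr at 7, 11, 12; midpoint 7)
central_tyr_index <- function(sequence) {
  pos <- which(strsplit(sequence, "")[[1]] == "Y")
  if (!length(pos)) return(NA_integer_)
  mid <- (nchar(sequence) + 1) / 2
  as.integer(pos[which.min(abs(pos - mid))])
}

#' Align peptides on their central tyrosine
#'
#' Builds the -5..+5 alignment window around each peptide's anchor
#' tyrosine. Positions falling outside a peptide are gaps (`NA`); column 0
#' is `"Y"` for every aligned peptide. Peptides without a tyrosine are
#' skipped with a warning.
#'
#' @param peptides data.frame with `peptide_id` and `sequence` (e.g. from
#'   [load_peptides()]), or a named character vector of sequences.
#' @param flank window half-width (default 5).
#' @return character matrix, rows = peptides (named by id), columns =
#'   positions `-flank..flank` (named `"-5"`.."5"), entries residue or `NA`.
#' @export
align_on_central_tyr <- function(peptides, flank = 5L) {
  if (is.character(peptides)) {
    peptides <- data.frame(peptide_id = names(peptides), sequence = peptides,
                           stringsAsFactors = FALSE)
  }
  anchors <- vapply(peptides$sequence, central_tyr_index, integer(1))
  drop <- is.na(anchors)
  if (any(drop)) {
    warning("skipping peptide(s) without Tyr: ",
            paste(peptides$peptide_id[drop], collapse = ", "))
  }
  peptides <- peptides[!drop, , drop = FALSE]
  anchors <- anchors[!drop]
  offs <- seq(-flank, flank)
  aln <- matrix(NA_character_, nrow(peptides), length(offs),
                dimnames = list(peptides$peptide_id, as.character(offs)))
  for (i in seq_len(nrow(peptides))) {
    chars <- strsplit(peptides$sequence[i], "")[[1]]
    pos <- anchors[i] + offs
    inside <- pos >= 1 & pos <= length(chars)
    aln[i, inside] <- chars[pos[inside]]
  }
  aln
}

#' Weighted substrate-motif matrix
#'
#' Per-position weighted residue frequencies and relative-entropy stack
#' heights for an alignment of substrate peptides, with weights typically
#' the percent-of-total catalytic efficiency of each peptide. At each
#' position, frequencies are normalized over the weight of peptides that
#' have a residue there (gap renormalization); the stack height is the
#' Kullback-Leibler divergence of that distribution from the uniform
#' background in bits,
#' \deqn{h_p = \log_2 20 + \sum_r f_{p,r} \log_2 f_{p,r},}
#' so a single invariant residue scores `log2(20)` (about 4.32 bits) and a
#' uniform position scores 0. The matrix is invariant to rescaling all
#' weights by a positive constant.
#'
#' @param alignment character matrix from [align_on_central_tyr()].
#' @param weights named non-negative numeric vector, peptide id -> weight;
#'   names must be a subset of the alignment rows and at least one weight
#'   must be positive.
#' @param background residue background distribution over [AA20] (default
#'   uniform 1/20).
#' @return object of class `motif_matrix`: list with `freq` (20 x positions
#'   matrix), `height` (bits per position), `letter_height` (freq x height),
#'   `effective_weight` (total non-gap weight per position), `positions`.
#' @export
weighted_motif <- function(alignment, weights,
                           background = rep(1 / 20, 20)) {
  stopifnot(is.matrix(alignment), !is.null(names(weights)))
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (all(weights == 0)) stop("all weights are zero", call. = FALSE)
  if (!all(names(weights) %in% rownames(alignment))) {
    stop("weight names must match alignment rows", call. = FALSE)
  }
  background <- stats::setNames(background / sum(background), AA20)
  aln <- alignment[names(weights), , drop = FALSE]
  npos <- ncol(aln)
  freq <- matrix(0, 20, npos, dimnames = list(AA20, colnames(aln)))
  effw <- numeric(npos)
  for (p in seq_len(npos)) {
    res <- aln[, p]
    present <- !is.na(res)
    w <- weights[present]
    effw[p] <- sum(w)
    if (effw[p] > 0) {
      tab <- tapply(w, factor(res[present], levels = AA20), sum)
      tab[is.na(tab)] <- 0
      freq[, p] <- tab / effw[p]
    }
  }
  height <- vapply(seq_len(npos), function(p) {
    if (effw[p] <= 0) return(0)
    f <- freq[, p]
    nz <- f > 0
    sum(f[nz] * (log2(f[nz]) - log2(background[nz])))
  }, numeric(1))
  names(height) <- colnames(aln)
  names(effw) <- colnames(aln)
  structure(list(freq = freq, height = height,
                 letter_height = sweep(freq, 2, height, `*`),
                 effective_weight = effw,
                 positions = as.integer(colnames(aln))),
            class = "motif_matrix")
}

#' Per-position divergence between two motifs
#'
#' Jensen-Shannon divergence (base 2, bounded in [0, 1] bits) between the
#' residue frequency columns of two motif matrices over the same position
#' range. Positions where either motif has no residue weight are `NA`.
#'
#' @param m1,m2 `motif_matrix` objects over identical positions.
#' @return named numeric vector of divergences, one per position.
#' @export
compare_motifs <- function(m1, m2) {
  stopifnot(inherits(m1, "motif_matrix"), inherits(m2, "motif_matrix"))
  if (!identical(m1$positions, m2$positions)) {
    stop("motif position ranges differ", call. = FALSE)
  }
  js <- function(p, q) {
    m <- (p + q) / 2
    kl <- function(a, b) {
      nz <- a > 0
      sum(a[nz] * (log2(a[nz]) - log2(b[nz])))
    }
    (kl(p, m) + kl(q, m)) / 2
  }
  out <- vapply(seq_along(m1$positions), function(i) {
    if (m1$effective_weight[i] <= 0 || m2$effective_weight[i] <= 0) {
      return(NA_real_)
    }
    js(m1$freq[, i], m2$freq[, i])
  }, numeric(1))
  stats::setNames(out, as.character(m1$positions))
}

#' Motif from the packaged catalytic-efficiency table
#'
#' Convenience wrapper: aligns the 24 custom-array peptides on their
#' central tyrosine and weights them by the construct's percent-of-total
#' Vmax/Km.
#'
#' @param construct_id construct column of the efficiency table to use.
#' @param eff_table efficiency table (default [load_efficiency_ref()]);
#'   must have `construct_id`, `peptide_id`, `vmax_km`.
#' @return a `motif_matrix` (see [weighted_motif()]).
#' @export
#' @examples
#' m <- efficiency_motif("JAK2_JH1")
#' m$height["0"]  # anchor Tyr: log2(20) bits
efficiency_motif <- function(construct_id, eff_table = NULL) {
  if (is.null(eff_table)) eff_table <- load_efficiency_ref()
  eff <- pct_total(eff_table)
  eff <- eff[eff$construct_id == construct_id, , drop = FALSE]
  if (!nrow(eff)) stop("no efficiencies for construct ", construct_id,
                       call. = FALSE)
  peps <- load_peptides()
  peps <- peps[peps$peptide_id %in% eff$peptide_id, , drop = FALSE]
  aln <- align_on_central_tyr(peps)
  weighted_motif(aln, stats::setNames(eff$pct_total, eff$peptide_id))
}

#' Write a motif matrix as tabular text and MEME-compatible matrix
#'
#' @param motif a `motif_matrix`.
#' @param path output path for the position x residue table (TSV with
#'   residues as rows, positions as columns, plus height and weight rows).
#' @param meme_path optional path for a MEME minimal-format probability
#'   matrix (positions as rows over the 20-letter alphabet).
#' @param name motif name used in the MEME record.
#' @return `path`, invisibly.
#' @export
write_motif <- function(motif, path, meme_path = NULL, name = "motif") {
  stopifnot(inherits(motif, "motif_matrix"))
  tab <- rbind(motif$freq,
               height_bits = motif$height,
               effective_weight = motif$effective_weight)
  utils::write.table(data.frame(row = rownames(tab), tab,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meme_path)) {
    con <- file(meme_path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "",
                 paste("ALPHABET=", paste(AA20, collapse = "")), "",
                 paste("MOTIF", name),
                 sprintf("letter-probability matrix: alength= 20 w= %d",
                         ncol(motif$freq))), con)
    for (p in seq_len(ncol(motif$freq))) {
      writeLines(paste(sprintf("%.6f", motif$freq[, p]), collapse = " "),
                 con)
    }
  }
  invisible(path)
}
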