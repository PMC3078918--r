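test_that("the central-tyrosine anchor rule is deterministic", {
  expect_equal(central_tyr_index("LAKAVDGYVKPQI"), 8L)   # unique Tyr
  expect_equal(central_tyr_index("GMSRDVYSTDYYR"), 7L)   # Tyr at 7,11,12
  expect_equal(central_tyr_index("AAAAAA"), NA_integer_)
  # tie between equidistant tyrosines goes N-terminal
  expect_equal(central_tyr_index("AAYAYAA"), 3L)
})

test_that("alignment windows are anchored with gaps outside the peptide", {
  peps <- data.frame(
    peptide_id = c("STA5A_687_699", "PP2AB_297_309"),
    sequence = c("LAKAVDGYVKPQI", "EPHVTRRTPDYFL"),
    stringsAsFactors = FALSE)
  aln <- align_on_central_tyr(peps)
  expect_equal(unname(aln["STA5A_687_699", ]),
               c("K", "A", "V", "D", "G", "Y", "V", "K", "P", "Q", "I"))
  # anchor at position 11 of a 13-mer leaves +3..+5 as gaps
  expect_equal(unname(aln["PP2AB_297_309", c("1", "2")]), c("F", "L"))
  expect_true(all(is.na(aln["PP2AB_297_309", c("3", "4", "5")])))
  expect_true(all(aln[, "0"] == "Y"))
  # tyrosine-free peptides are skipped with a warning
  bad <- rbind(peps, data.frame(peptide_id = "CTRL", sequence = "AAAAAAAAA"))
  expect_warning(aln2 <- align_on_central_tyr(bad), "CTRL")
  expect_equal(nrow(aln2), 2L)
})

test_that("single-peptide and uniform motifs hit the entropy extremes", {
  aln <- align_on_central_tyr(data.frame(peptide_id = "STA5A_687_699",
                                         sequence = "LAKAVDGYVKPQI"))
  m <- weighted_motif(aln, c(STA5A_687_699 = 1))
  expect_true(all(abs(m$height - log2(20)) < 1e-12))
  expect_equal(unname(m$freq["Y", "0"]), 1)
  # spreading one position uniformly over all 20 residues zeroes its height
  seqs <- paste0("AAAAA", "Y", AA20, "AAAA")
  names(seqs) <- paste0("P", seq_along(seqs))
  aln20 <- align_on_central_tyr(seqs)
  m20 <- weighted_motif(aln20, setNames(rep(1, 20), names(seqs)))
  expect_equal(unname(m20$height["1"]), 0, tolerance = 1e-12)
  expect_equal(unname(m20$height["0"]), log2(20), tolerance = 1e-12)
})

test_that("motif heights match an independent hand summation", {
  eff <- pct_total(load_efficiency_ref())
  eff <- eff[eff$construct_id == "JAK2_JH1", ]
  peps <- load_peptides(table2_only = TRUE)
  m <- efficiency_motif("JAK2_JH1")
  # anchor column is invariant
  expect_equal(unname(m$freq["Y", "0"]), 1)
  expect_equal(unname(m$height["0"]), log2(20))
  # spreadsheet-style recomputation of position +1
  w <- setNames(eff$pct_total, eff$peptide_id)
  counts <- setNames(numeric(20), AA20)
  total <- 0
  for (i in seq_len(nrow(peps))) {
    seq <- peps$sequence[i]
    anchor <- central_tyr_index(seq)
    pos <- anchor + 1L
    if (pos <= nchar(seq)) {
      r <- substr(seq, pos, pos)
      counts[r] <- counts[r] + w[peps$peptide_id[i]]
      total <- total + w[peps$peptide_id[i]]
    }
  }
  f <- counts / total
  h <- log2(20) + sum(f[f > 0] * log2(f[f > 0]))
  expect_equal(unname(m$freq[, "1"]), unname(f), tolerance = 1e-9)
  expect_equal(unname(m$height["1"]), h, tolerance = 1e-9)
})

test_that("motifs are invariant to weight scale and zero-weight rows", {
  aln <- align_on_central_tyr(load_peptides(table2_only = TRUE))
  eff <- pct_total(load_efficiency_ref())
  eff <- eff[eff$construct_id == "JAK2_JH1JH2_WT", ]
  w <- setNames(eff$pct_total, eff$peptide_id)
  m1 <- weighted_motif(aln, w)
  m2 <- weighted_motif(aln, w * 1337)
  expect_equal(m1$freq, m2$freq)
  expect_equal(m1$height, m2$height)
  # adding a zero-weight peptide changes nothing
  w0 <- c(w, DUMMY = 0)
  aln0 <- rbind(aln, DUMMY = aln[1, ])
  m3 <- weighted_motif(aln0, w0)
  expect_equal(m3$freq, m1$freq)
  expect_error(weighted_motif(aln, w * 0), "all weights")
  expect_error(weighted_motif(aln, setNames(1, "NOT_THERE")),
               "match alignment rows")
})

test_that("motif divergence is a bounded symmetric comparison", {
  aln <- align_on_central_tyr(c(A = "AAAAAYAAAAA", B = "CCCCCYCCCCC"))
  mA <- weighted_motif(aln, c(A = 1))
  mB <- weighted_motif(aln, c(B = 1))
  expect_true(all(compare_motifs(mA, mA) == 0))
  js <- compare_motifs(mA, mB)
  expect_equal(unname(js["0"]), 0)           # both anchored on Tyr
  expect_equal(unname(js["1"]), 1)           # disjoint point distributions
  expect_true(all(js >= 0 & js <= 1))
  expect_equal(compare_motifs(mA, mB), compare_motifs(mB, mA))

  # construct comparison: V617F resembles wild type more than JAK3 does
  mWT <- efficiency_motif("JAK2_JH1JH2_WT")
  mVF <- efficiency_motif("JAK2_JH1JH2_V617F")
  mJ3 <- efficiency_motif("JAK3_JH1")
  expect_lt(max(compare_motifs(mWT, mVF), na.rm = TRUE),
            max(compare_motifs(mWT, mJ3), na.rm = TRUE))
})

test_that("motif export writes tabular and MEME-compatible files", {
  m <- efficiency_motif("JAK2_JH1")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  meme <- withr::local_tempfile(fileext = ".meme")
  write_motif(m, tmp, meme_path = meme, name = "JAK2_JH1")
  tab <- read.delim(tmp, check.names = FALSE)
  expect_equal(nrow(tab), 22L)  # 20 residues + height + weight rows
  lines <- readLines(meme)
  expect_true(any(grepl("^MOTIF JAK2_JH1", lines)))
  probs <- strsplit(trimws(lines[grep("letter-probability", lines) + 1L]),
                    " +")[[1]]
  expect_equal(sum(as.numeric(probs)), 1, tolerance = 1e-4)
})
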