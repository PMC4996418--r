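# Column profiles, pattern construction, class-specific columns and
# discriminative refinement.

test_that("column profiles count residues, gaps and conservation", {
  msa <- ProteinMsa(c(a = "ACDE", b = "ACDE", c = "ACDE", d = "ACDE"))
  prof <- buildProfile(msa)
  expect_equal(unname(prof$conservation), rep(1, 4))

  msa <- ProteinMsa(c(r1 = "AS", r2 = "AG"))
  prof <- buildProfile(msa)
  expect_equal(prof$counts["A", 1], 2)
  expect_equal(prof$counts["S", 2], 1)
  expect_equal(prof$counts["G", 2], 1)
  expect_equal(unname(prof$conservation), c(1, 0.5))

  # 33-row group with a 30 V / 3 E column
  rows <- c(rep("V", 30), rep("E", 3))
  msa <- ProteinMsa(stats::setNames(rows, paste0("s", 1:33)))
  prof <- buildProfile(msa)
  expect_equal(prof$freqs["V", 1], 30 / 33, tolerance = 1e-12)
  expect_equal(prof$freqs["E", 1], 3 / 33, tolerance = 1e-12)
  # frequencies over residues + gap sum to one per column
  expect_equal(unname(colSums(prof$freqs)), 1)

  expect_error(buildProfile(msa, rowSubset = character(0)), "empty")
  expect_error(buildProfile(msa, colRange = c(1, 2)), "range")
})

test_that("profileToPattern builds literals, ordered sets and wildcards", {
  rows <- stats::setNames(rep("SSSPVSPADDSLSNSEEE", 4), paste0("m", 1:4))
  p <- profileToPattern(buildProfile(ProteinMsa(rows)))
  expect_equal(prositeText(p),
               "S-S-S-P-V-S-P-A-D-D-S-L-S-N-S-E-E-E")

  # frequency tie broken by first appearance top-to-bottom
  p <- profileToPattern(buildProfile(ProteinMsa(c(r1 = "SA", r2 = "SG"))))
  expect_equal(prositeText(p), "S-[AG]")
  p <- profileToPattern(buildProfile(ProteinMsa(c(r1 = "SG", r2 = "SA"))))
  expect_equal(prositeText(p), "S-[GA]")

  # five distinct residues exceed the default set size: wildcard
  msa <- ProteinMsa(stats::setNames(c("S", "G", "N", "R", "A"),
                                    paste0("s", 1:5)))
  p <- profileToPattern(buildProfile(msa))
  expect_equal(prositeText(p), "x")

  # gap handling
  gapped <- ProteinMsa(c(a = "A-C", b = "AGC"))
  expect_error(profileToPattern(buildProfile(gapped), gapPolicy = "forbid"),
               "column 2")
  p <- profileToPattern(buildProfile(gapped), gapPolicy = "skip-column")
  expect_equal(prositeText(p), "A-C")
})

test_that("patterns from profiles match every training row (completeness)", {
  set.seed(77)
  for (trial in 1:20) {
    n <- sample(3:8, 1); L <- sample(4:12, 1)
    rows <- vapply(seq_len(n), function(i) randomSeq(L), "")
    names(rows) <- paste0("s", seq_len(n))
    p <- profileToPattern(buildProfile(ProteinMsa(rows)))
    expect_true(all(vapply(rows, function(r)
      matchesProsite(p, r), logical(1))))
  }
})

test_that("class-specific columns are found in the aligned motif pair", {
  msa <- ProteinMsa(c(t1 = "SSSPVSPADDSLSNSEEE",
                      t2 = "SSSPVSPVD-SLGTSEEE"))
  cl <- findClassSpecificColumns(msa, list(A = "t1", B = "t2"))
  expect_equal(which(cl == "class-specific"), c(8L, 13L, 14L))
  expect_equal(which(cl == "gapped"), 10L)
  expect_equal(cl[1:7], rep("conserved", 7), ignore_attr = TRUE)

  same <- ProteinMsa(c(a = "ACDE", b = "ACDE", c = "ACDE", d = "ACDE"))
  cl <- findClassSpecificColumns(same, list(g1 = c("a", "b"),
                                            g2 = c("c", "d")))
  expect_equal(unname(cl), rep("conserved", 4))

  planted <- ProteinMsa(c(a1 = "ANA", a2 = "ANA", a3 = "ANA",
                          b1 = "ATA", b2 = "ATA", b3 = "ATA"))
  cl <- findClassSpecificColumns(planted,
                                 list(A = paste0("a", 1:3),
                                      B = paste0("b", 1:3)))
  expect_equal(unname(cl), c("conserved", "class-specific", "conserved"))

  expect_error(findClassSpecificColumns(planted, list(A = "a1")),
               "groups")
  expect_error(findClassSpecificColumns(planted,
                                        list(A = paste0("a", 1:3),
                                             B = c("a1", "b1"))),
               "groups")
})

test_that("refinement trims to an end-trim-minimal discriminative core", {
  # every one-element end-trim admits a negative: pattern unchanged
  p <- refineDiscriminativeMotif("A-C-D-E",
                                 positives = c("ACDE", "XACDEX"),
                                 negatives = c("ACDQ", "QCDE"))
  expect_equal(prositeText(p), "A-C-D-E")

  # with the single negative ACDQ, exhaustive end-trim enumeration shows
  # the literal E alone already discriminates (ACDQ contains no E), so
  # trimming runs all the way down to it
  p <- refineDiscriminativeMotif("A-C-D-E",
                                 positives = c("ACDE", "XACDEX"),
                                 negatives = c("ACDQ"))
  expect_equal(prositeText(p), "E")

  # the two printed mammalian motifs: hand enumeration of all end-trims
  # of the combined pattern shows D-D already separates them (it is the
  # shortest run absent from the group-B motif), so alternating
  # end-trimming reaches exactly that fixed point
  combined <- "[GSA]-[SGNR]-[SC]-P-[GVEA]-S-P-[VA]-D-D-S-[LVA]-[VGS]-[TN]-S-E-[EG]-E"
  tc <- twistConstants()
  ref <- refineDiscriminativeMotif(combined, positives = c(tc$t1_motif),
                                   negatives = c(tc$t2_motif))
  expect_equal(prositeText(ref), "D-D")
  # minimality re-checked independently: refined is discriminative, and
  # neither one-element end-trim is
  expect_true(isDiscriminative(ref, c(tc$t1_motif), c(tc$t2_motif)))
  if (patternLength(ref) > 1L) {
    expect_false(isDiscriminative(trimPattern(ref, from = 1L),
                                  c(tc$t1_motif), c(tc$t2_motif)))
    expect_false(isDiscriminative(trimPattern(ref, to = 1L),
                                  c(tc$t1_motif), c(tc$t2_motif)))
  }

  expect_error(refineDiscriminativeMotif("A-C", positives = c("AC"),
                                         negatives = c("AC")),
               "not discriminative at start")
})

test_that("refinement output stays discriminative on random corpora", {
  set.seed(99)
  done <- 0L
  while (done < 10L) {
    core <- randomSeq(6)
    pos <- paste0(vapply(1:4, function(i) randomSeq(5), ""), core,
                  vapply(1:4, function(i) randomSeq(5), ""))
    neg <- vapply(1:4, function(i) randomSeq(16), "")
    start <- parseProsite(paste(strsplit(core, "")[[1]], collapse = "-"))
    if (!isDiscriminative(start, pos, neg)) next
    done <- done + 1L
    ref <- refineDiscriminativeMotif(start, pos, neg)
    expect_true(isDiscriminative(ref, pos, neg))
    if (patternLength(ref) > 1L) {
      expect_false(isDiscriminative(trimPattern(ref, from = 1L), pos, neg))
      expect_false(isDiscriminative(trimPattern(ref, to = 1L), pos, neg))
    }
  }
})
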