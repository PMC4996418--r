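# Paralog classification, glycine-rich regions and curation.

test_that("signatures classify the packaged peptides", {
  tc <- twistConstants()
  r1 <- classifyParalog(c(tw1 = tc$t1_peptide), tc)
  expect_equal(r1$label, "group-A")
  expect_equal(r1$evidence$outcome[r1$evidence$rule == "signature_A"],
               "TRUE")
  r2 <- classifyParalog(c(tw2 = tc$t2_peptide), tc)
  expect_equal(r2$label, "group-B")
  # all rules are always evaluated and recorded
  expect_setequal(r1$evidence$rule,
                  c("signature_A", "signature_B", "key_residue",
                    "length", "glycine_regions"))
})

test_that("key residue and length fallbacks engage in order", {
  tc <- twistConstants()
  # sub-motif present, no full signature: the first [TN]SE[EG]E residue
  # decides
  expect_equal(classifyParalog("AAAANSEEEAAAA", tc)$label, "group-A")
  expect_equal(classifyParalog("AAAATSEEEAAAA", tc)$label, "group-B")
  # degenerate homopolymer: too short for the length heuristic
  expect_equal(classifyParalog("AAAAAAAA", tc)$label, "unclassified")
  set.seed(8)
  noMotif <- function(n) gsub("[NTSE]", "A", randomSeq(n))
  expect_equal(classifyParalog(noMotif(190), tc)$label, "group-A")
  expect_equal(classifyParalog(noMotif(150), tc)$label, "group-B")
  expect_equal(classifyParalog(noMotif(178), tc)$label, "unclassified")
})

test_that("classification is deterministic and order-invariant", {
  fam <- smallFamily()$fam
  recs <- as.character(familyRecords(fam))
  a <- classifyParalogs(recs)
  b <- classifyParalogs(rev(recs))
  expect_equal(stats::setNames(a$label, a$seq_id),
               stats::setNames(b$label, b$seq_id)[a$seq_id])
})

test_that("glycine regions are detected, merged and subtyped", {
  g <- detectGlycineRegions("GGAGAGGAGA")
  expect_equal(nrow(g), 1L)
  expect_equal(g$subtype, "G-A")
  expect_equal(g$g_fraction, 0.6)
  g <- detectGlycineRegions("GSGGSGSGGS")
  expect_equal(g$subtype, "G-S")
  expect_equal(nrow(detectGlycineRegions("ACDEFHIKLM")), 0L)
  # removing every glycine removes every region
  s <- "MMQGGGSGGGSAAAGGAGGAGAAA"
  expect_gt(nrow(detectGlycineRegions(s)), 0L)
  expect_equal(nrow(detectGlycineRegions(gsub("G", "K", s))), 0L)
  # regions are sorted and non-overlapping
  s2 <- paste0("GGSSGGSSGG", strrep("ACDEFHIKLM", 3), "GGAAGGAAGG")
  g <- detectGlycineRegions(s2)
  expect_equal(g$start, sort(g$start))
  if (nrow(g) > 1L)
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  # the search zone is N-terminal only
  far <- paste0(strrep("ACDEFHIKLM", 12), "GGGGGGGGGG")
  expect_equal(nrow(detectGlycineRegions(far)), 0L)
  expect_error(detectGlycineRegions("GGGG", window = 2), "window")
})

test_that("curation keeps by core and overall identity with reasons", {
  set.seed(13)
  ref <- randomSeq(200)
  core <- c(80L, 140L)
  # substitute every third core residue: the optimal local block still
  # spans the core but its identity drops to ~67%, well under 89%
  ch <- strsplit(ref, "")[[1]]
  hitCore <- seq(core[1], core[2], by = 3)
  ch[hitCore] <- vapply(ch[hitCore], function(r) setdiff(AA20, r)[1], "")
  scrambled <- paste(ch, collapse = "")
  # substitute every other residue outside the core: core identity stays
  # 100% but overall identity falls to ~65%
  ch <- strsplit(ref, "")[[1]]
  outside <- setdiff(seq_len(200), core[1]:core[2])
  flip <- outside[seq_along(outside) %% 2 == 1]
  ch[flip] <- vapply(ch[flip], function(r) setdiff(AA20, r)[1], "")
  noisy <- paste(ch, collapse = "")
  res <- curateCandidates(c(same = ref, scr = scrambled, noisy = noisy),
                          ref, core)
  expect_true(res$kept[res$seq_id == "same"])
  expect_equal(res$core_pct[res$seq_id == "same"], 100)
  expect_false(res$kept[res$seq_id == "scr"])
  expect_match(res$reason[res$seq_id == "scr"], "core identity")
  expect_false(res$kept[res$seq_id == "noisy"])
  expect_match(res$reason[res$seq_id == "noisy"], "overall identity")
  expect_gte(res$core_pct[res$seq_id == "noisy"], 89)
  # empty candidate list is an empty result, not an error
  expect_equal(nrow(curateCandidates(character(0), ref, core)), 0L)
})
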