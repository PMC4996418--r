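# The synthetic two-paralog family simulator.

test_that("simulation is deterministic and sized by the duplication", {
  cfg <- simulationConfig(seed = 42)
  f1 <- simulateFamily(cfg)
  f2 <- simulateFamily(cfg)
  expect_identical(as.character(familyRecords(f1)),
                   as.character(familyRecords(f2)))
  # duplication at the root: every species carries both paralogs
  lab <- familyLabels(f1)
  expect_length(lab, 24L)
  expect_equal(sum(lab == "group-A"), 12L)
  expect_equal(sum(lab == "group-B"), 12L)
  expect_equal(sort(familyTree(f1)$tip.label), sort(names(lab)))
})

test_that("the zero-rate limit isolates the planted differences", {
  cfg <- simulationConfig(rates = c(core = 0, motif = 0, disordered = 0),
                          seed = 9)
  fam <- simulateFamily(cfg)
  recs <- as.character(familyRecords(fam))
  lab <- familyLabels(fam)
  truth <- familyTruth(fam)
  bSeqs <- recs[names(lab)[lab == "group-B"]]
  # all group-B records equal the root sequence
  expect_length(unique(unname(bSeqs)), 1L)
  root <- bSeqs[[1]]
  keyPos <- truth$per_record[["B_fish1"]]$key_pos
  for (id in names(lab)[lab == "group-A"]) {
    a <- recs[[id]]
    regions <- truth$per_record[[id]]$regions
    # strip planted insertions (right to left to keep coordinates valid)
    if (nrow(regions)) {
      for (k in order(regions$start, decreasing = TRUE))
        a <- paste0(substr(a, 1, regions$start[k] - 1),
                    substr(a, regions$end[k] + 1, nchar(a)))
    }
    ch_a <- strsplit(a, "")[[1]]
    ch_r <- strsplit(root, "")[[1]]
    diff <- which(ch_a != ch_r)
    expect_equal(diff, keyPos)
    expect_equal(ch_a[keyPos], "N")
    expect_equal(ch_r[keyPos], "T")
  }
  # insertion staging: group-B never has regions; group-A events nest
  for (id in names(lab)[lab == "group-B"])
    expect_equal(nrow(truth$per_record[[id]]$regions), 0L)
  gs <- vapply(names(lab)[lab == "group-A"], function(id)
    "G-S" %in% truth$per_record[[id]]$regions$subtype, logical(1))
  ga <- vapply(names(lab)[lab == "group-A"], function(id)
    "G-A" %in% truth$per_record[[id]]$regions$subtype, logical(1))
  expect_setequal(names(gs)[gs],
                  paste0("A_", c("reptile1", "reptile2", "bird1", "bird2",
                                 "mammal1", "mammal2", "mammal3")))
  expect_setequal(names(ga)[ga], paste0("A_", c("mammal1", "mammal2",
                                                "mammal3")))
  # the later G-A insertion sits N-terminal of the earlier G-S region
  r <- truth$per_record[["A_mammal1"]]$regions
  expect_lt(r$start[r$subtype == "G-A"], r$start[r$subtype == "G-S"])
})

test_that("evolveSequence follows the per-site Poisson model", {
  set.seed(2)
  parent <- randomSeq(50)
  expect_identical(evolveSequence(parent, 0, 0.15), parent)
  # immutable sites never change even at extreme rates
  imm <- rep(c(TRUE, FALSE), 25)
  child <- evolveSequence(parent, 50, 5, immutable = imm)
  expect_identical(strsplit(child, "")[[1]][imm],
                   strsplit(parent, "")[[1]][imm])
  # changed-site fraction near the Poisson no-hit probability
  set.seed(6)
  parent <- randomSeq(1000)
  child <- evolveSequence(parent, 10, 0.15)
  frac <- mean(strsplit(child, "")[[1]] != strsplit(parent, "")[[1]])
  p <- 1 - exp(-1.5)
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(frac - p), 3 * se)
  expect_error(evolveSequence(parent, -1, 0.1), ">= 0")
})

test_that("planted glycine regions are detectable where planted", {
  fam <- smallFamily()$fam
  recs <- as.character(familyRecords(fam))
  truth <- familyTruth(fam)
  lab <- familyLabels(fam)
  for (id in names(recs)) {
    planted <- truth$per_record[[id]]$regions
    found <- detectGlycineRegions(recs[[id]])
    gsPlanted <- planted[planted$subtype == "G-S", , drop = FALSE]
    overlaps <- function(f, p)
      any(f$start <= p$end & f$end >= p$start & f$subtype == p$subtype)
    if (nrow(gsPlanted)) {
      expect_true(overlaps(found, gsPlanted),
                  label = paste("G-S region found in", id))
    } else if (lab[[id]] == "group-B") {
      # no planted region: nothing detected at the planted G-S locus
      expect_false(nrow(found) > 0 &&
                     overlaps(found, data.frame(start = 50, end = 59,
                                                subtype = "G-S")))
    }
  }
})
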