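# Trimming, distances, NJ + bootstrap, classical MDS, evolutionary trace.

test_that("trimming removes gappy and explicitly listed columns", {
  clean <- ProteinMsa(c(a = "ACDE", b = "ACDE"))
  r <- trimAlignment(clean)
  expect_equal(msaNcol(r$msa), 4L)
  expect_length(r$removed, 0L)

  rows <- c(paste0("AC", "DE"), paste0("A-", "DE"))
  rows <- vapply(1:10, function(i)
    paste0("A", if (i <= 5) "-" else "C", "DE"), "")
  names(rows) <- paste0("s", 1:10)
  msa <- ProteinMsa(rows)
  r <- trimAlignment(msa, maxGapFraction = 0.4)
  expect_equal(r$removed, 2L)  # gap fraction 0.5 > 0.4
  expect_equal(msaNcol(r$msa), 3L)
  # threshold 1.0 keeps everything that is not all-gap
  expect_length(trimAlignment(msa, maxGapFraction = 1.0)$removed, 0L)
  # explicit ranges removed regardless
  r <- trimAlignment(clean, dropRanges = list(c(1, 2)))
  expect_equal(r$removed, c(1L, 2L))
  expect_error(trimAlignment(clean, dropRanges = list(c(1, 4))),
               "every column")
})

test_that("distances mask gaps and normalize similarity", {
  same <- ProteinMsa(c(a = "ACDE", b = "ACDE"))
  expect_equal(msaDistance(same, "p-distance")["a", "b"], 0)
  expect_equal(msaDistance(same, "matrix-normalized")["a", "b"], 0)

  d <- msaDistance(ProteinMsa(c(a = "ACDE", b = "ACDA")), "p-distance")
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d, t(d))

  # compared columns are only those ungapped in both rows
  d <- msaDistance(ProteinMsa(c(a = "AC-E", b = "ACD-")), "p-distance")
  expect_equal(d["a", "b"], 0)
  expect_error(msaDistance(ProteinMsa(c(a = "AC--", b = "--DE"))),
               "no ungapped columns")
})

test_that("NJ solves the 3-taxon case and recovers additive trees", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  bl <- stats::setNames(tr$edge.length,
                        c(tr$tip.label, rep(NA, tr$Nnode))[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 2)

  # hand-computed additive matrix of ((A:1,B:2):1,(C:3,D:4):1)
  lab <- c("A", "B", "C", "D")
  d4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, dimnames = list(lab, lab))
  tr4 <- njTree(d4)
  expect_true(hasBipartition(tr4, c("A", "B")))
  expect_equal(unname(ape::cophenetic.phylo(tr4)[lab, lab]), unname(d4),
               tolerance = 1e-9)

  # a zero-distance pair must come out as siblings
  lab5 <- c("X", "Y", "Z", "W")
  d5 <- matrix(c(0, 0, 4, 5,
                 0, 0, 4, 5,
                 4, 4, 0, 3,
                 5, 5, 3, 0), 4, dimnames = list(lab5, lab5))
  expect_true(hasBipartition(njTree(d5), c("X", "Y")))
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("bootstrap support is seeded, bounded and saturates", {
  # 30 columns, every one separating AB|CD
  rows <- c(A = strrep("A", 30), B = strrep("A", 30),
            C = strrep("C", 30), D = strrep("C", 30))
  # add a little within-pair signal so branch lengths differ
  substr(rows[["B"]], 1, 2) <- "GG"
  substr(rows[["D"]], 1, 2) <- "KK"
  msa <- ProteinMsa(rows)
  tr <- bootstrapSupport(msa, replicates = 50, seed = 4)
  sup <- as.integer(tr$node.label)
  expect_equal(max(sup, na.rm = TRUE), 100L)
  expect_true(hasBipartition(tr, c("A", "B")))
  # one replicate: supports are 0 or 100 by definition
  tr1 <- bootstrapSupport(msa, replicates = 1, seed = 4)
  expect_true(all(as.integer(tr1$node.label) %in% c(0L, 100L)))
  # same seed, same supports
  tr2 <- bootstrapSupport(msa, replicates = 25, seed = 7)
  tr3 <- bootstrapSupport(msa, replicates = 25, seed = 7)
  expect_identical(tr2$node.label, tr3$node.label)
})

test_that("classical MDS reproduces Euclidean geometry", {
  lab <- c("p", "q")
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(lab, lab))
  e <- classicalMds(d, k = 2)
  expect_equal(sort(mdsPoints(e)[, 1]), c(-1, 1), ignore_attr = TRUE)
  expect_equal(mdsEigenvalues(e), c(2, 0), tolerance = 1e-12)

  # 3-4-5 right triangle: embedded distances equal the input
  lab <- c("a", "b", "c")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(lab, lab))
  e <- classicalMds(d, k = 3)
  expect_equal(unname(as.matrix(stats::dist(mdsPoints(e)))), unname(d),
               tolerance = 1e-9)
  # column means are zero and explained fractions sum to 1
  expect_equal(max(abs(colMeans(mdsPoints(e)))), 0, tolerance = 1e-9)
  expect_equal(sum(e@explained), 1, tolerance = 1e-12)

  # all-zero distances: every coordinate is zero
  z <- matrix(0, 3, 3, dimnames = list(lab, lab))
  ez <- classicalMds(z)
  expect_true(all(mdsPoints(ez) == 0))
})

test_that("MDS agrees with the stats reference implementation", {
  set.seed(31)
  for (trial in 1:5) {
    n <- sample(5:10, 1)
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(stats::dist(pts))
    dimnames(d) <- list(paste0("p", 1:n), paste0("p", 1:n))
    mine <- classicalMds(d, k = 3)
    ref <- stats::cmdscale(d, k = 3, eig = TRUE)
    expect_equal(unname(as.matrix(stats::dist(mdsPoints(mine)))),
                 unname(as.matrix(stats::dist(ref$points))),
                 tolerance = 1e-8)
    expect_equal(mdsEigenvalues(mine)[1:3], ref$eig[1:3],
                 tolerance = 1e-8)
  }
})

test_that("evolutionary trace classifies columns by partition level", {
  tree <- readNewick(
    "((a1:1,(a2:1,a3:1):1):1,(b1:1,(b2:1,b3:1):1):1);")
  msa <- ProteinMsa(c(a1 = "ANCA", a2 = "ANCA", a3 = "ANCC",
                      b1 = "ATCA", b2 = "ATCA", b3 = "ATCC"))
  tr <- evolutionaryTrace(msa, tree, levels = 3)
  expect_equal(traceClasses(tr, 1)[2], "unconserved", ignore_attr = TRUE)
  expect_equal(sum(traceClasses(tr, 1) == "class-specific"), 0L)
  cl2 <- traceClasses(tr, 2)
  expect_equal(unname(cl2), c("conserved", "class-specific", "conserved",
                              "unconserved"))
  expect_equal(lengths(traceGroups(tr, 2)), c(g1 = 3L, g2 = 3L))

  # identical rows: conserved at every level
  same <- ProteinMsa(stats::setNames(rep("ACDE", 6),
                                     c(paste0("a", 1:3), paste0("b", 1:3))))
  tr <- evolutionaryTrace(same, tree, levels = 4)
  for (p in 1:4)
    expect_true(all(traceClasses(tr, p) == "conserved"))

  # conserved at level 1 implies conserved at every deeper level
  set.seed(17)
  rows <- vapply(1:6, function(i) randomSeq(12), "")
  names(rows) <- c(paste0("a", 1:3), paste0("b", 1:3))
  msa <- ProteinMsa(rows)
  tr <- evolutionaryTrace(msa, tree, levels = 5)
  consAt1 <- traceClasses(tr, 1) == "conserved"
  for (p in 2:length(tr@levels))
    expect_true(all(traceClasses(tr, p)[consAt1] == "conserved"))

  expect_error(evolutionaryTrace(msa, ape::unroot(tree)), "rooted")
  expect_error(
    evolutionaryTrace(ProteinMsa(rows[1:3]), tree), "differ")
})
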