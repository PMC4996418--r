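# Shared fixtures and independent oracles.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

randomSeq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent PROSITE oracle: translate the pattern to a PCRE and find
# every overlapping match start with a lookahead. Semantics mirror the
# matcher's contract ('X' in the sequence matches only wildcards) but
# the route is entirely regex-based.
prositeToRegex <- function(pattern) {
  one <- function(e) {
    switch(e$type,
           literal  = e$residues,
           set      = paste0("[", paste(e$residues, collapse = ""), "]"),
           excluded = paste0("[^", paste(e$residues, collapse = ""), "X]"),
           wildcard = {
             core <- "[A-Z]"
             if (e$min == 1 && e$max == 1) core
             else sprintf("%s{%d,%d}", core, e$min, e$max)
           })
  }
  paste(vapply(pattern@elements, one, ""), collapse = "")
}

oracleStarts <- function(pattern, seq) {
  rx <- paste0("(?=", prositeToRegex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

randomPattern <- function(maxLen = 6L) {
  k <- sample(1:maxLen, 1)
  elems <- lapply(seq_len(k), function(i) {
    switch(sample(4, 1),
           twistmotif:::.literal(sample(AA20, 1)),
           twistmotif:::.altset(sample(AA20, sample(2:4, 1))),
           twistmotif:::.exclset(sample(AA20, sample(1:3, 1))),
           { n <- sample(0:2, 1); twistmotif:::.wild(n, n + sample(0:2, 1)) })
  })
  p <- new("PrositePattern", elements = elems, sourceText = "")
  p@sourceText <- prositeText(p)
  p
}

# Exhaustive end-trim oracle for refinement: a pattern is end-trim
# minimal iff it is discriminative and no single-end removal is.
isDiscriminative <- function(pattern, positives, negatives) {
  all(vapply(positives, function(s) matchesProsite(pattern, s), logical(1))) &&
    !any(vapply(negatives, function(s) matchesProsite(pattern, s), logical(1)))
}

smallFamily <- function(seed = 42) {
  # cached per test run: simulating + aligning the default family is the
  # expensive part of the recovery checks
  if (is.null(.family_cache$fam)) {
    .family_cache$fam <- simulateFamily(simulationConfig(seed = seed))
    .family_cache$msa <- progressiveMsa(familyRecords(.family_cache$fam))
  }
  list(fam = .family_cache$fam, msa = .family_cache$msa)
}
.family_cache <- new.env()

# offset of the refined pattern's elements inside the original pattern
# (serialized element comparison); NA when not a contiguous sub-run
refinementOffset <- function(original, refined) {
  otxt <- vapply(original@elements, function(e)
    prositeText(new("PrositePattern", elements = list(e),
                    sourceText = "")), "")
  rtxt <- vapply(refined@elements, function(e)
    prositeText(new("PrositePattern", elements = list(e),
                    sourceText = "")), "")
  nr <- length(rtxt)
  for (off in 0:(length(otxt) - nr)) {
    if (identical(otxt[(off + 1):(off + nr)], rtxt)) return(off)
  }
  NA_integer_
}
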