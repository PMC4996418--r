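---
title: "Signature motifs and paralog classification in the Twist family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature motifs and paralog classification in the Twist family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twistmotif)
```

## The problem

Twist1 and Twist2 are paralogous bHLH transcription factors born from a
gene duplication early in vertebrate evolution. Outside the
well-characterised bHLH domain their N-termini are intrinsically
disordered and fast-evolving, yet they carry a short, strictly conserved
motif (`SSSPVSPADDSLSNSEEE` in mammalian Twist1, `SSSPVSPVDSLGTSEEE` in
mammalian Twist2). Database annotations of the two paralogs are
frequently wrong because the traditional discriminator — the presence of
two glycine-rich regions in Twist1 — fails for early-branching lineages
that never acquired them. This package implements the comparative
workflow that turns grouped multiple alignments of such a two-paralog
family into *signature motifs*: minimal PROSITE-format patterns that
match one paralog group and reject the other, anchored on a single
class-specific **key residue** (asparagine in Twist1-like, threonine in
Twist2-like sequences, the position immediately preceding the acidic
`SEEE` block).

## The procedure

1. **Column profiles to patterns.** For a group of aligned sequences,
   each column becomes a pattern element: one observed residue gives a
   literal, up to `maxSetSize` (default 4) residues give an alternative
   set ordered by descending frequency (ties broken by first appearance
   top-to-bottom), more give a wildcard. With `minFreq = 0` the pattern
   is complete: it matches every ungapped training row.
2. **Discriminative refinement.** Starting from a pattern that matches
   all positives and no negatives, `refineDiscriminativeMotif()`
   repeatedly attempts to remove the first element, then the last; a
   removal is kept only if discrimination survives. The fixed point is
   *end-trim minimal*: removing either extreme element breaks it. The
   result depends on the positive/negative corpus — on the two printed
   mammalian motifs alone the minimal core is just `D-D` (the shortest
   run absent from the Twist2 motif), while on a full family the core
   retains the key N/T column, because unmutated negatives match every
   non-key column of the positives' profile.
3. **Classification.** `classifyParalog()` applies, in order: the two
   signature motifs (exactly one match decides); the key residue of the
   first `[TN]-S-E-[EG]-E` hit; a length heuristic (≥ 185 aa group-A,
   ≤ 170 aa group-B, engaged only for sequences of ≥ 140 aa so fragments
   are never length-classified). Glycine-rich regions are recorded as
   evidence but never decide, since early Twist1 lineages lack them.
4. **Kinase scanning.** Serine/threonine consensus rules (GSK3
   `pS-X-X-X-pS-P`, BARK `X-E-X-pS-X-X`, LKB1 `X-L-X-pT-X-X`, CK2
   `pS/T-X-D/E-D/E/pS-D/E`) are matched window-wise; the full window
   must lie inside the sequence and the reported position is the
   designated phospho element (for GSK3's primed consensus, the
   N-terminal serine). A `pS` in a non-reported position simply permits
   serine — phosphorylation state is not modelled.
5. **Evolutionary analyses.** Gap-masked p-distances or
   similarity-normalised distances (`1 - s(a,b)/sqrt(s(a,a) s(b,b))`),
   neighbor-joining trees with column-bootstrap support, classical
   metric MDS of sequence space, and evolutionary-trace classing of
   columns (conserved / class-specific / unconserved / gapped) across
   nested tree partitions obtained by opening internal nodes in order of
   their height above the root.

## Parameters that matter

* **Alignment scoring** — BLOSUM62 with gap open 11 / extend 1 (a gap of
  length *k* costs 11 + *k*), the protein-BLAST defaults; identity is
  identities over alignment columns, so values may differ by about one
  percentage point from servers that apply compositional adjustment.
* **Glycine regions** — window 10, glycine fraction ≥ 0.4, searched in
  the N-terminal 110 residues. The thresholds are this package's own
  operationalisation of "glycine-rich": they detect both human Twist1
  regions while leaving mammalian Twist2 N-termini empty. Subtype is the
  dominant non-glycine residue (A → `G-A`, S → `G-S`, ties → `other`).
* **Curation** — candidates are kept when local-alignment identity to
  the reference bHLH-like core is ≥ 89% and overall identity is > 75%.
* **Trimming** — columns with gap fraction > 0.4 are removed; explicit
  column ranges (e.g. the glycine insertions) can be dropped regardless.
  This replaces slope-based trimming heuristics with a single
  transparent threshold chosen so that insertion columns present in only
  one paralog group of a combined alignment are removed.
* **Trees** — neighbor-joining plus bootstrap is used throughout instead
  of maximum likelihood: it is exact on additive distances, fast enough
  to bootstrap thousands of replicates, and sufficient for the
  topology-level claims made here (the group-A/group-B bipartition and
  outgroup placement). Negative NJ branch estimates are clamped to zero
  with a message.
* **MDS** — coordinates come only from positive eigenvalues of the
  doubly centred matrix, scaled by the square root of the eigenvalue;
  per-axis sign is fixed by making the first nonzero loading positive.
  An all-zero distance matrix embeds every point at the origin; a
  centred matrix with no positive eigenvalue raises an error. All
  retained components are exported — the choice of which axes to plot is
  left to the user.

## The simulator

`simulateFamily()` provides ground truth so every stage is testable
without downloads. Defaults (all chosen up front, see
`simulationConfig()`):

* a 12-tip pectinate species tree tiered fish → amphibian → reptile →
  bird → mammal, every edge 0.25 expected-substitution units. The depth
  is calibrated so that the slow core (rate 0.02/site/unit) keeps ~90%
  identity across the family, matching the ≥ 89% bHLH identity used for
  curation; the disordered flanks (rate 0.15) then diverge to roughly
  half identity between the deepest tips, as real Twist N-termini do.
* duplication at the root: all 12 species carry both paralogs
  (24 records). The group-A copy receives the single T→N key-column
  swap at its birth; the key column itself is immutable thereafter, so
  its divergence is exactly the planted event.
* the motif occupies positions 5–21 (the Twist2 mammalian template), so
  the key residue lands at sequence position 17 — the same coordinate
  reported for the human Twist2 peptide.
* two atomic insertions on the group-A lineage: `GGSGGGSSGG` (G-S) on
  the branch to the reptile-to-mammal clade at position 50, and
  `GGAGGGAGGG` (G-A) later, on the branch to the mammals at position 30
  (N-terminal of the earlier region, shifting its coordinates, which the
  truth tracks). Inserted regions subsequently evolve at the slow core
  rate, mirroring their conservation once acquired.
* substitutions follow a per-site Poisson count with uniform replacement
  over the other 19 residues. This deliberately ignores empirical
  exchangeabilities: recovery of planted structure, not realism of the
  substitution process, is what the tests need. Residue composition is
  uniform, so the background glycine frequency (5%) is below real
  disordered-region composition.

What passing recovery tests do **not** show: performance on real
databases with fragmentary sequences, non-uniform composition, indels
outside the planted events, or more than two paralog groups.

## Numerical and design choices

* Pattern matching is element-wise; an `X` in a sequence matches only
  wildcards, never literals, sets or exclusions, and B/Z/U/O are
  rejected on input — ambiguity never silently satisfies a pattern.
  At most one hit is reported per start position (the shortest, for
  variable wildcards).
* Bracket-set ordering in generated patterns is frequency-descending
  with first-appearance tie-breaks; comparisons between patterns should
  compare sets, not orderings.
* Profile merging in `progressiveMsa()` scores column pairs by the
  frequency-weighted substitution score and breaks traceback ties
  diagonal-first; it is a self-test aligner, not a production one.
* Pipeline stages write one artifact each (11 on a default run without
  curation) and log one line to stderr; identical inputs and seed
  reproduce every artifact byte-identically.
* Problem sizes in the shipped tests: the default 24-record family for
  recovery checks, 10,000 random pattern/sequence pairs for the
  matcher/oracle equivalence, 200 random trees (5–12 leaves) for NJ
  exactness, 200 random 3-D point sets for MDS round-trips, and 10–50
  bootstrap replicates in pipeline tests (the default for analyses
  remains 1000).

## Known limitations

* The refinement's stopping rule is defined against caller-supplied
  labelled sets; the original database-composition stopping criterion is
  out of scope, so refined cores on small corpora can be shorter than
  the published signature motifs (see step 2 above).
* `percentIdentity()` reproduces BLASTP-style identities but not its
  compositional adjustment or E-values.
* Maximum-likelihood trees, disorder/structure prediction, and remote
  database scans are intentionally absent.
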