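## End-to-end orchestration: curation (optional) -> alignment ->
## group profiles & motifs -> discriminative refinement ->
## classification -> kinase scan -> glycine regions -> trimming ->
## distances -> NJ + bootstrap -> MDS -> evolutionary trace. Every stage
## writes one artifact and logs one machine-readable line to stderr.
## Re-running with the same inputs and seed reproduces all artifacts.

.stageLog <- function(stage, detail, t0) {
  message(sprintf("stage=%s %s elapsed=%.2fs", stage, detail,
                  as.numeric(proc.time()[3L]) - t0))
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full comparative-analysis pipeline
#'
#' @param sequences named \code{AAStringSet}, named character vector, or
#'   a FASTA path; ungapped protein sequences.
#' @param alignment optional precomputed \code{\linkS4class{ProteinMsa}}
#'   (or aligned-FASTA path); when absent, \code{\link{progressiveMsa}}
#'   is used.
#' @param groups optional named list \code{list("group-A"=, "group-B"=)}
#'   of sequence ids; when absent, groups are taken from
#'   \code{\link{classifyParalogs}} labels.
#' @param reference,coreRange optional curation reference sequence and
#'   its core interval; curation runs only when both are given.
#' @param motifColumns optional 1-based alignment column interval of the
#'   N-terminal motif; when absent it is auto-located as a window of
#'   up to 8 columns on both sides of the first class-specific column.
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the bootstrap stage.
#' @param bootstrapReplicates bootstrap replicate count (default 1000).
#' @param maxGapFraction trimming threshold (default 0.4).
#' @param dropRanges explicit alignment columns to trim, e.g. the
#'   glycine-rich insertions.
#' @param outgroup optional tip id used to root the tree for the trace
#'   stage; default is the first group-B sequence.
#' @param traceLevels partition levels for the trace (default 10).
#' @param constants packaged constants, see \code{\link{twistConstants}}.
#' @return invisibly, a list with the stage artifacts (file paths) and
#'   the main in-memory results.
#' @export
runPipeline <- function(sequences, alignment = NULL, groups = NULL,
                        reference = NULL, coreRange = NULL,
                        motifColumns = NULL, outDir, seed = 1L,
                        bootstrapReplicates = 1000L,
                        maxGapFraction = 0.4, dropRanges = NULL,
                        outgroup = NULL, traceLevels = 10L,
                        constants = twistConstants()) {
  t0 <- as.numeric(proc.time()[3L])
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences))) {
    if (!file.exists(sequences))
      stop("no such input file: ", sequences, call. = FALSE)
    sequences <- readProteins(sequences, "fasta")
  }
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences need unique names", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  art <- function(name) {
    p <- file.path(outDir, name)
    artifacts <<- c(artifacts, p)
    p
  }

  if (!is.null(reference) && !is.null(coreRange)) {
    cur <- curateCandidates(sequences, reference, coreRange)
    .writeTsv(cur, art("curation.tsv"))
    sequences <- sequences[cur$seq_id[cur$kept]]
    .stageLog("curate", sprintf("kept=%d rejected=%d",
                                sum(cur$kept), sum(!cur$kept)), t0)
  }

  if (is.null(alignment)) {
    msa <- progressiveMsa(sequences)
    .stageLog("align", sprintf("rows=%d cols=%d method=progressive",
                               msaNrow(msa), msaNcol(msa)), t0)
  } else {
    msa <- if (is.character(alignment))
      readProteins(alignment, "aligned_fasta") else alignment
    .stageLog("align", "loaded", t0)
  }
  writeProteinsFasta(msa, art("alignment.fasta"))

  cls <- classifyParalogs(sequences, constants)
  if (is.null(groups)) {
    groups <- split(cls$seq_id, cls$label)
    groups <- groups[intersect(c("group-A", "group-B"), names(groups))]
    if (length(groups) < 2L)
      stop("classification produced fewer than 2 groups; supply 'groups'",
           call. = FALSE)
  }

  colClasses <- findClassSpecificColumns(
    msaSubset(msa, unlist(groups, use.names = FALSE)), groups)
  if (is.null(motifColumns)) {
    cs <- which(colClasses == "class-specific")
    if (!length(cs))
      stop("no class-specific column found; supply 'motifColumns'",
           call. = FALSE)
    motifColumns <- c(max(1L, cs[1L] - 8L),
                      min(msaNcol(msa), cs[1L] + 8L))
  }
  patterns <- lapply(names(groups), function(g) {
    prof <- buildProfile(msa, rowSubset = groups[[g]],
                         colRange = motifColumns)
    profileToPattern(prof, gapPolicy = "skip-column")
  })
  names(patterns) <- names(groups)
  writeLines(sprintf("%s\t%s", names(patterns),
                     vapply(patterns, prositeText, "")),
             art("motifs.txt"))
  .stageLog("motifs", sprintf("columns=%d-%d groups=%d",
                              motifColumns[1L], motifColumns[2L],
                              length(groups)), t0)

  signatures <- lapply(names(groups), function(g) {
    pos <- sequences[groups[[g]]]
    neg <- sequences[unlist(groups[names(groups) != g], use.names = FALSE)]
    refineDiscriminativeMotif(patterns[[g]], pos, neg)
  })
  names(signatures) <- names(groups)
  writeLines(sprintf("%s\t%s", names(signatures),
                     vapply(signatures, prositeText, "")),
             art("signatures.txt"))
  .stageLog("refine", paste(vapply(signatures, patternLength, 0L),
                            collapse = "/"), t0)

  .writeTsv(cls, art("classification.tsv"))
  .stageLog("classify", sprintf("n=%d", nrow(cls)), t0)

  kin <- do.call(rbind, lapply(names(sequences), function(id)
    scanKinaseSites(sequences[[id]], constants$kinase_rules, id = id)))
  .writeTsv(kin, art("phosphosites.tsv"))
  .stageLog("kinase", sprintf("sites=%d", nrow(kin)), t0)

  gly <- do.call(rbind, lapply(names(sequences), function(id) {
    g <- detectGlycineRegions(sequences[[id]])
    if (nrow(g)) cbind(seq_id = id, g) else NULL
  }))
  if (is.null(gly))
    gly <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), g_fraction = numeric(0),
                      subtype = character(0))
  .writeTsv(gly, art("glycine_regions.tsv"))
  .stageLog("glycine", sprintf("regions=%d", nrow(gly)), t0)

  trimmed <- trimAlignment(msa, maxGapFraction, dropRanges)
  writeProteinsFasta(trimmed$msa, art("trimmed.fasta"))
  .stageLog("trim", sprintf("removed=%d", length(trimmed$removed)), t0)

  d <- msaDistance(trimmed$msa, "p-distance")
  .writeTsv(data.frame(id = rownames(d), d, check.names = FALSE),
            art("distances.tsv"))
  .stageLog("distance", "method=p-distance", t0)

  tree <- bootstrapSupport(trimmed$msa, replicates = bootstrapReplicates,
                           seed = seed)
  writeLines(writeNewick(tree), art("tree.nwk"))
  .stageLog("tree", sprintf("replicates=%d", bootstrapReplicates), t0)

  mds <- classicalMds(d, k = 3L)
  .writeTsv(data.frame(id = mds@labels, mdsPoints(mds),
                       check.names = FALSE), art("mds.tsv"))
  .stageLog("mds", sprintf("components=%d", ncol(mdsPoints(mds))), t0)

  if (is.null(outgroup)) outgroup <- groups[["group-B"]][1L]
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  trace <- evolutionaryTrace(trimmed$msa, rooted, levels = traceLevels)
  traceTab <- do.call(rbind, lapply(seq_along(trace@levels), function(p)
    data.frame(level = p, column = seq_along(traceClasses(trace, p)),
               class = traceClasses(trace, p))))
  .writeTsv(traceTab, art("trace.tsv"))
  .stageLog("trace", sprintf("levels=%d", length(trace@levels)), t0)

  invisible(list(artifacts = artifacts, msa = msa, groups = groups,
                 patterns = patterns, signatures = signatures,
                 classification = cls, tree = tree, distances = d,
                 mds = mds, trace = trace))
}
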