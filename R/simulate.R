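## Seeded simulator of a Twist-like two-paralog family: a species tree,
## a duplication giving birth to the group-A (Twist1-like) lineage, a
## slow bHLH-like core, a very slow N-terminal motif carrying one
## immutable class-specific column (T in group-B, swapped to N at the
## duplication for group-A), fast disordered flanks, and staged
## glycine-rich insertions on the group-A lineage (the G-S region on an
## earlier branch, the G-A region on a later branch).

.defaultSpeciesTree <- function() {
  tips <- c("fish1", "fish2", "fish3", "amphibian1", "amphibian2",
            "reptile1", "reptile2", "bird1", "bird2",
            "mammal1", "mammal2", "mammal3")
  bl <- 0.25
  nwk <- sprintf("(mammal2:%g,mammal3:%g)", bl, bl)
  for (t in rev(tips[1:10]))
    nwk <- sprintf("(%s:%g,%s:%g)", t, bl, nwk, bl)
  paste0(nwk, ";")
}

#' Simulation configuration for a two-paralog family
#'
#' The defaults emulate the study conditions: a 12-tip pectinate species
#' tree tiered fish to mammal (every edge 0.25 expected-substitution
#' units, calibrated so the slow core stays ~90\% identical across the
#' family), duplication at the root (so all 12 species carry both
#' paralogs), site-class substitution rates 0.02 (core) / 0.005 (motif)
#' / 0.15 (disordered) per unit branch length, the group-B mammalian
#' motif as the root motif with the key column (T, motif column 13)
#' immutable and swapped to N on the group-A copy, and two staged
#' glycine insertions on the group-A lineage: the G-S region
#' ("GGSGGGSSGG", sequence position 50) on the branch to the
#' reptile-to-mammal clade, and the G-A region ("GGAGGGAGGG", position
#' 30) later, on the branch to the mammals. Inserted regions evolve at
#' the slow core rate thereafter (they are conserved once acquired).
#'
#' @param speciesTree Newick string.
#' @param duplicationTips tips whose MRCA is the duplication node;
#'   \code{NULL} means the root.
#' @param rates named vector with \code{core}, \code{motif},
#'   \code{disordered} substitution rates.
#' @param motifTemplate the root (group-B-like) motif string.
#' @param keyColumn class-specific column within the motif (immutable).
#' @param motifStart 1-based position of the motif in the root sequence.
#' @param coreRange 1-based interval of the slow core.
#' @param insertionEvents list of events, each
#'   \code{list(tips=, region=, position=, subtype=)}; the event fires
#'   on the branch leading to the MRCA of \code{tips} in the group-A
#'   copy.
#' @param rootLength root sequence length.
#' @param duplicationEdge branch length of the two edges hanging off the
#'   duplication node.
#' @param seed integer RNG seed.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(speciesTree = .defaultSpeciesTree(),
                             duplicationTips = NULL,
                             rates = c(core = 0.02, motif = 0.005,
                                       disordered = 0.15),
                             motifTemplate = "SSSPVSPVDSLGTSEEE",
                             keyColumn = 13L,
                             motifStart = 5L,
                             coreRange = c(80L, 135L),
                             insertionEvents = list(
                               list(tips = c("reptile1", "mammal3"),
                                    region = "GGSGGGSSGG",
                                    position = 50L, subtype = "G-S"),
                               list(tips = c("mammal1", "mammal3"),
                                    region = "GGAGGGAGGG",
                                    position = 30L, subtype = "G-A")),
                             rootLength = 160L,
                             duplicationEdge = 0.25,
                             seed = 1L) {
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (keyColumn < 1L || keyColumn > nchar(motifTemplate))
    stop("keyColumn outside the motif", call. = FALSE)
  if (motifStart + nchar(motifTemplate) - 1L > rootLength)
    stop("motif does not fit in the root sequence", call. = FALSE)
  structure(list(speciesTree = speciesTree,
                 duplicationTips = duplicationTips, rates = rates,
                 motifTemplate = motifTemplate, keyColumn = keyColumn,
                 motifStart = motifStart, coreRange = coreRange,
                 insertionEvents = insertionEvents,
                 rootLength = rootLength,
                 duplicationEdge = duplicationEdge, seed = seed),
            class = "SimulationConfig")
}

#' Evolve a sequence along a branch
#'
#' Per site, the substitution count is Poisson(rate x branch length);
#' each substitution replaces the residue by a uniformly chosen
#' different canonical residue. Immutable sites never change. Uses the
#' current RNG state.
#'
#' @param parent residue string (or character vector of residues).
#' @param branchLength branch length >= 0.
#' @param siteRates per-site substitution rates (recycled if length 1).
#' @param immutable logical per-site mask of frozen sites.
#' @return the child residue string.
#' @export
evolveSequence <- function(parent, branchLength, siteRates,
                           immutable = NULL) {
  if (branchLength < 0) stop("branch length must be >= 0", call. = FALSE)
  chars <- if (length(parent) == 1L) strsplit(parent, "")[[1]] else parent
  n <- length(chars)
  siteRates <- rep_len(siteRates, n)
  if (is.null(immutable)) immutable <- rep(FALSE, n)
  k <- stats::rpois(n, siteRates * branchLength)
  k[immutable] <- 0L
  for (i in which(k > 0L)) {
    for (s in seq_len(k[i])) {
      alt <- AA_CANONICAL[AA_CANONICAL != chars[i]]
      chars[i] <- alt[sample.int(length(alt), 1L)]
    }
  }
  paste(chars, collapse = "")
}

# internal node state: seq (char vector), rate (numeric per site),
# immutable (logical), coords (motif_start, key_pos), regions
# (data.frame start, end, subtype)
.applyInsertion <- function(state, region, position, subtype, coreRate) {
  reg <- strsplit(region, "")[[1]]
  L <- length(reg)
  p <- min(position, length(state$seq) + 1L)
  before <- seq_len(p - 1L)
  after <- if (p <= length(state$seq)) p:length(state$seq) else integer(0)
  state$seq <- c(state$seq[before], reg, state$seq[after])
  state$rate <- c(state$rate[before], rep(coreRate, L), state$rate[after])
  state$immutable <- c(state$immutable[before], rep(FALSE, L),
                       state$immutable[after])
  shift <- function(x) ifelse(x >= p, x + L, x)
  state$coords <- lapply(state$coords, shift)
  if (nrow(state$regions)) {
    state$regions$start <- shift(state$regions$start)
    state$regions$end <- shift(state$regions$end)
  }
  state$regions <- rbind(state$regions,
                         data.frame(start = p, end = p + L - 1L,
                                    subtype = subtype,
                                    stringsAsFactors = FALSE))
  state
}

#' Simulate a two-paralog protein family with ground truth
#'
#' Builds the gene tree (species tree with the subtree below the
#' duplication node duplicated into a group-A and a group-B copy; group-B
#' also covers species outside the duplicated clade), draws a root
#' sequence from uniform residue frequencies except at the motif
#' (set to the group-B template with the immutable key column), evolves
#' it down the tree with per-site-class Poisson substitutions, applies
#' the key-column swap on the group-A copy at the duplication and the
#' configured insertion events on group-A branches, and returns records,
#' the true gene tree and planted truth. Identical seeds give identical
#' output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \code{\linkS4class{SimulatedFamily}}.
#' @examples
#' fam <- simulateFamily(simulationConfig(seed = 42))
#' fam
#' @export
simulateFamily <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  sp <- readNewick(config$speciesTree)
  if (is.null(sp$edge.length))
    stop("species tree needs branch lengths", call. = FALSE)
  nsp <- length(sp$tip.label)
  dupNode <- if (is.null(config$duplicationTips)) nsp + 1L
    else ape::getMRCA(sp, config$duplicationTips)
  kids <- .childrenList(sp)
  dupTips <- .tipsBelow(sp, dupNode, kids)

  # gene-tree Newick: the subtree below the duplication node appears
  # twice (an A_ and a B_ copy); all other species carry a B_ gene only
  edgeLen <- function(node) sp$edge.length[which(sp$edge[, 2L] == node)]
  subNwk <- function(node, prefix) {
    if (node <= nsp) return(paste0(prefix, sp$tip.label[node]))
    paste0("(", paste(vapply(kids[[node]], function(ch)
      paste0(subNwk(ch, prefix), ":", edgeLen(ch)), ""),
      collapse = ","), ")")
  }
  dupPair <- paste0("(", subNwk(dupNode, "A_"), ":",
                    config$duplicationEdge, ",",
                    subNwk(dupNode, "B_"), ":",
                    config$duplicationEdge, ")")
  geneSub <- function(node) {
    if (node == dupNode) return(dupPair)
    if (node <= nsp) return(paste0("B_", sp$tip.label[node]))
    paste0("(", paste(vapply(kids[[node]], function(ch)
      paste0(geneSub(ch), ":", edgeLen(ch)), ""),
      collapse = ","), ")")
  }
  gene <- readNewick(paste0(geneSub(nsp + 1L), ";"))

  set.seed(config$seed)
  L <- config$rootLength
  tmpl <- strsplit(config$motifTemplate, "")[[1]]
  motifSpan <- config$motifStart:(config$motifStart + length(tmpl) - 1L)
  keyPos <- config$motifStart + config$keyColumn - 1L
  rootSeq <- AA_CANONICAL[sample.int(20L, L, replace = TRUE)]
  rootSeq[motifSpan] <- tmpl
  rate <- rep(config$rates[["disordered"]], L)
  rate[config$coreRange[1L]:config$coreRange[2L]] <- config$rates[["core"]]
  rate[motifSpan] <- config$rates[["motif"]]
  immutable <- rep(FALSE, L)
  immutable[keyPos] <- TRUE
  rootState <- list(seq = rootSeq, rate = rate, immutable = immutable,
                    coords = list(motif_start = config$motifStart,
                                  motif_end = max(motifSpan),
                                  key_pos = keyPos),
                    regions = data.frame(start = integer(0),
                                         end = integer(0),
                                         subtype = character(0),
                                         stringsAsFactors = FALSE))

  ng <- length(gene$tip.label)
  gkids <- .childrenList(gene)
  # event node = MRCA of the prefixed tips in the gene tree
  eventNode <- vapply(config$insertionEvents, function(ev) {
    tips <- paste0("A_", ev$tips)
    tips <- tips[tips %in% gene$tip.label]
    if (length(tips) < 1L) return(NA_integer_)
    if (length(tips) == 1L) return(match(tips, gene$tip.label))
    ape::getMRCA(gene, tips)
  }, integer(1))
  aCopyRoot <- {
    aTips <- paste0("A_", dupTips)
    if (length(aTips) == 1L) match(aTips, gene$tip.label)
    else ape::getMRCA(gene, aTips)
  }

  tipStates <- vector("list", ng)
  recurse <- function(node, state) {
    for (ch in gkids[[node]]) {
      bl <- gene$edge.length[which(gene$edge[, 2L] == ch)]
      st <- state
      if (ch == aCopyRoot) {
        st$seq[st$coords$key_pos] <- "N"   # birth of the group-A lineage
      }
      st$seq <- strsplit(evolveSequence(st$seq, bl, st$rate,
                                        st$immutable), "")[[1]]
      for (k in which(!is.na(eventNode) & eventNode == ch)) {
        ev <- config$insertionEvents[[k]]
        st <- .applyInsertion(st, ev$region, ev$position, ev$subtype,
                              config$rates[["core"]])
      }
      if (ch <= ng) tipStates[[ch]] <<- st
      else recurse(ch, st)
    }
  }
  root <- ng + 1L
  st0 <- rootState
  if (root == aCopyRoot) st0$seq[st0$coords$key_pos] <- "N"
  recurse(root, st0)

  ids <- gene$tip.label
  seqs <- vapply(tipStates, function(s) paste(s$seq, collapse = ""), "")
  records <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  lab <- ifelse(startsWith(ids, "A_"), "group-A", "group-B")
  S4Vectors::mcols(records) <- S4Vectors::DataFrame(
    paralog_label = lab, species = sub("^[AB]_", "", ids))
  truth <- list(
    per_record = stats::setNames(lapply(tipStates, function(s)
      list(motif_start = s$coords$motif_start,
           motif_end = s$coords$motif_end,
           key_pos = s$coords$key_pos,
           regions = s$regions)), ids),
    key_column = config$keyColumn,
    key_residues = c("group-A" = "N", "group-B" = "T"),
    duplication_tips = dupTips)
  new("SimulatedFamily", records = records, tree = gene, truth = truth)
}

#' Accessors for simulated families
#'
#' @param fam a \code{\linkS4class{SimulatedFamily}}.
#' @return \code{familyRecords}: the \code{AAStringSet} (metadata
#'   columns \code{paralog_label}, \code{species}); \code{familyTree}:
#'   the true gene tree; \code{familyTruth}: the planted ground truth;
#'   \code{familyLabels}: named label vector.
#' @export
familyRecords <- function(fam) fam@records

#' @rdname familyRecords
#' @export
familyTree <- function(fam) fam@tree

#' @rdname familyRecords
#' @export
familyTruth <- function(fam) fam@truth

#' @rdname familyRecords
#' @export
familyLabels <- function(fam) {
  stats::setNames(S4Vectors::mcols(fam@records)$paralog_label,
                  names(fam@records))
}
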