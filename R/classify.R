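## Paralog classification by signature motif / key residue / length,
## glycine-rich region detection with G-A vs G-S subtyping, and the
## bHLH-core + overall-identity curation filter.

#' Detect N-terminal glycine-rich regions
#'
#' Sliding windows with glycine fraction >= \code{gThreshold} are merged
#' into maximal regions; each region is re-scored over its full span and
#' subtyped by its most frequent non-glycine residue (A-dominant =
#' \code{"G-A"}, S-dominant = \code{"G-S"}, anything else or a tie =
#' \code{"other"}).
#'
#' @param seq sequence (character or \code{AAString}).
#' @param window window width (>= 3; default 10).
#' @param gThreshold minimum glycine fraction in a window (default 0.4).
#' @param regionLimit 1-based end of the N-terminal search zone; default
#'   \code{min(length, 110)}.
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{g_fraction}, \code{subtype}; zero rows when nothing is found.
#' @examples
#' detectGlycineRegions("GGAGAGGAGA")
#' @export
detectGlycineRegions <- function(seq, window = 10L, gThreshold = 0.4,
                                 regionLimit = NULL) {
  if (window < 3L) stop("window must be >= 3", call. = FALSE)
  s <- .seqString(seq)
  n <- nchar(s)
  if (is.null(regionLimit)) regionLimit <- min(n, 110L)
  zone <- strsplit(substr(s, 1L, regionLimit), "")[[1]]
  nz <- length(zone)
  empty <- data.frame(start = integer(0), end = integer(0),
                      g_fraction = numeric(0), subtype = character(0),
                      stringsAsFactors = FALSE)
  if (nz < window) return(empty)
  isG <- as.integer(zone == "G")
  csum <- c(0L, cumsum(isG))
  starts <- seq_len(nz - window + 1L)
  frac <- (csum[starts + window] - csum[starts]) / window
  hit <- starts[frac >= gThreshold]
  if (!length(hit)) return(empty)
  # merge overlapping/adjacent window spans into maximal regions
  spans <- cbind(hit, hit + window - 1L)
  regions <- list()
  cur <- spans[1L, ]
  for (i in seq_len(nrow(spans))[-1L]) {
    if (spans[i, 1L] <= cur[2L] + 1L) {
      cur[2L] <- max(cur[2L], spans[i, 2L])
    } else {
      regions <- c(regions, list(cur))
      cur <- spans[i, ]
    }
  }
  regions <- c(regions, list(cur))
  out <- do.call(rbind, lapply(regions, function(r) {
    res <- zone[r[1L]:r[2L]]
    gf <- mean(res == "G")
    nonG <- res[res != "G"]
    subtype <- "other"
    if (length(nonG)) {
      tab <- sort(table(nonG), decreasing = TRUE)
      top <- names(tab)[tab == tab[1L]]
      if (length(top) == 1L && top == "A") subtype <- "G-A"
      if (length(top) == 1L && top == "S") subtype <- "G-S"
    }
    data.frame(start = r[1L], end = r[2L], g_fraction = gf,
               subtype = subtype, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify a sequence into the two paralog classes
#'
#' Decision procedure, in order: (1) scan both signature motifs; if
#' exactly one matches, that class wins. (2) Otherwise scan the shared
#' [TN]-S-E-[EG]-E sub-motif; the first residue of its first hit calls
#' the class (N = group-A / Twist1-like, T = group-B / Twist2-like).
#' (3) Otherwise, for sequences of at least \code{lengthMin} residues, a
#' length heuristic: >= \code{lengthBounds[2]} is group-A, <=
#' \code{lengthBounds[1]} is group-B. (4) Otherwise unclassified.
#' Glycine-rich regions are reported as evidence only and are never
#' decisive (their presence or absence does not discriminate the early
#' lineages).
#'
#' @param seq sequence (character or \code{AAString}); name used as id.
#' @param constants packaged constants from \code{\link{twistConstants}}.
#' @param lengthBounds \code{c(low, high)} length thresholds (defaults
#'   170 and 185, interpolating the typical ~160 aa group-B and ~200 aa
#'   group-A lengths).
#' @param lengthMin minimum length for the length heuristic to engage
#'   (default 140; fragments are never classified by length).
#' @param id id override.
#' @return a list of class \code{"ClassificationResult"} with
#'   \code{seq_id}, \code{label} (\code{"group-A"}, \code{"group-B"} or
#'   \code{"unclassified"}) and \code{evidence} (data.frame of rule name
#'   and outcome, all rules always evaluated).
#' @export
classifyParalog <- function(seq, constants = twistConstants(),
                            lengthBounds = c(170L, 185L),
                            lengthMin = 140L, id = NULL) {
  if (is.null(id))
    id <- if (!is.null(names(seq)) && nzchar(names(seq)[1L]))
      names(seq)[1L] else "seq"
  s <- .seqString(seq)
  n <- nchar(s)
  sigA <- matchesProsite(constants$t1_signature, s)
  sigB <- matchesProsite(constants$t2_signature, s)
  keyHits <- scanProsite(constants$submotif2, s, mode = "all")
  keyRes <- if (nrow(keyHits)) substr(keyHits$matched_text[1L], 1L, 1L)
            else NA_character_
  if (nrow(keyHits) > 1L)
    warning(sprintf("%s: multiple [TN]-S-E-[EG]-E hits; using the first",
                    id), call. = FALSE)
  glyc <- detectGlycineRegions(s)
  label <- "unclassified"
  if (xor(sigA, sigB)) {
    label <- if (sigA) "group-A" else "group-B"
  } else if (!is.na(keyRes) && keyRes %in% c("N", "T")) {
    label <- if (keyRes == "N") "group-A" else "group-B"
  } else if (n >= lengthMin) {
    if (n >= lengthBounds[2L]) label <- "group-A"
    else if (n <= lengthBounds[1L]) label <- "group-B"
  }
  glycTxt <- if (nrow(glyc))
    paste(sprintf("%d-%d:%s", glyc$start, glyc$end, glyc$subtype),
          collapse = ";") else "none"
  evidence <- data.frame(
    rule = c("signature_A", "signature_B", "key_residue", "length",
             "glycine_regions"),
    outcome = c(as.character(sigA), as.character(sigB),
                ifelse(is.na(keyRes), "none", keyRes),
                as.character(n), glycTxt),
    stringsAsFactors = FALSE)
  structure(list(seq_id = id, label = label, evidence = evidence,
                 glycine_regions = glyc),
            class = "ClassificationResult")
}

#' @export
print.ClassificationResult <- function(x, ...) {
  cat(sprintf("%s -> %s\n", x$seq_id, x$label))
  for (i in seq_len(nrow(x$evidence)))
    cat(sprintf("  %-16s %s\n", x$evidence$rule[i], x$evidence$outcome[i]))
  invisible(x)
}

#' Classify a set of sequences
#'
#' @param seqs named \code{AAStringSet} or named character vector.
#' @inheritParams classifyParalog
#' @return data.frame with one row per sequence: \code{seq_id},
#'   \code{label}, \code{signature_A}, \code{signature_B},
#'   \code{key_residue}, \code{length}, \code{glycine_regions}.
#' @export
classifyParalogs <- function(seqs, constants = twistConstants(),
                             lengthBounds = c(170L, 185L),
                             lengthMin = 140L) {
  if (is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    r <- classifyParalog(seqs[[i]], constants, lengthBounds, lengthMin,
                         id = names(seqs)[i])
    ev <- stats::setNames(r$evidence$outcome, r$evidence$rule)
    data.frame(seq_id = r$seq_id, label = r$label,
               signature_A = ev[["signature_A"]],
               signature_B = ev[["signature_B"]],
               key_residue = ev[["key_residue"]],
               length = as.integer(ev[["length"]]),
               glycine_regions = ev[["glycine_regions"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Curate candidate sequences against a reference
#'
#' A candidate is kept iff its local-alignment identity against the
#' reference core (e.g. the bHLH-like domain) is at least
#' \code{coreMinPct} and its overall local-alignment identity against
#' the full reference exceeds \code{overallMinPct}. Every rejection
#' carries the failing criterion and the measured value.
#'
#' @param candidates named \code{AAStringSet} or named character vector
#'   (may be empty).
#' @param reference single reference sequence.
#' @param coreRange 1-based inclusive interval of the core on the
#'   reference.
#' @param coreMinPct core identity threshold (default 89).
#' @param overallMinPct overall identity threshold (default 75).
#' @param scoring a \code{\link{scoringScheme}}.
#' @return data.frame with \code{seq_id}, \code{core_pct},
#'   \code{overall_pct}, \code{kept}, \code{reason}.
#' @export
curateCandidates <- function(candidates, reference, coreRange,
                             coreMinPct = 89, overallMinPct = 75,
                             scoring = scoringScheme()) {
  if (is(candidates, "AAStringSet")) candidates <- as.character(candidates)
  ref <- .seqString(reference)
  if (coreRange[1L] < 1L || coreRange[2L] > nchar(ref) ||
      coreRange[1L] > coreRange[2L])
    stop("core range outside the reference", call. = FALSE)
  core <- substr(ref, coreRange[1L], coreRange[2L])
  empty <- data.frame(seq_id = character(0), core_pct = numeric(0),
                      overall_pct = numeric(0), kept = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (!length(candidates)) return(empty)
  rows <- lapply(seq_along(candidates), function(i) {
    id <- names(candidates)[i]
    cpct <- percentIdentity(candidates[[i]], core, "local",
                            scoring)$identity_pct
    opct <- percentIdentity(candidates[[i]], ref, "local",
                            scoring)$identity_pct
    cpct <- ifelse(is.na(cpct), 0, cpct)
    opct <- ifelse(is.na(opct), 0, opct)
    kept <- cpct >= coreMinPct && opct > overallMinPct
    reason <- if (kept) "kept"
      else if (cpct < coreMinPct)
        sprintf("core identity %.1f%% < %.1f%%", cpct, coreMinPct)
      else sprintf("overall identity %.1f%% <= %.1f%%", opct, overallMinPct)
    data.frame(seq_id = if (is.null(id)) as.character(i) else id,
               core_pct = cpct, overall_pct = opct, kept = kept,
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
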