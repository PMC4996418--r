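## Column profiles over alignment groups, profile -> PROSITE pattern
## construction, class-specific column finding, and the discriminative
## end-trimming refinement that produces signature motifs.

#' Column profile of an alignment (or sub-alignment)
#'
#' Counts residues and gaps per column over a chosen row subset and
#' column range. Column conservation is the maximum residue frequency
#' (gaps excluded from the maximum but reported).
#'
#' @param msa a \code{\linkS4class{ProteinMsa}}.
#' @param rowSubset optional vector of row ids.
#' @param colRange optional 1-based inclusive column interval
#'   \code{c(from, to)}.
#' @return an object of class \code{"ColumnProfile"}: a list with
#'   \code{counts} (residues+gap x columns), \code{freqs},
#'   \code{conservation}, \code{columns} (original column indices),
#'   \code{nrows} and \code{rows} (the raw character sub-matrix, used
#'   for tie-breaking in \code{\link{profileToPattern}}).
#' @export
buildProfile <- function(msa, rowSubset = NULL, colRange = NULL) {
  stopifnot(is(msa, "ProteinMsa"))
  m <- msaMatrix(msa)
  if (!is.null(rowSubset)) {
    if (!length(rowSubset)) stop("empty row subset", call. = FALSE)
    miss <- setdiff(rowSubset, rownames(m))
    if (length(miss))
      stop("unknown row ids: ", paste(miss, collapse = ", "),
           call. = FALSE)
    m <- m[rowSubset, , drop = FALSE]
  }
  cols <- seq_len(ncol(m))
  if (!is.null(colRange)) {
    if (colRange[1L] < 1L || colRange[2L] > ncol(m) ||
        colRange[1L] > colRange[2L])
      stop("column range outside the alignment", call. = FALSE)
    cols <- seq.int(colRange[1L], colRange[2L])
    m <- m[, cols, drop = FALSE]
  }
  levels <- c(AA_LEGAL, "-")
  counts <- apply(m, 2, function(col)
    tabulate(factor(col, levels = levels), nbins = length(levels)))
  dimnames(counts) <- list(levels, as.character(cols))
  freqs <- counts / nrow(m)
  resFreqs <- freqs[AA_LEGAL, , drop = FALSE]
  structure(list(counts = counts, freqs = freqs,
                 conservation = apply(resFreqs, 2, max),
                 columns = cols, nrows = nrow(m), rows = m),
            class = "ColumnProfile")
}

#' @export
print.ColumnProfile <- function(x, ...) {
  cat(sprintf("ColumnProfile: %d columns over %d rows\n",
              length(x$columns), x$nrows))
  invisible(x)
}

#' Build a PROSITE pattern from a column profile
#'
#' Per column: a single observed residue becomes a literal; 2 to
#' \code{maxSetSize} residues become an alternative set ordered by
#' descending frequency (ties broken by first appearance top-to-bottom
#' in the profile's row order); more residues become a wildcard. With
#' \code{minFreq = 0} the resulting pattern is guaranteed to match every
#' ungapped input row restricted to the profile's columns.
#'
#' @param profile a \code{\link{buildProfile}} result.
#' @param maxSetSize largest alternative set before collapsing to a
#'   wildcard (default 4).
#' @param minFreq residues at frequency <= \code{minFreq} are ignored
#'   (default 0, i.e. keep everything observed).
#' @param gapPolicy \code{"forbid"} (error on a gapped column) or
#'   \code{"skip-column"} (drop gapped columns).
#' @return a \code{\linkS4class{PrositePattern}}.
#' @export
profileToPattern <- function(profile, maxSetSize = 4L, minFreq = 0,
                             gapPolicy = c("forbid", "skip-column")) {
  gapPolicy <- match.arg(gapPolicy)
  stopifnot(inherits(profile, "ColumnProfile"))
  m <- profile$rows
  elems <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-")) {
      if (gapPolicy == "forbid")
        stop(sprintf("gap in alignment column %d under gap policy 'forbid'",
                     profile$columns[j]), call. = FALSE)
      next
    }
    freq <- profile$freqs[AA_LEGAL, j]
    res <- names(freq)[freq > minFreq]
    if (!length(res))
      stop(sprintf("no residue above minFreq in column %d",
                   profile$columns[j]), call. = FALSE)
    firstSeen <- vapply(res, function(r) match(r, col), integer(1))
    res <- res[order(-freq[res], firstSeen)]
    el <- if (length(res) == 1L) .literal(res)
          else if (length(res) <= maxSetSize) .altset(res)
          else .wild(1L, 1L)
    elems <- c(elems, list(el))
  }
  if (!length(elems))
    stop("all profile columns were gapped; nothing to build", call. = FALSE)
  p <- new("PrositePattern", elements = elems, sourceText = "")
  p@sourceText <- prositeText(p)
  p
}

#' Classify alignment columns against a grouping
#'
#' Per column: \code{"gapped"} if any row has a gap; \code{"conserved"}
#' if a single residue is shared by all rows; \code{"class-specific"}
#' if every group is internally fixed to a single residue and at least
#' two groups differ; otherwise \code{"unconserved"}.
#'
#' @param msa a \code{\linkS4class{ProteinMsa}}.
#' @param groups named list of row-id vectors forming a partition of the
#'   alignment rows (at least 2 groups, disjoint, covering all rows).
#' @return character vector of length \code{msaNcol(msa)}.
#' @export
findClassSpecificColumns <- function(msa, groups) {
  stopifnot(is(msa, "ProteinMsa"))
  ids <- msaIds(msa)
  flat <- unlist(groups, use.names = FALSE)
  if (length(groups) < 2L || anyDuplicated(flat) ||
      !setequal(flat, ids) || any(!lengths(groups)))
    stop("groups must be >=2 disjoint non-empty sets covering all rows",
         call. = FALSE)
  m <- msaMatrix(msa)
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == "-")) return("gapped")
    if (length(unique(col)) == 1L) return("conserved")
    per <- vapply(groups, function(g) {
      u <- unique(col[g])
      if (length(u) == 1L) u else NA_character_
    }, "")
    if (anyNA(per)) return("unconserved")
    if (length(unique(per)) >= 2L) "class-specific" else "unconserved"
  }, "")
}

.matchesAll <- function(pattern, seqs) {
  all(vapply(seq_along(seqs),
             function(i) matchesProsite(pattern, seqs[i]), logical(1)))
}

.matchesAny <- function(pattern, seqs) {
  any(vapply(seq_along(seqs),
             function(i) matchesProsite(pattern, seqs[i]), logical(1)))
}

#' Refine a motif into a minimal discriminative core
#'
#' Starting from a pattern that matches every positive sequence and no
#' negative sequence, repeatedly attempts to remove the first element,
#' then the last element; a removal is kept iff the shortened pattern is
#' still discriminative. Stops when neither end can be removed, so the
#' result is end-trim minimal.
#'
#' @param pattern a \code{\linkS4class{PrositePattern}} or pattern text.
#' @param positives,negatives sequences (\code{AAStringSet} or named
#'   character vectors).
#' @return the refined \code{\linkS4class{PrositePattern}}.
#' @export
refineDiscriminativeMotif <- function(pattern, positives, negatives) {
  if (is.character(pattern)) pattern <- parseProsite(pattern)
  if (is(positives, "AAStringSet")) positives <- as.character(positives)
  if (is(negatives, "AAStringSet")) negatives <- as.character(negatives)
  if (!length(positives) || !length(negatives))
    stop("need at least one positive and one negative", call. = FALSE)
  disc <- function(p) .matchesAll(p, positives) && !.matchesAny(p, negatives)
  if (!disc(pattern)) {
    missed <- names(positives)[!vapply(seq_along(positives), function(i)
      matchesProsite(pattern, positives[i]), logical(1))]
    hitNeg <- names(negatives)[vapply(seq_along(negatives), function(i)
      matchesProsite(pattern, negatives[i]), logical(1))]
    stop("pattern not discriminative at start",
         if (length(missed)) paste0("; misses positives: ",
                                    paste(missed, collapse = ", ")),
         if (length(hitNeg)) paste0("; matches negatives: ",
                                    paste(hitNeg, collapse = ", ")),
         call. = FALSE)
  }
  repeat {
    changed <- FALSE
    if (patternLength(pattern) > 1L) {
      cand <- trimPattern(pattern, from = 1L)
      if (disc(cand)) { pattern <- cand; changed <- TRUE }
    }
    if (patternLength(pattern) > 1L) {
      cand <- trimPattern(pattern, to = 1L)
      if (disc(cand)) { pattern <- cand; changed <- TRUE }
    }
    if (!changed) break
  }
  pattern
}
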