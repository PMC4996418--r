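#' @import methods
#' @importFrom Biostrings AAStringSet width readAAStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern alignedSubject score
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom stats hclust as.dist rpois runif setNames aggregate
#' @importFrom utils write.table read.delim
NULL

AA_CANONICAL <- c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y")
AA_LEGAL <- c(AA_CANONICAL, "X")

#' Multiple sequence alignment of protein sequences
#'
#' A light container for an equal-width gapped protein alignment. Rows are
#' stored as a named character vector of gapped residue strings; the only
#' gap character is \code{"-"}. Ungapping any row must yield a legal
#' (non-empty) residue string over the 20 canonical amino acids plus X.
#'
#' @slot seqs named character vector of gapped rows, all the same width.
#'
#' @seealso \code{\link{ProteinMsa}}, \code{\link{msaNcol}},
#'   \code{\link{ungapMsa}}
#' @exportClass ProteinMsa
setClass("ProteinMsa", representation(seqs = "character"))

setValidity("ProteinMsa", function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment has no rows")
  if (is.null(names(s)) || any(!nzchar(names(s))))
    return("every row needs a non-empty id")
  if (anyDuplicated(names(s))) return("duplicate row ids")
  w <- nchar(s)
  if (length(unique(w)) != 1L)
    return(sprintf("rows have unequal widths (%s)",
                   paste(unique(w), collapse = ", ")))
  chars <- unique(strsplit(paste(s, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(AA_LEGAL, "-"))
  if (length(bad))
    return(sprintf("illegal characters in alignment: %s",
                   paste(bad, collapse = "")))
  ung <- gsub("-", "", s, fixed = TRUE)
  if (any(!nzchar(ung)))
    return(sprintf("all-gap row: %s", names(s)[!nzchar(ung)][1L]))
  TRUE
})

#' One element of a PROSITE pattern
#'
#' Internal representation: a list with fields \code{type} (one of
#' \code{"literal"}, \code{"set"}, \code{"excluded"}, \code{"wildcard"}),
#' \code{residues} (character vector, empty for wildcards) and, for
#' wildcards, \code{min}/\code{max} repeat counts.
#'
#' @name prosite-element
#' @keywords internal
NULL

#' PROSITE-format sequence pattern
#'
#' Ordered pattern over amino acids in the standard PROSITE subset:
#' literal residues, alternative sets \code{[..]}, excluded sets
#' \code{{..}} and wildcards \code{x}, \code{x(n)}, \code{x(n,m)}.
#'
#' @slot elements list of pattern elements (see \code{prosite-element}).
#' @slot sourceText canonical PROSITE-syntax serialization.
#'
#' @seealso \code{\link{parseProsite}}, \code{\link{scanProsite}}
#' @exportClass PrositePattern
setClass("PrositePattern",
         representation(elements = "list", sourceText = "character"))

setValidity("PrositePattern", function(object) {
  el <- object@elements
  if (length(el) < 1L) return("pattern needs at least one element")
  for (e in el) {
    if (!e$type %in% c("literal", "set", "excluded", "wildcard"))
      return(sprintf("unknown element type '%s'", e$type))
    if (e$type %in% c("set", "excluded")) {
      if (length(e$residues) < 1L) return("empty residue set")
      if (anyDuplicated(e$residues)) return("duplicate residues in a set")
    }
    if (e$type == "literal" && length(e$residues) != 1L)
      return("literal element must hold exactly one residue")
    if (e$type == "wildcard" &&
        (e$min < 0L || e$max < e$min))
      return("wildcard repeat range invalid")
  }
  TRUE
})

#' Kinase consensus phosphorylation rule
#'
#' An ordered window of elements, each either \code{any} (X), a plain
#' residue set, or a phospho residue set (flagged). Exactly one phospho
#' element is designated as the reported site.
#'
#' @slot kinase kinase name, e.g. \code{"GSK3"}.
#' @slot elements list; each element is \code{list(residues=, phospho=)}
#'   where \code{residues = NULL} means "any residue".
#' @slot siteIndex 1-based index of the phospho element whose sequence
#'   position is reported.
#'
#' @seealso \code{\link{kinaseRule}}, \code{\link{scanKinaseSites}}
#' @exportClass KinaseRule
setClass("KinaseRule",
         representation(kinase = "character", elements = "list",
                        siteIndex = "integer"))

setValidity("KinaseRule", function(object) {
  if (length(object@elements) < 1L) return("rule needs elements")
  ph <- vapply(object@elements, function(e) isTRUE(e$phospho), logical(1))
  if (!any(ph)) return("rule needs at least one phospho element")
  i <- object@siteIndex
  if (length(i) != 1L || i < 1L || i > length(object@elements))
    return("siteIndex out of range")
  if (!ph[i]) return("siteIndex must point at a phospho element")
  TRUE
})

#' Pairwise alignment result
#'
#' @slot alignedA,alignedB equal-length gapped strings (empty for an
#'   empty optimal local alignment).
#' @slot score alignment score.
#' @slot mode \code{"global"} or \code{"local"}.
#'
#' @seealso \code{\link{globalAlign}}, \code{\link{localAlign}}
#' @exportClass PairAlignment
setClass("PairAlignment",
         representation(alignedA = "character", alignedB = "character",
                        score = "numeric", mode = "character"))

setValidity("PairAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings differ in length")
  if (!object@mode %in% c("global", "local")) return("bad mode")
  if (nchar(object@alignedA) > 0L) {
    a <- strsplit(object@alignedA, "")[[1]]
    b <- strsplit(object@alignedB, "")[[1]]
    if (any(a == "-" & b == "-")) return("gap/gap column")
  }
  TRUE
})

#' Classical metric MDS embedding
#'
#' @slot labels point labels.
#' @slot points matrix (labels x components) of coordinates, one column
#'   per retained positive eigenvalue, scaled by sqrt(eigenvalue).
#' @slot eigenvalues all eigenvalues of the doubly centered matrix,
#'   sorted descending.
#' @slot explained fraction of the positive-eigenvalue mass explained by
#'   each retained component.
#'
#' @seealso \code{\link{classicalMds}}
#' @exportClass MdsEmbedding
setClass("MdsEmbedding",
         representation(labels = "character", points = "matrix",
                        eigenvalues = "numeric", explained = "numeric"))

#' Evolutionary trace result
#'
#' @slot levels list, one entry per partition level; each entry is a
#'   list with \code{groups} (list of leaf-id vectors) and \code{classes}
#'   (per-column classification: conserved / class-specific /
#'   unconserved / gapped).
#' @slot ids alignment row ids the trace was computed over.
#'
#' @seealso \code{\link{evolutionaryTrace}}
#' @exportClass TraceResult
setClass("TraceResult", representation(levels = "list", ids = "character"))

#' Simulated two-paralog protein family
#'
#' @slot records \code{AAStringSet} of ungapped sequences; metadata
#'   columns carry \code{paralog_label} and \code{species}.
#' @slot tree the true gene tree (\code{ape} \code{phylo}), tips named
#'   like the records.
#' @slot truth list of planted ground truth: per-record motif span and
#'   key-residue position, class-specific motif column, and per-record
#'   inserted-region coordinates with subtype.
#'
#' @seealso \code{\link{simulateFamily}}
#' @exportClass SimulatedFamily
setClass("SimulatedFamily",
         representation(records = "AAStringSet", tree = "ANY",
                        truth = "list"))

setMethod("show", "ProteinMsa", function(object) {
  cat(sprintf("ProteinMsa: %d rows x %d columns\n",
              length(object@seqs), nchar(object@seqs[[1L]])))
  n <- min(6L, length(object@seqs))
  for (i in seq_len(n)) {
    s <- object@seqs[[i]]
    if (nchar(s) > 50L) s <- paste0(substr(s, 1L, 50L), "...")
    cat(sprintf("  %-12s %s\n", names(object@seqs)[i], s))
  }
  if (length(object@seqs) > n) cat("  ...\n")
})

setMethod("show", "PrositePattern", function(object) {
  cat("PrositePattern:", object@sourceText, "\n")
})

setMethod("show", "KinaseRule", function(object) {
  cat(sprintf("KinaseRule %s: %s (site element %d)\n",
              object@kinase, kinaseConsensusText(object),
              object@siteIndex))
})

setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment (%s), score %.1f\n",
              object@mode, object@score))
  if (nchar(object@alignedA) == 0L) {
    cat("  <empty alignment>\n")
  } else {
    cat(" ", object@alignedA, "\n ", object@alignedB, "\n")
  }
})

setMethod("show", "MdsEmbedding", function(object) {
  cat(sprintf("MdsEmbedding: %d points, %d components\n",
              length(object@labels), ncol(object@points)))
  cat("  explained:", paste(sprintf("%.3f", object@explained),
                            collapse = " "), "\n")
})

setMethod("show", "TraceResult", function(object) {
  cat(sprintf("TraceResult: %d levels over %d sequences\n",
              length(object@levels), length(object@ids)))
})

setMethod("show", "SimulatedFamily", function(object) {
  lab <- S4Vectors::mcols(object@records)$paralog_label
  cat(sprintf("SimulatedFamily: %d records (%d group-A, %d group-B)\n",
              length(object@records), sum(lab == "group-A"),
              sum(lab == "group-B")))
})
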