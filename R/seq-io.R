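## Sequence and tree IO: FASTA / aligned FASTA / Clustal in, FASTA out
## (wrapped at 60 columns), Newick via ape. Residue alphabet is the 20
## canonical amino acids plus X; B/Z/U/O are rejected so that pattern
## matching never has to resolve ambiguity codes.

.checkResidues <- function(x, ids, allow_gap = FALSE) {
  legal <- c(AA_LEGAL, if (allow_gap) "-")
  for (i in seq_along(x)) {
    ch <- strsplit(x[[i]], "")[[1]]
    bad <- which(!ch %in% legal)
    if (length(bad))
      stop(sprintf("illegal residue '%s' in record '%s' at position %d",
                   ch[bad[1L]], ids[i], bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

.cleanResidues <- function(x, ids) {
  x <- toupper(x)
  if (any(grepl("*", x, fixed = TRUE))) {
    warning("stop symbols '*' stripped from input sequences",
            call. = FALSE)
    x <- gsub("*", "", x, fixed = TRUE)
  }
  if (any(grepl(".", x, fixed = TRUE))) {
    warning("gap character '.' converted to '-'", call. = FALSE)
    x <- gsub(".", "-", x, fixed = TRUE)
  }
  names(x) <- ids
  x
}

#' Construct a protein multiple sequence alignment
#'
#' @param seqs named character vector of gapped rows (gap character
#'   \code{"-"}), all of equal width.
#' @return a \code{\linkS4class{ProteinMsa}}.
#' @examples
#' msa <- ProteinMsa(c(a = "AC-E", b = "ACDE"))
#' msaNcol(msa)
#' @export
ProteinMsa <- function(seqs) {
  new("ProteinMsa", seqs = seqs)
}

#' @rdname msa-accessors
#' @export
msaNcol <- function(msa) nchar(msa@seqs[[1L]])

#' Alignment accessors
#'
#' \code{msaNcol}/\code{msaNrow} give dimensions, \code{msaIds} the row
#' ids, \code{msaRows} the gapped rows, \code{msaMatrix} a character
#' matrix (rows x columns), and \code{msaSubset} a row subset.
#'
#' @param msa a \code{\linkS4class{ProteinMsa}}.
#' @param ids row ids to keep (for \code{msaSubset}).
#' @name msa-accessors
#' @export
msaNrow <- function(msa) length(msa@seqs)

#' @rdname msa-accessors
#' @export
msaIds <- function(msa) names(msa@seqs)

#' @rdname msa-accessors
#' @export
msaRows <- function(msa) msa@seqs

#' @rdname msa-accessors
#' @export
msaMatrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa@seqs, ""))
  rownames(m) <- names(msa@seqs)
  m
}

#' @rdname msa-accessors
#' @export
msaSubset <- function(msa, ids) {
  miss <- setdiff(ids, msaIds(msa))
  if (length(miss))
    stop("unknown row ids: ", paste(miss, collapse = ", "), call. = FALSE)
  ProteinMsa(msa@seqs[ids])
}

#' Remove gaps from alignment rows
#'
#' @param msa a \code{\linkS4class{ProteinMsa}}.
#' @return an \code{AAStringSet} of the ungapped rows.
#' @export
ungapMsa <- function(msa) {
  Biostrings::AAStringSet(gsub("-", "", msa@seqs, fixed = TRUE))
}

# Clustal block format: a header line, then blocks of "name  segment"
# rows; conservation lines (leading whitespace, only * : . and blanks)
# and optional trailing residue counts are ignored.
.readClustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1L]))
    stop("not a Clustal file: ", path, call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  body <- body[!grepl("^\\s", body)]   # conservation lines
  if (!length(body)) stop("Clustal file has no sequence rows",
                          call. = FALSE)
  parts <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)(\\s+\\d+)?\\s*$",
                                    body))
  bad <- which(!lengths(parts))
  if (length(bad))
    stop("malformed Clustal row: ", body[bad[1L]], call. = FALSE)
  ids <- vapply(parts, `[`, "", 2L)
  segs <- vapply(parts, `[`, "", 3L)
  out <- vapply(unique(ids), function(id)
    paste(segs[ids == id], collapse = ""), "")
  out
}

.guessFormat <- function(path) {
  head <- readLines(path, n = 5L, warn = FALSE)
  head <- head[nzchar(head)]
  if (length(head) && grepl("^CLUSTAL", head[1L])) return("clustal")
  if (length(head) && startsWith(head[1L], ">")) {
    ss <- tryCatch(Biostrings::readAAStringSet(path), error = function(e) NULL)
    if (!is.null(ss) && length(ss) > 1L &&
        length(unique(Biostrings::width(ss))) == 1L &&
        any(grepl("-", as.character(ss), fixed = TRUE)))
      return("aligned_fasta")
    return("fasta")
  }
  stop("cannot recognize sequence format of ", path, call. = FALSE)
}

#' Read protein sequences or an alignment
#'
#' Reads FASTA (returns an \code{AAStringSet} of ungapped records),
#' aligned FASTA or Clustal (both return a
#' \code{\linkS4class{ProteinMsa}}). Residues are upper-cased, stop
#' symbols \code{*} are stripped with a warning, and the legacy gap
#' character \code{.} is converted to \code{-} with a warning.
#'
#' @param path input file.
#' @param format one of \code{"auto"}, \code{"fasta"},
#'   \code{"aligned_fasta"}, \code{"clustal"}.
#' @return \code{AAStringSet} or \code{ProteinMsa}.
#' @export
readProteins <- function(path,
                         format = c("auto", "fasta", "aligned_fasta",
                                    "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") format <- .guessFormat(path)
  if (format == "clustal") {
    seqs <- .readClustal(path)
    seqs <- .cleanResidues(unname(seqs), names(seqs))
  } else {
    ss <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- .cleanResidues(as.character(ss), ids)
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  if (format == "fasta") {
    .checkResidues(seqs, names(seqs), allow_gap = FALSE)
    return(Biostrings::AAStringSet(seqs))
  }
  .checkResidues(seqs, names(seqs), allow_gap = TRUE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned input has rows of unequal length", call. = FALSE)
  ProteinMsa(seqs)
}

#' Write sequences or an alignment as FASTA
#'
#' Output is wrapped at 60 columns. Gapped alignments are written as
#' aligned FASTA.
#'
#' @param x an \code{AAStringSet} or \code{\linkS4class{ProteinMsa}}.
#' @param path output file.
#' @export
writeProteinsFasta <- function(x, path) {
  if (is(x, "ProteinMsa")) x <- Biostrings::AAStringSet(msaRows(x))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers over \code{ape}: parsing rejects duplicate leaf labels,
#' serialization round-trips. Unrooted trees keep their trifurcating
#' root node as read.
#'
#' @param text Newick string (for \code{readNewick}) or a \code{phylo}
#'   (for \code{writeNewick}).
#' @return \code{phylo}, or a Newick string.
#' @export
readNewick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL)
  if (is.null(tr))
    stop("cannot parse Newick: ", text, call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in Newick input", call. = FALSE)
  tr
}

#' @rdname readNewick
#' @export
writeNewick <- function(text) {
  ape::write.tree(text)
}
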