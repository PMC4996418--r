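## Kinase consensus rules and phosphosite scanning. Consensus text uses
## the compact notation of kinase specificity tables: elements separated
## by '-', 'X' = any residue, 'pS' = phospho-serine, alternatives with
## '/' (e.g. "pS/T", "D/E/pS"). A 'pS' in a non-reported position simply
## permits S: phosphorylation state is not modelled, only sequence.

.parseConsensusElement <- function(tok) {
  parts <- strsplit(tok, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1L && toupper(parts) == "X")
    return(list(residues = NULL, phospho = FALSE))
  phospho <- FALSE
  residues <- character(0)
  for (p in parts) {
    if (grepl("^p", p)) { phospho <- TRUE; p <- sub("^p", "", p) }
    if (!p %in% AA_CANONICAL)
      stop(sprintf("bad consensus token '%s'", tok), call. = FALSE)
    residues <- c(residues, p)
  }
  list(residues = unique(residues), phospho = phospho)
}

#' Construct a kinase consensus rule
#'
#' @param kinase kinase name.
#' @param consensus consensus text, e.g. \code{"pS-X-X-X-pS-P"}.
#' @param siteIndex 1-based index of the phospho element whose position
#'   is reported; defaults to the first (most N-terminal) phospho
#'   element.
#' @return a \code{\linkS4class{KinaseRule}}.
#' @examples
#' kinaseRule("GSK3", "pS-X-X-X-pS-P")
#' @export
kinaseRule <- function(kinase, consensus, siteIndex = NULL) {
  toks <- strsplit(trimws(consensus), "-", fixed = TRUE)[[1]]
  elems <- lapply(toks, .parseConsensusElement)
  if (is.null(siteIndex)) {
    ph <- which(vapply(elems, function(e) e$phospho, logical(1)))
    if (!length(ph)) stop("consensus has no phospho element", call. = FALSE)
    siteIndex <- ph[1L]
  }
  new("KinaseRule", kinase = kinase, elements = elems,
      siteIndex = as.integer(siteIndex))
}

#' @rdname kinaseRule
#' @param rule a \code{\linkS4class{KinaseRule}}.
#' @export
kinaseConsensusText <- function(rule) {
  one <- function(e) {
    if (is.null(e$residues)) return("X")
    pre <- if (e$phospho) "p" else ""
    paste0(pre, paste(e$residues, collapse = "/"))
  }
  paste(vapply(rule@elements, one, ""), collapse = "-")
}

#' Read kinase rules from a TSV file
#'
#' Expected columns: \code{kinase}, \code{consensus} and optionally
#' \code{site_index}.
#'
#' @param path TSV file with a header row.
#' @return list of \code{\linkS4class{KinaseRule}} objects.
#' @export
readKinaseRules <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    si <- if ("site_index" %in% names(tab) && !is.na(tab$site_index[i]))
      tab$site_index[i] else NULL
    kinaseRule(tab$kinase[i], tab$consensus[i], si)
  })
}

.ruleMatchesAt <- function(rule, chars, start) {
  for (k in seq_along(rule@elements)) {
    e <- rule@elements[[k]]
    r <- chars[start + k - 1L]
    if (is.null(e$residues)) next          # 'X': any residue
    if (r == "X" || !(r %in% e$residues)) return(FALSE)
  }
  TRUE
}

#' Scan a sequence for kinase consensus phosphosites
#'
#' A window matches iff every consensus element matches its residue; the
#' full window must lie inside the sequence (no overhang). The reported
#' position is the residue aligned with the rule's designated phospho
#' element. All matches are returned, sorted by position then kinase
#' name.
#'
#' @param seq a sequence (character or \code{AAString}); its name is
#'   used as \code{seq_id}.
#' @param rules a \code{\linkS4class{KinaseRule}} or list of rules.
#' @param id sequence id override.
#' @return data.frame with columns \code{seq_id}, \code{position},
#'   \code{residue}, \code{kinase}, \code{window_start},
#'   \code{window_end}.
#' @examples
#' scanKinaseSites(c(tw2 = "MEEGSSSPVSPVDSLGTSEEE"),
#'                 kinaseRule("LKB1", "X-L-X-pT-X-X"))
#' @export
scanKinaseSites <- function(seq, rules, id = NULL) {
  if (is(rules, "KinaseRule")) rules <- list(rules)
  if (is.null(id))
    id <- if (!is.null(names(seq)) && nzchar(names(seq)[1L]))
      names(seq)[1L] else "seq"
  s <- .seqString(seq)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  out <- list()
  for (rule in rules) {
    K <- length(rule@elements)
    if (K > n) next
    for (start in seq_len(n - K + 1L)) {
      if (.ruleMatchesAt(rule, chars, start)) {
        pos <- start + rule@siteIndex - 1L
        out[[length(out) + 1L]] <- data.frame(
          seq_id = id, position = pos, residue = chars[pos],
          kinase = rule@kinase, window_start = start,
          window_end = start + K - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(0), position = integer(0),
                      residue = character(0), kinase = character(0),
                      window_start = integer(0), window_end = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$position, res$kinase), , drop = FALSE]
}
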