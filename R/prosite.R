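## PROSITE pattern parsing, canonical serialization and element-wise
## scanning. Supported subset: literal residues, alternative sets [..],
## excluded sets {..}, wildcards x / x(n) / x(n,m), optional '-'
## separators and an optional trailing '.'. Matching semantics: an 'X'
## in the sequence matches only wildcard elements, never literals, sets
## or exclusions.

.literal <- function(r) list(type = "literal", residues = r)
.altset  <- function(r) list(type = "set", residues = r)
.exclset <- function(r) list(type = "excluded", residues = r)
.wild    <- function(n, m) list(type = "wildcard", residues = character(0),
                                min = as.integer(n), max = as.integer(m))

#' Parse a PROSITE-syntax pattern
#'
#' @param text pattern text, e.g. \code{"[TN]-S-E-[EG]-E"} or
#'   \code{"x(2)-A"}.
#' @return a \code{\linkS4class{PrositePattern}}; its \code{sourceText}
#'   is the canonical serialization (elements joined by \code{"-"}).
#' @examples
#' parseProsite("[TN]-S-E-[EG]-E")
#' @export
parseProsite <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("pattern text must be a non-empty string", call. = FALSE)
  src <- sub("\\.$", "", trimws(text))
  ch <- strsplit(src, "")[[1]]
  n <- length(ch)
  i <- 1L
  elems <- list()
  perr <- function(msg, pos) {
    stop(sprintf("PROSITE parse error at position %d: %s", pos, msg),
         call. = FALSE)
  }
  readSet <- function(close) {
    j <- i + 1L
    res <- character(0)
    while (j <= n && ch[j] != close) {
      if (!ch[j] %in% AA_CANONICAL)
        perr(sprintf("'%s' is not a residue", ch[j]), j)
      res <- c(res, ch[j])
      j <- j + 1L
    }
    if (j > n) perr(sprintf("unclosed '%s'", if (close == "]") "[" else "{"), i)
    if (!length(res)) perr("empty bracket set", i)
    if (anyDuplicated(res)) perr("duplicate residue in bracket set", i)
    i <<- j + 1L
    res
  }
  readRepeat <- function() {
    # optional "(n)" or "(n,m)" following a wildcard
    if (i > n || ch[i] != "(") return(c(1L, 1L))
    j <- i + 1L
    num <- ""
    while (j <= n && ch[j] != ")") { num <- paste0(num, ch[j]); j <- j + 1L }
    if (j > n) perr("unclosed repeat '('", i)
    parts <- strsplit(num, ",", fixed = TRUE)[[1]]
    if (!length(parts) || length(parts) > 2L ||
        any(!grepl("^[0-9]+$", parts)))
      perr(sprintf("malformed repeat '(%s)'", num), i)
    i <<- j + 1L
    v <- as.integer(parts)
    if (length(v) == 1L) v <- c(v, v)
    if (v[2] < v[1]) perr("repeat range has max < min", i)
    v
  }
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "-") { i <- i + 1L; next }
    if (c0 == "[") { elems <- c(elems, list(.altset(readSet("]")))); next }
    if (c0 == "{") { elems <- c(elems, list(.exclset(readSet("}")))); next }
    if (c0 == "x" || c0 == "X") {
      i <- i + 1L
      r <- readRepeat()
      elems <- c(elems, list(.wild(r[1], r[2])))
      next
    }
    if (c0 %in% AA_CANONICAL) {
      elems <- c(elems, list(.literal(c0)))
      i <- i + 1L
      next
    }
    perr(sprintf("unexpected character '%s'", c0), i)
  }
  if (!length(elems)) perr("pattern has no elements", 1L)
  p <- new("PrositePattern", elements = elems, sourceText = "")
  p@sourceText <- prositeText(p)
  validObject(p)
  p
}

#' Canonical PROSITE serialization
#'
#' @param pattern a \code{\linkS4class{PrositePattern}}.
#' @return the canonical pattern string, elements joined by \code{"-"}.
#' @export
prositeText <- function(pattern) {
  stopifnot(is(pattern, "PrositePattern"))
  one <- function(e) {
    switch(e$type,
           literal  = e$residues,
           set      = paste0("[", paste(e$residues, collapse = ""), "]"),
           excluded = paste0("{", paste(e$residues, collapse = ""), "}"),
           wildcard = {
             if (e$min == 1L && e$max == 1L) "x"
             else if (e$min == e$max) sprintf("x(%d)", e$min)
             else sprintf("x(%d,%d)", e$min, e$max)
           })
  }
  paste(vapply(pattern@elements, one, ""), collapse = "-")
}

#' Number of elements in a pattern
#' @param pattern a \code{\linkS4class{PrositePattern}}.
#' @export
patternLength <- function(pattern) length(pattern@elements)

#' Drop elements from the ends of a pattern
#'
#' @param pattern a \code{\linkS4class{PrositePattern}}.
#' @param from number of elements to drop from the front.
#' @param to number of elements to drop from the back.
#' @return the shortened \code{PrositePattern}.
#' @export
trimPattern <- function(pattern, from = 0L, to = 0L) {
  el <- pattern@elements
  keep <- seq.int(1L + from, length(el) - to)
  if (length(keep) < 1L) stop("cannot trim pattern to zero elements",
                              call. = FALSE)
  p <- new("PrositePattern", elements = el[keep], sourceText = "")
  p@sourceText <- prositeText(p)
  p
}

.elementMatches <- function(e, residue) {
  # 'X' in the sequence only ever matches wildcards
  switch(e$type,
         literal  = residue == e$residues,
         set      = residue %in% e$residues,
         excluded = residue != "X" && !(residue %in% e$residues),
         wildcard = TRUE)
}

# Returns the 0-based end offset of the shortest match of elements
# k..K starting at pos, or -1L if none.
.matchFrom <- function(chars, pos, elems, k) {
  n <- length(chars)
  K <- length(elems)
  while (k <= K) {
    e <- elems[[k]]
    if (e$type == "wildcard") {
      if (e$min == 1L && e$max == 1L) {
        if (pos > n) return(-1L)
        pos <- pos + 1L; k <- k + 1L
        next
      }
      for (len in e$min:e$max) {
        if (pos + len - 1L > n) break
        res <- .matchFrom(chars, pos + len, elems, k + 1L)
        if (res >= 0L) return(res)
      }
      return(-1L)
    }
    if (pos > n || !.elementMatches(e, chars[pos])) return(-1L)
    pos <- pos + 1L; k <- k + 1L
  }
  pos - 1L
}

#' Scan a sequence with a PROSITE pattern
#'
#' Element-wise matching over the ungapped sequence. All overlapping
#' matches are reported in \code{"all"} mode (at most one hit per start
#' position; for variable-length wildcards the shortest match at a
#' start is reported), ordered by start.
#'
#' @param pattern a \code{\linkS4class{PrositePattern}} or pattern text.
#' @param seq a sequence (character, \code{AAString}); its name (or
#'   \code{id}) is used as \code{seq_id}.
#' @param mode \code{"all"} or \code{"first"}.
#' @param id sequence id for the report; defaults to the name of
#'   \code{seq} or \code{"seq"}.
#' @return data.frame with columns \code{seq_id}, \code{start},
#'   \code{end} (1-based, inclusive) and \code{matched_text}.
#' @examples
#' scanProsite("[TN]-S-E-[EG]-E", c(pep = "MEEGSSSPVSPVDSLGTSEEE"))
#' @export
scanProsite <- function(pattern, seq, mode = c("all", "first"), id = NULL) {
  mode <- match.arg(mode)
  if (is.character(pattern)) pattern <- parseProsite(pattern)
  stopifnot(is(pattern, "PrositePattern"))
  if (is.null(id))
    id <- if (!is.null(names(seq)) && nzchar(names(seq)[1L]))
      names(seq)[1L] else "seq"
  s <- .seqString(seq)
  chars <- strsplit(s, "")[[1]]
  hits <- list()
  for (start in seq_along(chars)) {
    end <- .matchFrom(chars, start, pattern@elements, 1L)
    if (end >= 0L) {
      hits[[length(hits) + 1L]] <-
        data.frame(seq_id = id, start = start, end = end,
                   matched_text = substr(s, start, end),
                   stringsAsFactors = FALSE)
      if (mode == "first") break
    }
  }
  if (!length(hits))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Does a pattern match anywhere in a sequence?
#'
#' @inheritParams scanProsite
#' @return logical.
#' @export
matchesProsite <- function(pattern, seq) {
  nrow(scanProsite(pattern, seq, mode = "first")) > 0L
}
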