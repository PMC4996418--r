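## Pairwise alignment and percent identity. The aligner itself is
## Biostrings::pairwiseAlignment; the defaults reproduce protein-BLAST
## scoring (BLOSUM62, gap open 11, gap extend 1: a gap of length k costs
## 11 + k). Identity is identities / alignment columns, the way BLASTP
## reports "Identities"; +-1 percentage point vs the NCBI server is
## possible because no compositional adjustment is applied.

#' Default alignment scoring scheme
#'
#' @param matrix substitution matrix (symmetric, residue-labelled);
#'   default BLOSUM62 as shipped with Biostrings.
#' @param gapOpen,gapExtend non-negative gap penalties; a gap of length
#'   k costs \code{gapOpen + k * gapExtend}.
#' @return a list with elements \code{matrix}, \code{gapOpen},
#'   \code{gapExtend}.
#' @export
scoringScheme <- function(matrix = NULL, gapOpen = 11, gapExtend = 1) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  if (!isSymmetric(unname(matrix)))
    stop("substitution matrix must be symmetric", call. = FALSE)
  if (gapOpen < 0 || gapExtend < 0 || gapExtend > gapOpen)
    stop("need 0 <= gapExtend <= gapOpen", call. = FALSE)
  list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend)
}

#' Read a substitution matrix from whitespace-separated text
#'
#' Standard NCBI-style matrix files: a header row of residue labels,
#' then one labelled row per residue. Comment lines starting with
#' \code{#} are ignored.
#'
#' @param path matrix file.
#' @return numeric matrix with residue dimnames.
#' @export
readScoringMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  body <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1]])
  rn <- vapply(body, `[`, "", 1L)
  m <- do.call(rbind, lapply(body, function(x) as.numeric(x[-1L])))
  dimnames(m) <- list(rn, header)
  m
}

.seqString <- function(x) {
  if (is(x, "AAString") || is(x, "AAStringSet"))
    x <- as.character(x)
  if (length(x) != 1L) stop("expected a single sequence", call. = FALSE)
  if (!nzchar(x)) stop("empty sequence", call. = FALSE)
  toupper(unname(x))
}

.pairAlign <- function(a, b, scoring, mode) {
  a <- .seqString(a); b <- .seqString(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend,
    type = mode)
  sa <- as.character(Biostrings::alignedPattern(aln))
  sb <- as.character(Biostrings::alignedSubject(aln))
  sc <- Biostrings::score(aln)
  if (mode == "local" && sc <= 0) {
    # all sub-alignments score <= 0: the optimal local alignment is empty
    sa <- ""; sb <- ""; sc <- 0
  }
  new("PairAlignment", alignedA = unname(sa), alignedB = unname(sb),
      score = sc, mode = mode)
}

#' Optimal pairwise alignment
#'
#' Affine-gap global (Needleman-Wunsch) or local (Smith-Waterman)
#' alignment. A local alignment in which every sub-alignment scores
#' at most zero is returned as an explicit empty
#' \code{\linkS4class{PairAlignment}}.
#'
#' @param a,b sequences (character, \code{AAString}, or length-1
#'   \code{AAStringSet}).
#' @param scoring a scheme from \code{\link{scoringScheme}}.
#' @return a \code{\linkS4class{PairAlignment}}.
#' @export
globalAlign <- function(a, b, scoring = scoringScheme()) {
  .pairAlign(a, b, scoring, "global")
}

#' @rdname globalAlign
#' @export
localAlign <- function(a, b, scoring = scoringScheme()) {
  .pairAlign(a, b, scoring, "local")
}

#' Identity statistics of a pairwise alignment
#'
#' @param aln a \code{\linkS4class{PairAlignment}}.
#' @return list with \code{n_identical}, \code{n_cols},
#'   \code{identity_pct} (100 * identical / columns; \code{NA} for an
#'   empty alignment) and \code{rounded_pct} (round half up).
#' @export
alignmentIdentity <- function(aln) {
  stopifnot(is(aln, "PairAlignment"))
  n_cols <- nchar(aln@alignedA)
  if (n_cols == 0L)
    return(list(n_identical = 0L, n_cols = 0L,
                identity_pct = NA_real_, rounded_pct = NA_integer_))
  ca <- strsplit(aln@alignedA, "")[[1]]
  cb <- strsplit(aln@alignedB, "")[[1]]
  n_id <- sum(ca == cb & ca != "-")
  pct <- 100 * n_id / n_cols
  list(n_identical = n_id, n_cols = n_cols, identity_pct = pct,
       rounded_pct = as.integer(floor(pct + 0.5)))
}

#' Percent identity between two sequences
#'
#' Aligns and reports identity over the alignment columns. Symmetric in
#' its arguments.
#'
#' @inheritParams globalAlign
#' @param mode \code{"global"} or \code{"local"}.
#' @return see \code{\link{alignmentIdentity}}.
#' @examples
#' percentIdentity("ACDEFG", "ACDEYG")$rounded_pct  # 83
#' @export
percentIdentity <- function(a, b, mode = c("global", "local"),
                            scoring = scoringScheme()) {
  mode <- match.arg(mode)
  alignmentIdentity(.pairAlign(a, b, scoring, mode))
}

## ---- progressive MSA (profile alignment) -----------------------------
## A deliberately small progressive aligner so that synthetic-family
## self-tests need no external alignment tool. Guide tree: single
## linkage on (1 - identity/100) from global pairwise alignments.
## Profiles are merged by affine-gap global alignment of column
## frequency profiles under the same substitution matrix.

.profileScores <- function(mA, mB, sub) {
  res <- AA_LEGAL
  fm <- function(m) {
    t(apply(m, 2, function(col) {
      tabulate(factor(col, levels = res), nbins = length(res))
    })) / nrow(m)
  }
  FA <- fm(mA); FB <- fm(mB)
  S <- sub[res, res]
  FA %*% S %*% t(FB)
}

.alignProfiles <- function(mA, mB, scoring) {
  go <- scoring$gapOpen; ge <- scoring$gapExtend
  sc <- .profileScores(mA, mB, scoring$matrix)
  la <- ncol(mA); lb <- ncol(mB)
  NEG <- -1e18
  M <- matrix(NEG, la + 1L, lb + 1L)
  X <- matrix(NEG, la + 1L, lb + 1L)  # column of A over gap
  Y <- matrix(NEG, la + 1L, lb + 1L)  # gap over column of B
  M[1L, 1L] <- 0
  for (i in seq_len(la)) X[i + 1L, 1L] <- -(go + i * ge)
  for (j in seq_len(lb)) Y[1L, j + 1L] <- -(go + j * ge)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      best <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1L, j + 1L] <- best + sc[i, j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - go - ge,
                               X[i, j + 1L] - ge)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - go - ge,
                               Y[i + 1L, j] - ge)
    }
  }
  # traceback; preference M > X > Y for determinism
  i <- la; j <- lb
  state <- which.max(c(M[i + 1L, j + 1L], X[i + 1L, j + 1L],
                       Y[i + 1L, j + 1L]))
  opsA <- integer(0); opsB <- integer(0)  # 0 = gap, else column index
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      prev <- c(M[i, j], X[i, j], Y[i, j])
      opsA <- c(i, opsA); opsB <- c(j, opsB)
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L) {
      opsA <- c(i, opsA); opsB <- c(0L, opsB)
      from_m <- M[i, j + 1L] - go - ge
      from_x <- X[i, j + 1L] - ge
      i <- i - 1L
      state <- if (from_m >= from_x) 1L else 2L
    } else {
      opsA <- c(0L, opsA); opsB <- c(j, opsB)
      from_m <- M[i + 1L, j] - go - ge
      from_y <- Y[i + 1L, j] - ge
      j <- j - 1L
      state <- if (from_m >= from_y) 1L else 3L
    }
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  grab <- function(m, ops) {
    out <- matrix("-", nrow(m), length(ops))
    keep <- ops > 0L
    out[, keep] <- m[, ops[keep], drop = FALSE]
    rownames(out) <- rownames(m)
    out
  }
  rbind(grab(mA, opsA), grab(mB, opsB))
}

#' Progressive multiple sequence alignment
#'
#' A minimal progressive aligner: a single-linkage guide tree over
#' global-alignment identity distances, then profile-profile merges by
#' affine-gap global alignment of column frequency profiles. Intended
#' for self-contained analyses of simulated families, not as a
#' replacement for a production aligner.
#'
#' @param seqs named \code{AAStringSet} or named character vector of at
#'   least two ungapped sequences.
#' @param scoring a scheme from \code{\link{scoringScheme}}.
#' @return a \code{\linkS4class{ProteinMsa}} with rows in input order.
#' @export
progressiveMsa <- function(seqs, scoring = scoringScheme()) {
  if (is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (length(seqs) < 2L)
    stop("need at least 2 sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences need unique names", call. = FALSE)
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- percentIdentity(seqs[[i]], seqs[[j]], "global", scoring)
      d[i, j] <- d[j, i] <- 1 - pid$identity_pct / 100
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(seqs[[i]], "")[[1]], nrow = 1L)
    rownames(m) <- names(seqs)[i]
    m
  })
  merged <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    pick <- function(idx) if (idx < 0L) profiles[[-idx]] else merged[[idx]]
    merged[[k]] <- .alignProfiles(pick(hc$merge[k, 1L]),
                                  pick(hc$merge[k, 2L]), scoring)
  }
  final <- merged[[n - 1L]]
  rows <- apply(final, 1L, paste, collapse = "")
  ProteinMsa(rows[names(seqs)])
}
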