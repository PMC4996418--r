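## Alignment trimming, gap-masked distance matrices, neighbor-joining
## with column-bootstrap support (trees via ape), classical metric MDS
## of sequence space (double-centering + eigendecomposition), and
## evolutionary-trace residue classing over nested tree partitions.

#' Trim gappy alignment columns
#'
#' Removes columns whose gap fraction exceeds \code{maxGapFraction};
#' explicitly listed column ranges are removed regardless. Row order is
#' preserved.
#'
#' @param msa a \code{\linkS4class{ProteinMsa}}.
#' @param maxGapFraction columns with gap fraction strictly greater than
#'   this are removed (default 0.4).
#' @param dropRanges optional list of 1-based inclusive column intervals
#'   \code{c(from, to)} to remove unconditionally.
#' @return list with \code{msa} (trimmed) and \code{removed} (original
#'   1-based indices of removed columns, sorted).
#' @export
trimAlignment <- function(msa, maxGapFraction = 0.4, dropRanges = NULL) {
  stopifnot(is(msa, "ProteinMsa"))
  if (maxGapFraction <= 0 || maxGapFraction > 1)
    stop("maxGapFraction must be in (0, 1]", call. = FALSE)
  m <- msaMatrix(msa)
  gapFrac <- colMeans(m == "-")
  drop <- gapFrac > maxGapFraction
  if (!is.null(dropRanges)) {
    if (is.numeric(dropRanges)) dropRanges <- list(dropRanges)
    for (r in dropRanges) {
      if (r[1L] < 1L || r[2L] > ncol(m) || r[1L] > r[2L])
        stop("drop range outside the alignment", call. = FALSE)
      drop[r[1L]:r[2L]] <- TRUE
    }
  }
  if (all(drop))
    stop("trimming would remove every column", call. = FALSE)
  kept <- m[, !drop, drop = FALSE]
  rows <- apply(kept, 1L, paste, collapse = "")
  list(msa = ProteinMsa(stats::setNames(rows, rownames(m))),
       removed = which(drop))
}

#' Distance matrix from an alignment
#'
#' Pairwise distances over the columns where neither row has a gap.
#' \code{"p-distance"} is mismatches / compared columns;
#' \code{"matrix-normalized"} is \code{1 - s(a,b) / sqrt(s(a,a) s(b,b))}
#' with \code{s} the sum of similarity-matrix entries over the compared
#' columns, clamped below at zero.
#'
#' @param msa a \code{\linkS4class{ProteinMsa}} with >= 2 rows.
#' @param method \code{"p-distance"} or \code{"matrix-normalized"}.
#' @param similarityMatrix residue similarity matrix for the normalized
#'   method; defaults to BLOSUM62.
#' @return symmetric numeric matrix with row ids as dimnames.
#' @export
msaDistance <- function(msa, method = c("p-distance", "matrix-normalized"),
                        similarityMatrix = NULL) {
  method <- match.arg(method)
  stopifnot(is(msa, "ProteinMsa"))
  m <- msaMatrix(msa)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  if (method == "matrix-normalized" && is.null(similarityMatrix))
    similarityMatrix <- scoringScheme()$matrix
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok))
        stop(sprintf("rows '%s' and '%s' share no ungapped columns",
                     rownames(m)[i], rownames(m)[j]), call. = FALSE)
      a <- m[i, ok]; b <- m[j, ok]
      if (method == "p-distance") {
        dij <- mean(a != b)
      } else {
        sab <- sum(similarityMatrix[cbind(a, b)])
        saa <- sum(similarityMatrix[cbind(a, a)])
        sbb <- sum(similarityMatrix[cbind(b, b)])
        dij <- max(0, 1 - sab / sqrt(saa * sbb))
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining via \code{ape::nj}; negative branch-length
#' estimates are clamped to zero with a message. Additive input
#' distances are reproduced exactly by path lengths on the output tree.
#'
#' @param d symmetric distance matrix with >= 3 labelled rows.
#' @return an unrooted \code{phylo}.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 labels", call. = FALSE)
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative NJ branch length(s) to 0",
                    sum(neg)))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Builds the reference NJ tree from the full alignment, resamples
#' columns with replacement \code{replicates} times, rebuilds an NJ tree
#' per replicate, and reports for each internal bipartition of the
#' reference tree the percentage of replicates containing it
#' (stored in \code{node.label}).
#'
#' @param msa a \code{\linkS4class{ProteinMsa}}.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed; resampling is fully reproducible.
#' @param method,similarityMatrix passed to \code{\link{msaDistance}}.
#' @return the reference \code{phylo} with support percentages as
#'   internal node labels.
#' @export
bootstrapSupport <- function(msa, replicates = 1000L, seed = 1L,
                             method = "p-distance",
                             similarityMatrix = NULL) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  ref <- njTree(msaDistance(msa, method, similarityMatrix))
  set.seed(seed)
  L <- msaNcol(msa)
  rows <- msaRows(msa)
  mat <- msaMatrix(msa)
  boots <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- mat[, idx, drop = FALSE]
    rowsB <- apply(sub, 1L, paste, collapse = "")
    msaB <- ProteinMsa(stats::setNames(rowsB, names(rows)))
    boots[[b]] <- suppressMessages(
      njTree(msaDistance(msaB, method, similarityMatrix)))
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(round(100 * counts / replicates))
  ref
}

#' Does a tree contain a given bipartition?
#'
#' @param tree an unrooted or rooted \code{phylo}.
#' @param tips character vector of tip labels on one side of the split.
#' @return logical; TRUE iff some edge of the tree separates exactly
#'   \code{tips} from the remaining tips.
#' @export
hasBipartition <- function(tree, tips) {
  all_tips <- tree$tip.label
  if (!all(tips %in% all_tips)) return(FALSE)
  parts <- ape::prop.part(tree)
  target <- sort(match(tips, all_tips))
  other <- sort(setdiff(seq_along(all_tips), target))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, other)) return(TRUE)
  }
  FALSE
}

#' Classical metric multidimensional scaling
#'
#' Double-centers the squared distance matrix (B = -1/2 J D^2 J),
#' eigendecomposes it, and returns coordinates for the top-k positive
#' eigenpairs scaled by the square root of the eigenvalue. The per-axis
#' sign is fixed by making the first nonzero loading positive. An
#' all-zero distance matrix yields an embedding with zero retained
#' components (all points at the origin); a matrix whose centered form
#' has no positive eigenvalue but a genuinely negative spectrum is an
#' error.
#'
#' @param d symmetric distance matrix with labels.
#' @param k number of components to retain (default 3; fewer are
#'   returned when fewer positive eigenvalues exist).
#' @return an \code{\linkS4class{MdsEmbedding}}.
#' @export
classicalMds <- function(d, k = 3L) {
  d <- as.matrix(d)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values), 1e-12) * 1e-9
  pos <- which(eig$values > tol)
  if (!length(pos)) {
    if (any(eig$values < -tol))
      stop("degenerate embedding: no positive eigenvalue", call. = FALSE)
    return(new("MdsEmbedding", labels = labels,
               points = matrix(0, n, 0, dimnames = list(labels, NULL)),
               eigenvalues = eig$values, explained = numeric(0)))
  }
  keep <- pos[seq_len(min(k, length(pos)))]
  pts <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), nrow = length(keep))
  for (c0 in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, c0]) > 1e-9)
    if (length(nz) && pts[nz[1L], c0] < 0) pts[, c0] <- -pts[, c0]
  }
  dimnames(pts) <- list(labels, paste0("C", seq_along(keep)))
  new("MdsEmbedding", labels = labels, points = pts,
      eigenvalues = eig$values,
      explained = eig$values[keep] / sum(eig$values[pos]))
}

#' @rdname classicalMds
#' @param x an \code{MdsEmbedding}.
#' @export
mdsPoints <- function(x) x@points

#' @rdname classicalMds
#' @export
mdsEigenvalues <- function(x) x@eigenvalues

## ---- evolutionary trace ----------------------------------------------

.childrenList <- function(tree) {
  n <- length(tree$tip.label)
  kids <- vector("list", n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]],
                                  tree$edge[i, 2L])
  kids
}

.tipsBelow <- function(tree, node, kids) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (v <= n) out <- c(out, tree$tip.label[v])
    else stack <- c(stack, kids[[v]])
  }
  out
}

#' Evolutionary-trace residue classing
#'
#' For each partition level p = 1..P, the rooted tree is cut by
#' "opening" the p-1 internal nodes closest to the root (node height,
#' ties by node index): opening a node replaces its group with its child
#' subtrees. Each alignment column is then classified against the
#' resulting grouping with the semantics of
#' \code{\link{findClassSpecificColumns}} (at level 1 there is a single
#' group, so no column can be class-specific). A column conserved at
#' level 1 is conserved at every level.
#'
#' @param msa a \code{\linkS4class{ProteinMsa}}; row ids must equal the
#'   tree's tip labels.
#' @param tree a rooted \code{phylo} (root on the designated outgroup
#'   before calling).
#' @param levels number of partition levels P (default 10; capped at the
#'   number of achievable groups).
#' @return a \code{\linkS4class{TraceResult}}.
#' @export
evolutionaryTrace <- function(msa, tree, levels = 10L) {
  stopifnot(is(msa, "ProteinMsa"))
  if (!ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  if (!setequal(tree$tip.label, msaIds(msa)))
    stop("tree tips and alignment rows differ", call. = FALSE)
  n <- length(tree$tip.label)
  kids <- .childrenList(tree)
  depth <- ape::node.depth.edgelength(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  internal <- internal[order(depth[internal], internal)]
  m <- msaMatrix(msa)
  classifyCols <- function(groups) {
    vapply(seq_len(ncol(m)), function(j) {
      col <- m[, j]
      if (any(col == "-")) return("gapped")
      if (length(unique(col)) == 1L) return("conserved")
      if (length(groups) < 2L) return("unconserved")
      per <- vapply(groups, function(g) {
        u <- unique(col[g])
        if (length(u) == 1L) u else NA_character_
      }, "")
      if (anyNA(per)) return("unconserved")
      if (length(unique(per)) >= 2L) "class-specific" else "unconserved"
    }, "")
  }
  lvls <- list()
  maxLevels <- min(levels, length(internal) + 1L)
  for (p in seq_len(maxLevels)) {
    opened <- internal[seq_len(p - 1L)]
    # group of a leaf = subtree rooted at the first unopened node on the
    # root-to-leaf path
    groupNodes <- integer(0)
    collect <- function(node) {
      if (!(node %in% opened)) {
        groupNodes <<- c(groupNodes, node)
      } else {
        for (ch in kids[[node]]) collect(ch)
      }
    }
    collect(n + 1L)
    groups <- lapply(groupNodes, function(g) .tipsBelow(tree, g, kids))
    names(groups) <- paste0("g", seq_along(groups))
    lvls[[p]] <- list(groups = groups, classes = classifyCols(groups))
  }
  new("TraceResult", levels = lvls, ids = msaIds(msa))
}

#' @rdname evolutionaryTrace
#' @param trace a \code{TraceResult}.
#' @param level partition level.
#' @export
traceClasses <- function(trace, level) {
  stopifnot(is(trace, "TraceResult"))
  if (level < 1L || level > length(trace@levels))
    stop("no such trace level", call. = FALSE)
  trace@levels[[level]]$classes
}

#' @rdname evolutionaryTrace
#' @export
traceGroups <- function(trace, level) {
  stopifnot(is(trace, "TraceResult"))
  trace@levels[[level]]$groups
}
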