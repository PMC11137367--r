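## Candidate-enzyme selection: seed-identity filtering, CD-HIT-style
## greedy identity clustering, neighbor joining, and per-clade medoid
## representatives.

.asCharSeqs <- function(x, what = "sequences") {
  if (is(x, "XStringSet")) {
    chr <- as.character(x)
    if (is.null(names(chr))) names(chr) <- paste0("seq", seq_along(chr))
    chr
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x
  } else stop(what, " must be a character vector or XStringSet",
              call. = FALSE)
}

#' Global pairwise identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, linear gap
#' penalty -1 per residue, end gaps penalized) maximizing first the score
#' and then, among score-optimal alignments, the number of identical
#' aligned positions. Identity is identical positions divided by the
#' length of the *shorter* sequence (the CD-HIT convention; this choice
#' changes membership near thresholds and is therefore stated here).
#'
#' @param a,b single sequences (character or XString(Set)).
#' @return identity fraction in `[0, 1]`.
#' @examples
#' globalIdentity("AAAA", "AATA")  # 0.75
#' @export
globalIdentity <- function(a, b) {
  if (is(a, "XStringSet")) a <- as.character(a)[1]
  if (is(b, "XStringSet")) b <- as.character(b)[1]
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  r <- .nw_identity_cpp(a, b)
  r$matches / min(nchar(a), nchar(b))
}

#' Pairwise identity matrix
#'
#' @param seqs named character vector or XStringSet.
#' @return symmetric matrix of [globalIdentity()] values, unit diagonal.
#' @export
identityMatrix <- function(seqs) {
  s <- .asCharSeqs(seqs)
  n <- length(s)
  m <- diag(1, n)
  dimnames(m) <- list(names(s), names(s))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- globalIdentity(s[i], s[j])
  m
}

#' Filter candidates by identity to a seed sequence
#'
#' Keeps candidates whose global identity to the seed is *strictly*
#' greater than `minIdentity` (the selection rule is "more than" the
#' cutoff, so a candidate exactly at the cutoff is dropped).
#'
#' @param seed a single sequence.
#' @param candidates named character vector or XStringSet.
#' @param minIdentity cutoff (default 0.45).
#' @return an [Biostrings::AAStringSet] of the retained candidates, with
#'   the realized identities in `metadata()$identity_to_seed`.
#' @export
filterByIdentity <- function(seed, candidates, minIdentity = 0.45) {
  cand <- .asCharSeqs(candidates, "candidates")
  if (is(seed, "XStringSet")) seed <- as.character(seed)[1]
  seed <- as.character(seed)
  idn <- vapply(cand, function(s) globalIdentity(seed, s), numeric(1))
  keep <- idn > minIdentity
  out <- Biostrings::AAStringSet(cand[keep])
  S4Vectors::metadata(out)$identity_to_seed <- idn[keep]
  out
}

#' Greedy incremental identity clustering (CD-HIT style)
#'
#' Sequences are sorted by length descending (ties: id, C-locale); each
#' sequence joins the first existing cluster whose *representative* has
#' identity >= `threshold` to it, else founds a new cluster. The
#' representative is therefore always the longest member (ties broken by
#' id). Clusters are returned in founding order.
#'
#' @param seqs named character vector or XStringSet.
#' @param threshold identity cutoff (default 0.75).
#' @return data.frame with one row per member: `cluster_id` (1-based,
#'   founding order), `representative`, `member`, `identity_to_rep`.
#' @export
greedyCluster <- function(seqs, threshold = 0.75) {
  s <- .asCharSeqs(seqs)
  if (length(s) < 1L) stop("need at least one sequence", call. = FALSE)
  ord <- order(-nchar(s), names(s), method = "radix")
  s <- s[ord]
  repIdx <- integer()          # index (into s) of each cluster rep
  rows <- vector("list", length(s))
  for (k in seq_along(s)) {
    placed <- FALSE
    for (ci in seq_along(repIdx)) {
      idn <- globalIdentity(s[repIdx[ci]], s[k])
      if (idn >= threshold) {
        rows[[k]] <- data.frame(cluster_id = ci,
                                representative = names(s)[repIdx[ci]],
                                member = names(s)[k],
                                identity_to_rep = idn,
                                stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      repIdx <- c(repIdx, k)
      rows[[k]] <- data.frame(cluster_id = length(repIdx),
                              representative = names(s)[k],
                              member = names(s)[k], identity_to_rep = 1,
                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df[order(df$cluster_id, df$member != df$representative, df$member,
           method = "radix"), , drop = FALSE]
}

#' Neighbor-joining tree from a distance matrix
#'
#' The classical agglomerative neighbor-joining algorithm, which exactly
#' recovers the generating tree (topology and branch lengths) from any
#' additive distance matrix. Pair selection ties are broken by matrix
#' order, so identical inputs give byte-identical newick output. Negative
#' branch-length estimates are clamped to 0 with a note.
#'
#' @param d symmetric numeric matrix with zero diagonal, labeled dimnames,
#'   size >= 3. For protein sets the conventional distance is
#'   `1 - identityMatrix(seqs)`.
#' @return an [ape] `phylo` (unrooted).
#' @export
njTree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3L)
    stop("d must be a square matrix of size >= 3", call. = FALSE)
  if (is.null(rownames(d)))
    stop("d must have labeled dimnames", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12))
    stop("d must be symmetric with a zero diagonal", call. = FALSE)
  lab <- rownames(d)
  clamped <- FALSE
  bl <- function(v) {
    if (v < 0) { clamped <<- TRUE; 0 } else v
  }
  fmt <- function(v) sprintf("%.12g", v)
  nodes <- lab                        # newick fragment per active node
  D <- d
  while (length(nodes) > 3L) {
    N <- length(nodes)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE]   # deterministic tie
    i <- min(k[1, ]); j <- max(k[1, ])
    vi <- bl(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (N - 2)))
    vj <- bl(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (N - 2))))
    newNode <- paste0("(", nodes[i], ":", fmt(vi), ",",
                      nodes[j], ":", fmt(vj), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(N), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newNode)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }
  ## closed-form star join of the last three nodes
  va <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", nodes[1], ":", fmt(va), ",", nodes[2], ":", fmt(vb),
                ",", nodes[3], ":", fmt(vc), ");")
  if (clamped)
    message("njTree: negative branch length estimate(s) clamped to 0")
  ape::read.tree(text = nwk)
}

## leaf partitions obtained by cutting edges of a phylo tree
.leafGroups <- function(tree, cutEdges) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  keep <- setdiff(seq_len(nrow(tree$edge)), cutEdges)
  adj <- vector("list", nn)
  for (e in keep) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(nn)
  cid <- 0L
  for (v in seq_len(nn)) {
    if (comp[v]) next
    cid <- cid + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[u]) next
      comp[u] <- cid
      stack <- c(stack, adj[[u]][comp[adj[[u]]] == 0L])
    }
  }
  split(tree$tip.label, comp[seq_len(nt)])
}

#' Pick one representative per tree branch
#'
#' Cuts the tree's longest internal edges (then, if more partitions are
#' needed than internal edges can provide, the longest terminal edges)
#' until the leaves fall into `nGroups` groups, then returns the medoid of
#' each group: the leaf with the smallest mean tree (patristic) distance
#' to the other leaves of its group. Ties are broken by edge order and
#' lexicographic leaf id.
#'
#' @param tree an [ape] `phylo` with branch lengths.
#' @param nGroups number of groups (default 5, the number of evolutionary
#'   branches used when picking screening candidates).
#' @return character vector of `nGroups` leaf labels, one per group, in
#'   group order along the tree.
#' @export
pickRepresentatives <- function(tree, nGroups = 5L) {
  stopifnot(inherits(tree, "phylo"))
  nGroups <- as.integer(nGroups)
  nt <- length(tree$tip.label)
  if (nGroups < 1L) stop("nGroups must be >= 1", call. = FALSE)
  if (nGroups > nt) stop("nGroups exceeds leaf count", call. = FALSE)
  isInternal <- tree$edge[, 2] > nt
  len <- tree$edge.length
  ord <- c(which(isInternal)[order(-len[isInternal])],
           which(!isInternal)[order(-len[!isInternal])])
  cut <- integer()
  groups <- .leafGroups(tree, cut)
  for (e in ord) {
    if (length(groups) >= nGroups) break
    trial <- .leafGroups(tree, c(cut, e))
    if (length(trial) > length(groups)) {  # each cut adds at most 1 group
      cut <- c(cut, e)
      groups <- trial
    }
  }
  if (length(groups) != nGroups)
    stop("could not partition tree into ", nGroups, " leaf groups",
         call. = FALSE)
  D <- ape::cophenetic.phylo(tree)
  reps <- vapply(groups, function(g) {
    md <- colMeans(D[g, g, drop = FALSE])
    g[order(md, g, method = "radix")][1]
  }, character(1))
  unname(reps)
}

#' End-to-end homolog screening pipeline
#'
#' [filterByIdentity()] against the seed, [greedyCluster()] of the
#' survivors, an [njTree()] on `1 - identity` between cluster
#' representatives, and [pickRepresentatives()] per tree branch.
#'
#' @param seed the reference protein (e.g. a Ku protein seed).
#' @param candidates candidate homologs (named).
#' @param minSeedIdentity strict lower identity bound vs the seed
#'   (default 0.45).
#' @param clusterThreshold greedy clustering cutoff (default 0.75).
#' @param nGroups branches to pick representatives from (default 5).
#' @return list with `filtered` (AAStringSet), `clusters` (data.frame),
#'   `tree` (`phylo`), `representatives` (character).
#' @export
selectHomologs <- function(seed, candidates, minSeedIdentity = 0.45,
                           clusterThreshold = 0.75, nGroups = 5L) {
  filt <- filterByIdentity(seed, candidates, minSeedIdentity)
  if (length(filt) < 1L)
    stop("no candidates above the seed identity cutoff", call. = FALSE)
  clusters <- greedyCluster(filt, clusterThreshold)
  repIds <- unique(clusters$representative)
  if (length(repIds) < 3L)
    stop("need >= 3 clusters to build a tree; lower clusterThreshold or ",
         "supply more candidates", call. = FALSE)
  reps <- filt[repIds]
  d <- 1 - identityMatrix(reps)
  tree <- njTree(d)
  list(filtered = filt, clusters = clusters, tree = tree,
       representatives = pickRepresentatives(tree,
                                             min(nGroups, length(repIds))))
}
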