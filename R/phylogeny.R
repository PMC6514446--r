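#' Build a pairwise distance matrix under a substitution model
#'
#' All-pairs model-corrected distances with pairwise deletion of gap/N
#' columns. If any pair is saturated (correction undefined) the matrix cannot
#' feed tree building, so an error lists the offending pairs.
#'
#' @param sequences Named character vector of aligned sequences (equal
#'   length), or a [region_alignment()].
#' @param model `"JC69"` (default), `"K2P"` or `"p"`.
#' @return A symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
build_distance_matrix <- function(sequences, model = c("JC69", "K2P", "p")) {
  model <- match.arg(model)
  if (inherits(sequences, "region_alignment")) {
    sequences <- setNames(sequences$haplotypes$sequence,
                          sequences$haplotypes$haplotype_id)
  }
  n <- length(sequences)
  if (n < 3) stop("need at least 3 sequences", call. = FALSE)
  labs <- names(sequences)
  if (is.null(labs) || anyDuplicated(labs)) {
    stop("sequences must have unique names", call. = FALSE)
  }
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  saturated <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      est <- pair_distance(sequences[[i]], sequences[[j]], model)
      if (!est$valid) {
        saturated <- c(saturated, paste(labs[i], labs[j], sep = "/"))
      } else {
        m[i, j] <- m[j, i] <- est$d
      }
    }
  }
  if (length(saturated)) {
    stop("saturated pairs (distance undefined): ",
         paste(saturated, collapse = ", "), call. = FALSE)
  }
  m
}

#' Neighbor-joining tree
#'
#' Classic agglomerative neighbor joining: iteratively join the pair
#' minimising `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with
#' branch lengths from the standard two-point formulas and the joined pair
#' replaced by a node at distance `(d(i,k) + d(j,k) - d(i,j)) / 2` from every
#' other taxon. On an additive matrix this recovers the generating tree and
#' branch lengths exactly.
#'
#' Conventions: ties in the Q minimisation are broken by the
#' lexicographically smallest label pair (so the result is independent of
#' input order), and negative branch lengths are clamped to zero with the
#' deficit moved to the sibling branch so path lengths are preserved.
#'
#' @param dm Symmetric distance matrix with labelled dimnames (or a `dist`).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  # working node set: newick fragment per active node, keyed by the smallest
  # original label in the subtree (used for deterministic tie-breaking)
  frag <- labs
  key <- labs
  d <- dm
  while (length(frag) > 3) {
    m <- length(frag)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    if (nrow(best) > 1) {
      pair_key <- apply(best, 1, function(ij) {
        ks <- sort(c(key[ij[1]], key[ij[2]]))
        paste(ks, collapse = "\r")
      })
      best <- best[order(pair_key)[1], , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    new_key <- min(key[i], key[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }
  # resolve the final three nodes around the central (trifurcating) node
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  ord <- order(key)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[ord[1]], lens[ord[1]],
                 frag[ord[2]], lens[ord[2]],
                 frag[ord[3]], lens[ord[3]])
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge, the
#' conventional display for trees whose outgroup is a single taxon. Rooting
#' an already correctly rooted tree is a no-op.
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup Leaf label to root on.
#' @return A rooted `ape::phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a leaf of the tree",
         call. = FALSE)
  }
  tip <- match(outgroup, tree$tip.label)
  root_node <- ape::Ntip(tree) + 1L
  if (ape::is.rooted(tree)) {
    kids <- tree$edge[tree$edge[, 1] == root_node, 2]
    if (tip %in% kids && length(kids) == 2) return(tree)
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root_node <- ape::Ntip(rooted) + 1L
  root_edges <- which(rooted$edge[, 1] == root_node)
  total <- sum(rooted$edge.length[root_edges])
  rooted$edge.length[root_edges] <- total / 2
  rooted
}

#' Is a set of leaves monophyletic?
#'
#' TRUE when some clade of the rooted tree contains exactly the given leaves.
#'
#' @param tree A rooted `ape::phylo` tree.
#' @param leaves Character vector of leaf labels (non-empty, all present).
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(leaves)) stop("empty leaf set", call. = FALSE)
  leaves <- unique(leaves)
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing)) {
    stop("unknown leaves: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (length(leaves) == 1) return(TRUE)
  target <- sort(leaves)
  clades <- ape::prop.part(tree)
  labs <- attr(clades, "labels")
  for (cl in clades) {
    if (length(cl) == length(target) &&
        identical(sort(labs[cl]), target)) {
      return(TRUE)
    }
  }
  FALSE
}
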