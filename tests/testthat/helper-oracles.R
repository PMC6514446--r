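# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force two-sided exact binomial p-value: enumerate all outcomes and
# sum the probabilities of those no more likely than the observed count
brute_force_binom <- function(k, n, p0, rel_tol = 1e-7) {
  probs <- dbinom(0:n, n, p0)
  target <- probs[k + 1] * (1 + rel_tol)
  sum(probs[probs <= target])
}

# vectorised over all k for one (n, p0): returns p-values for k = 0..n
brute_force_binom_all_k <- function(n, p0, rel_tol = 1e-7) {
  probs <- dbinom(0:n, n, p0)
  inc <- outer(probs, probs * (1 + rel_tol), "<=")
  colSums(probs * inc)
}

# exhaustive-topology least-squares oracle: find the unrooted topology (over
# all of them, via phangorn::allTrees) whose least-squares branch lengths
# reproduce the distance matrix with zero residual; returns the fitted tree
ls_tree_oracle <- function(dm) {
  labs <- rownames(dm)
  n <- length(labs)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  pairs <- t(combn(seq_len(n), 2))
  best <- NULL
  for (ti in seq_along(topos)) {
    topo <- topos[[ti]] # [[ reattaches tip labels on a compressed multiPhylo
    ne <- nrow(topo$edge)
    X <- matrix(0, nrow(pairs), ne)
    for (r in seq_len(nrow(pairs))) {
      np <- ape::nodepath(topo, pairs[r, 1], pairs[r, 2])
      for (s in seq_len(length(np) - 1)) {
        e <- which((topo$edge[, 1] == np[s] & topo$edge[, 2] == np[s + 1]) |
                     (topo$edge[, 2] == np[s] & topo$edge[, 1] == np[s + 1]))
        X[r, e] <- 1
      }
    }
    y <- dm[pairs]
    fit <- stats::lm.fit(X, y)
    if (sum(fit$residuals^2) < 1e-18 && all(fit$coefficients > -1e-9)) {
      topo$edge.length <- pmax(fit$coefficients, 0)
      best <- c(best, list(topo))
    }
  }
  stopifnot(length(best) == 1) # additive matrices have a unique tree
  best[[1]]
}

# random additive distance matrix from a random unrooted binary tree
random_additive_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE,
                     tip.label = paste0("t", seq_len(n)))
    tr$edge.length <- runif(nrow(tr$edge), 0.5, 3)
    dm <- as.matrix(ape::cophenetic.phylo(tr))
    dm <- dm[order(rownames(dm)), order(colnames(dm))]
    list(tree = tr, dm = dm)
  })
}

# path-distance check: tree reproduces the matrix
tree_matches_matrix <- function(tree, dm, tol = 1e-9) {
  cd <- as.matrix(ape::cophenetic.phylo(tree))
  cd <- cd[rownames(dm), colnames(dm)]
  max(abs(cd - dm)) < tol
}

# same unrooted topology?
same_topology <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))) == 0
}
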