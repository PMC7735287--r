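# D statistic for phylogenetic signal in a binary trait (sister-clade sum
# of nodal contrasts, calibrated against label permutation and a
# threshold-Brownian process). Values near 1 indicate phylogenetically
# random placement; near 0, Brownian-like clumping.

# sister-clade contrast sum for each column of a tips-by-replicates matrix:
# nodal values are daughter means computed tips-down; d is the summed
# absolute difference between the two daughters at every internal node
d_sister_sum <- function(tree, M) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  R <- ncol(M)
  vals <- matrix(0, nn, R)
  vals[seq_len(ntip), ] <- M
  d <- numeric(R)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  # group consecutive edges sharing a parent (postorder lists them together)
  i <- 1L
  ne <- nrow(po)
  while (i <= ne) {
    p <- po[i, 1L]
    j <- i
    while (j < ne && po[j + 1L, 1L] == p) j <- j + 1L
    ch <- po[i:j, 2L]
    if (length(ch) != 2L) stop("D statistic requires a binary tree")
    d <- d + abs(vals[ch[1L], ] - vals[ch[2L], ])
    vals[p, ] <- (vals[ch[1L], ] + vals[ch[2L], ]) / 2
    i <- j + 1L
  }
  d
}

#' D statistic for a binary trait on a phylogeny
#'
#' Computes the observed sister-clade contrast sum of the 0/1 trait and
#' scales it between the expectation under random label permutation
#' (D = 1) and under a threshold-Brownian process with matching prevalence
#' (D = 0).
#'
#' @param tree a binary `phylo` object (e.g. a clade-level tree).
#' @param flags named 0/1 (or logical) vector over tips; both states must
#'   be present.
#' @param n_perm number of permutation and Brownian replicates (default
#'   1000).
#' @param seed optional integer seed.
#' @return an object of class `d_stat` with fields `D`, `p_random`
#'   (fraction of permutations with d <= observed), `p_brownian` (fraction
#'   of threshold-BM replicates with d >= observed) and `n_perm`.
#' @export
d_statistic <- function(tree, flags, n_perm = 1000, seed = NULL) {
  validate_tree(tree)
  flags <- align_trait(as.numeric(flags), tree)
  if (!all(flags %in% c(0, 1))) stop("flags must be binary 0/1")
  k1 <- sum(flags)
  if (k1 == 0 || k1 == length(flags)) {
    stop("both states must be present among the tips")
  }
  ntip <- length(flags)
  with_local_seed(seed, {
    d_obs <- d_sister_sum(tree, matrix(flags, ncol = 1))
    perm <- vapply(seq_len(n_perm), function(i) sample(flags),
                   numeric(ntip))
    d_perm <- d_sister_sum(tree, perm)
    # threshold-Brownian: unit-rate BM values binarized so that each
    # replicate matches the observed prevalence (top-k tips scored 1)
    bm <- sim_gaussian(tree, model_spec("BM", sig2 = 1), NULL, n_perm)
    thr <- apply(bm, 2L, function(v) {
      as.numeric(rank(-v, ties.method = "first") <= k1)
    })
    d_bm <- d_sister_sum(tree, thr)
    D <- (d_obs - mean(d_bm)) / (mean(d_perm) - mean(d_bm))
    structure(list(D = D,
                   p_random = mean(d_perm <= d_obs),
                   p_brownian = mean(d_bm >= d_obs),
                   n_perm = n_perm, d_obs = d_obs,
                   mean_d_random = mean(d_perm),
                   mean_d_brownian = mean(d_bm)),
              class = "d_stat")
  })
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("D = %.4f  (P[random structure] = %.3f, P[Brownian] = %.3f, %d replicates)\n",
              x$D, x$p_random, x$p_brownian, x$n_perm))
  invisible(x)
}

#' Collapse named clades to single tips
#'
#' Replaces each clade (a group of tips) by one representative tip labelled
#' with the clade identifier, producing the clade-level tree used for
#' across-clade signal analyses. The representative's pendant edge runs
#' from the clade's stem attachment point to the present.
#'
#' @param tree a `phylo` object.
#' @param membership named character vector mapping every tip to a clade id.
#' @return a `phylo` tree with one tip per clade.
#' @export
collapse_clades <- function(tree, membership) {
  membership <- membership[tree$tip.label]
  if (anyNA(membership)) stop("every tip needs a clade id")
  reps <- tapply(tree$tip.label, membership, `[`, 1L)
  out <- ape::keep.tip(tree, unname(reps))
  out$tip.label <- names(reps)[match(out$tip.label, reps)]
  out
}
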