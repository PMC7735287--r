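# Trait simulation under every model. Gaussian-increment models (BM, OU,
# TD, DD) are simulated exactly branch by branch; the matching competition
# model uses Euler-Maruyama on a shared global time grid because lineages
# are coupled through the running group means.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate tip traits under a trait-evolution model
#'
#' @param tree a `phylo` object (ultrametric for DD and MC models).
#' @param spec a [model_spec()].
#' @param regimes a `regime_map`; required when `spec$structured` is `TRUE`,
#'   optional for unstructured MC (then all coexisting lineages interact).
#' @param seed optional integer; when given the call is reproducible and
#'   leaves the global RNG state untouched.
#' @param nsim number of independent replicate datasets.
#' @param n_steps MC discretization: number of Euler steps spanning the tree
#'   depth (default 2000); refined automatically so that `|S| * h <= 0.01`.
#' @param method `"exact"` Gaussian branch increments where available, or
#'   `"euler"` to force BM onto the same discretized path as MC (useful for
#'   checking the `S = 0` reduction pathwise).
#' @return a named tip vector (`nsim = 1`) or a tips-by-replicates matrix.
#' @export
simulate_trait <- function(tree, spec, regimes = NULL, seed = NULL,
                           nsim = 1, n_steps = 2000,
                           method = c("exact", "euler")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "model_spec"))
  if (spec$structured && is.null(regimes)) {
    stop("a regime map is required for a structured model spec")
  }
  if (spec$name %in% c("DDlin", "DDexp", "MC")) {
    validate_tree(tree, ultrametric = TRUE)
  } else {
    validate_tree(tree)
  }
  out <- with_local_seed(seed, {
    if (spec$name == "MC" || method == "euler") {
      if (method == "euler" && !spec$name %in% c("BM", "MC")) {
        stop("euler discretization is only supported for BM and MC")
      }
      sim_euler(tree, spec, regimes, nsim, n_steps)
    } else {
      sim_gaussian(tree, spec, regimes, nsim)
    }
  })
  rownames(out) <- tree$tip.label
  if (nsim == 1) setNames(out[, 1L], tree$tip.label) else out
}

# exact branch-increment simulation for the Gaussian-family models
sim_gaussian <- function(tree, spec, regimes, nsim) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  nt <- node_times(tree)
  edge <- tree$edge
  ord <- rev(ape::postorder(tree))  # preorder: parents before children
  Z <- matrix(0, nn, nsim)
  Z[ntip + 1L, ] <- spec$z0

  if (spec$name == "OU" && spec$alpha >= 1e-12) {
    a <- spec$alpha
    for (ei in ord) {
      p <- edge[ei, 1L]; ch <- edge[ei, 2L]; len <- tree$edge.length[ei]
      f <- exp(-a * len)
      sdv <- sqrt(spec$sig2 / (2 * a) * (1 - exp(-2 * a * len)))
      Z[ch, ] <- spec$z0 + (Z[p, ] - spec$z0) * f + rnorm(nsim, 0, sdv)
    }
  } else {
    ev <- edge_variances(tree, spec, regimes, nt, edge)
    for (ei in ord) {
      p <- edge[ei, 1L]; ch <- edge[ei, 2L]
      Z[ch, ] <- Z[p, ] + if (ev[ei] > 0) rnorm(nsim, 0, sqrt(ev[ei])) else 0
    }
  }
  Z[seq_len(ntip), , drop = FALSE]
}

# per-edge variance increments: integral of the effective rate over the edge
edge_variances <- function(tree, spec, regimes, nt, edge) {
  t0 <- nt[edge[, 1L]]
  t1 <- nt[edge[, 2L]]
  if (spec$name %in% c("BM", "OU")) {
    return(spec$sig2 * (t1 - t0))
  }
  if (spec$name %in% c("TDlin", "TDexp")) {
    R <- switch(spec$name,
      TDlin = function(t) spec$sig2 * t + spec$slope_t * t^2 / 2,
      TDexp = if (abs(spec$rate_t) < 1e-12) {
        function(t) spec$sig2 * t
      } else {
        function(t) spec$sig2 * (exp(spec$rate_t * t) - 1) / spec$rate_t
      })
    v <- R(t1) - R(t0)
    if (any(v < 0)) stop("rate integral negative; parameters out of domain")
    return(v)
  }
  # DD models
  if (is.null(regimes)) {
    lc <- lineage_count(tree)
    v <- switch(spec$name,
      DDlin = spec$sig2 * (t1 - t0) +
        spec$slope_n * (cum_lineage_integral(lc, t1) -
                        cum_lineage_integral(lc, t0)),
      DDexp = spec$sig2 * (v0_ddexp_unstr(t1, lc, spec$rate_n) -
                           v0_ddexp_unstr(t0, lc, spec$rate_n)))
  } else {
    rg <- regime_grid(regimes)
    v <- vapply(seq_len(nrow(edge)), function(ei) {
      js <- which(!is.na(rg$SM[ei, ]))
      if (!length(js)) return(0)
      k <- rg$counts[cbind(rg$SM[ei, js], js)]
      switch(spec$name,
        DDlin = sum((spec$sig2 + spec$slope_n * k) * rg$lens[js]),
        DDexp = sum(spec$sig2 * exp(spec$rate_n * k) * rg$lens[js]))
    }, numeric(1))
  }
  if (any(v < 0)) stop("rate integral negative; parameters out of domain")
  v
}

# Euler-Maruyama on the shared event mesh; drift S * (group mean - self)
sim_euler <- function(tree, spec, regimes, nsim, n_steps) {
  S <- if (spec$name == "MC") spec$S else 0
  if (is.null(regimes)) regimes <- single_regime_map(tree)
  rg <- regime_grid(regimes)
  mesh <- mc_mesh(rg)
  T <- rg$depth
  h_base <- T / n_steps
  if (S != 0) h_base <- min(h_base, 0.01 / abs(S))
  Z <- matrix(0, 2, nsim)
  for (j in seq_along(mesh$steps)) {
    st <- mesh$steps[[j]]
    if (st$h > 0) {
      m <- max(1L, ceiling(st$h / h_base))
      hs <- st$h / m
      noise_sd <- sqrt(spec$sig2 * hs)
      for (s in seq_len(m)) {
        if (S != 0) {
          mu <- rowsum(Z, st$g) / st$sz
          Z <- Z + S * hs * (mu[st$g, , drop = FALSE] - Z)
        }
        Z <- Z + matrix(rnorm(nrow(Z) * nsim, 0, noise_sd), nrow(Z), nsim)
      }
    }
    for (p in mesh$splits[[j]]) {
      Z <- rbind(Z, Z[p, ])
    }
  }
  spec$z0 + Z[mesh$tip_perm, , drop = FALSE]
}
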