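# Exact tip means and covariances under every model, and the Gaussian
# log-likelihood. All models are Gaussian on the tips:
#   x ~ N(z0 * 1, sig2 * V0(theta))
# where V0 is a unit-rate structure matrix depending only on the tree, the
# model's shape parameter and (for structured models) the regime map. The
# scale property is what lets fitting profile sig2 and z0 analytically.

#' Tip moments container
#'
#' @param mean numeric tip mean vector.
#' @param cov symmetric positive-semidefinite tip covariance matrix.
#' @return an object of class `tip_moments`.
#' @export
tip_moments <- function(mean, cov) {
  stopifnot(is.numeric(mean), is.matrix(cov),
            length(mean) == nrow(cov), nrow(cov) == ncol(cov))
  rel <- max(abs(cov - t(cov)))
  scale <- max(abs(cov), 1e-300)
  if (rel > 1e-10 * scale) stop("covariance is not symmetric")
  cov <- (cov + t(cov)) / 2
  structure(list(mean = mean, cov = cov), class = "tip_moments")
}

#' @export
print.tip_moments <- function(x, ...) {
  cat("Tip moments over", length(x$mean), "tips; trace(cov) =",
      format(sum(diag(x$cov))), "\n")
  invisible(x)
}

# ---- unit-rate structure matrices ---------------------------------------
# C is the shared-time matrix t_ij (diag = tip times), T the tree depth.

v0_ou <- function(C, T, alpha) {
  if (alpha < 1e-12) return(C)
  exp(-2 * alpha * (T - C)) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
}

v0_tdlin <- function(C, cc) C + cc * C * C / 2

v0_tdexp <- function(C, r) {
  if (abs(r) < 1e-12) return(C + r * C * C / 2)
  (exp(r * C) - 1) / r
}

# cumulative integral of exp(r * n(u)) for an unstructured lineage count
v0_ddexp_unstr <- function(C, lc, r) {
  bp <- lc$breakpoints
  ends <- c(bp[-1L], lc$depth)
  w <- exp(r * lc$counts)
  cum <- c(0, cumsum(w * (ends - bp)))
  idx <- findInterval(C, bp, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  out <- cum[idx] + w[idx] * (C - bp[idx])
  dim(out) <- dim(C)
  out
}

# context of tree- and regime-level precomputations shared by moments and
# fitting; building it once per (tree, map) makes likelihood evaluation
# cheap inside optimizers and simulation studies
tree_ctx <- function(tree, regimes = NULL, need = c("all", "independent")) {
  need <- match.arg(need)
  validate_tree(tree)
  C <- ape::vcv(tree)
  ctx <- list(tree = tree, C = C, T = tree_depth(tree),
              n = ape::Ntip(tree),
              ultrametric = is_ultrametric_tol(tree))
  if (need == "independent") return(ctx)
  if (is.null(regimes)) {
    ctx$lc <- lineage_count(tree)
    ctx$Nmat <- cum_lineage_integral(ctx$lc, C)
    ctx$count_range <- range(ctx$lc$counts)
    ctx$mesh <- mc_mesh(regime_grid(single_regime_map(tree)))
  } else {
    stopifnot(inherits(regimes, "regime_map"))
    rg <- regime_grid(regimes)
    ctx$rg <- rg
    D <- node_path_integrals(rg)
    ctx$D <- D
    ctx$mrca <- ape::mrca(tree)
    Ln <- as.numeric(D %*% seq_len(ncol(D)))
    ctx$Lmat <- matrix(Ln[ctx$mrca], ctx$n, ctx$n)
    ctx$count_range <- range(rg$counts[rg$counts > 0L])
    ctx$mesh <- mc_mesh(rg)
  }
  ctx
}

# unit-rate covariance for any model given a context
cov_unit <- function(ctx, name, theta) {
  switch(name,
    BM = ctx$C,
    OU = {
      if (!ctx$ultrametric) stop("OU requires an ultrametric tree")
      v0_ou(ctx$C, ctx$T, theta)
    },
    TDlin = v0_tdlin(ctx$C, theta),
    TDexp = v0_tdexp(ctx$C, theta),
    DDlin = {
      if (is.null(ctx$Lmat)) ctx$C + theta * ctx$Nmat
      else ctx$C + theta * ctx$Lmat
    },
    DDexp = {
      if (is.null(ctx$D)) v0_ddexp_unstr(ctx$C, ctx$lc, theta)
      else {
        v <- as.numeric(ctx$D %*% exp(theta * seq_len(ncol(ctx$D))))
        matrix(v[ctx$mrca], ctx$n, ctx$n)
      }
    },
    MC = mc_cov_unit(ctx$mesh, theta),
    stop("unknown model ", name))
}

# ---- public moments operations ------------------------------------------

#' Tip moments under independent-evolution models
#'
#' Closed-form tip mean and covariance for BM, OU and the time-dependent
#' rate models. OU uses the root-conditioned, non-stationary form and
#' requires an ultrametric tree.
#'
#' @param tree a `phylo` object.
#' @param spec a [model_spec()] with name in `BM`, `OU`, `TDlin`, `TDexp`.
#' @return a [tip_moments()] object.
#' @export
moments_independent <- function(tree, spec) {
  stopifnot(inherits(spec, "model_spec"),
            spec$name %in% INDEPENDENT_MODELS)
  ctx <- tree_ctx(tree, need = "independent")
  theta <- switch(spec$name, BM = NULL, OU = spec$alpha,
                  TDlin = spec$slope_t / spec$sig2,
                  TDexp = spec$rate_t)
  if (spec$name == "TDlin" &&
      min(spec$sig2, spec$sig2 + spec$slope_t * ctx$T) < RATE_FLOOR) {
    stop("TDlin rate falls below the admissible floor on [0, T]")
  }
  V <- spec$sig2 * cov_unit(ctx, spec$name, theta)
  tip_moments(rep(spec$z0, ctx$n), V)
}

#' Tip moments under diversity-dependent models
#'
#' Covariances are shared-path integrals of the diversity-driven rate.
#' Without a regime map the rate follows the global lineage count; with one,
#' each lineage's rate at time u uses the count of lineages sharing its
#' regime state at u, accumulated along the root-to-ancestor path.
#'
#' @param tree an ultrametric `phylo` object.
#' @param spec a [model_spec()] with name `DDlin` or `DDexp`.
#' @param n optional precomputed [lineage_count()] (unstructured case).
#' @param regimes optional `regime_map` restricting the counts.
#' @return a [tip_moments()] object.
#' @export
moments_diversity <- function(tree, spec, n = NULL, regimes = NULL) {
  stopifnot(inherits(spec, "model_spec"),
            spec$name %in% c("DDlin", "DDexp"))
  validate_tree(tree, ultrametric = TRUE)
  ctx <- tree_ctx(tree, regimes = regimes)
  if (!is.null(n) && is.null(regimes)) {
    ctx$lc <- n
    ctx$Nmat <- cum_lineage_integral(n, ctx$C)
    ctx$count_range <- range(n$counts)
  }
  if (spec$name == "DDlin") {
    cc <- spec$slope_n / spec$sig2
    if (any(1 + cc * ctx$count_range < RATE_FLOOR / spec$sig2)) {
      stop("DDlin rate falls below the admissible floor")
    }
    theta <- cc
  } else {
    theta <- spec$rate_n
  }
  V <- spec$sig2 * cov_unit(ctx, spec$name, theta)
  tip_moments(rep(spec$z0, ctx$n), V)
}

#' Tip moments under the matching competition model
#'
#' Propagates the joint covariance of all alive lineages through time.
#' Between events (branching times, regime changes) the drift matrix
#' `A = S (P - I)` is constant, with `P` the symmetric projection averaging
#' over each lineage's interaction set (same-regime coexisting lineages,
#' including itself), so the Lyapunov update is available in closed form.
#' The tip mean is identically `z0` because `P` preserves constants.
#'
#' @param tree an ultrametric `phylo` object.
#' @param spec a [model_spec()] with name `MC` and `S <= 0`.
#' @param regimes optional `regime_map`; `NULL` means all lineages interact.
#' @return a [tip_moments()] object.
#' @export
moments_mc <- function(tree, spec, regimes = NULL) {
  stopifnot(inherits(spec, "model_spec"), spec$name == "MC")
  validate_tree(tree, ultrametric = TRUE)
  ctx <- tree_ctx(tree, regimes = regimes)
  V <- spec$sig2 * cov_unit(ctx, "MC", spec$S)
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  tip_moments(rep(spec$z0, ctx$n), V)
}

#' Tip moments under any model
#'
#' Dispatcher over [moments_independent()], [moments_diversity()] and
#' [moments_mc()].
#'
#' @param tree a `phylo` object.
#' @param spec a [model_spec()].
#' @param regimes optional `regime_map` for structured models.
#' @return a [tip_moments()] object.
#' @export
model_moments <- function(tree, spec, regimes = NULL) {
  switch(spec$name,
    BM = , OU = , TDlin = , TDexp = moments_independent(tree, spec),
    DDlin = , DDexp = moments_diversity(tree, spec, regimes = regimes),
    MC = moments_mc(tree, spec, regimes = regimes))
}

# ---- Gaussian log-likelihood --------------------------------------------

# Cholesky with a single jitter retry bounded by 1e-10 * trace
chol_jitter <- function(V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    eps <- 1e-10 * sum(diag(V))
    L <- tryCatch(chol(V + diag(eps, nrow(V))), error = function(e) NULL)
    if (is.null(L)) stop("covariance is numerically indefinite")
  }
  L
}

#' Multivariate-normal log-likelihood of tip data
#'
#' @param x named (or tip-ordered) numeric trait vector.
#' @param moments a [tip_moments()] object.
#' @return the log density of `x` under `N(mean, cov)`.
#' @export
loglik_mvnorm <- function(x, moments) {
  stopifnot(inherits(moments, "tip_moments"),
            length(x) == length(moments$mean))
  if (!is.null(names(x)) && !is.null(rownames(moments$cov))) {
    x <- x[rownames(moments$cov)]
  }
  L <- chol_jitter(moments$cov)
  r <- backsolve(L, x - moments$mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}
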