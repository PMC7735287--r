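# Maximum-likelihood fitting. Every model's tip distribution is
#   x ~ N(z0 * 1, sig2 * V0(theta))
# with at most one shape parameter theta (OU: alpha; TD/DD: slope or
# exponent; MC: S). z0 is profiled by GLS and sig2 by its closed-form ML
# estimator, so the optimizer works in one dimension over documented bounds,
# seeded with Latin-hypercube start points refined by L-BFGS-B.

# Profiled log-likelihood given a unit-rate structure matrix. Fitting uses
# a strict Cholesky: parameter regions whose covariance is numerically
# indefinite (e.g. extreme matching-competition strengths, where entries
# grow like exp(2|S|t)) are rejected outright -- regularizing them would
# hand the optimizer spurious likelihood values.
profile_ll <- function(x, V0, strict = FALSE) {
  n <- length(x)
  L <- if (strict) chol(V0) else chol_jitter(V0)
  u <- backsolve(L, x, transpose = TRUE)
  w <- backsolve(L, rep(1, n), transpose = TRUE)
  z0 <- sum(w * u) / sum(w * w)
  rss <- sum((u - z0 * w)^2)
  sig2 <- rss / n
  if (sig2 <= 0) return(list(ll = -Inf, sig2 = NA_real_, z0 = z0))
  ll <- -0.5 * (n * log(2 * pi * sig2) + 2 * sum(log(diag(L))) + n)
  list(ll = ll, sig2 = sig2, z0 = z0)
}

# optimizer bounds for the 1D shape parameter, on the scale optimized over
shape_bounds <- function(name, ctx) {
  T <- ctx$T
  switch(name,
    OU = c(-10, 7),                            # log(alpha)
    TDlin = c((RATE_FLOOR - 1) / T, (1e6 - 1) / T),
    TDexp = c(log(RATE_FLOOR) / T, log(1e6) / T),
    DDlin = {
      k <- ctx$count_range
      c((RATE_FLOOR - 1) / k[2L], (1e6 - 1) / k[1L])
    },
    DDexp = {
      k <- ctx$count_range[2L]
      c(log(RATE_FLOOR) / k, log(1e6) / k)
    },
    MC = c(-50, 0))
}

# natural-scale fitted parameters from the optimized shape parameter
shape_to_params <- function(name, theta, prof) {
  p <- list(sig2 = prof$sig2, z0 = prof$z0)
  if (name == "OU") p$alpha <- exp(theta)
  if (name == "TDlin") p$slope_t <- theta * prof$sig2
  if (name == "TDexp") p$rate_t <- theta
  if (name == "DDlin") p$slope_n <- theta * prof$sig2
  if (name == "DDexp") p$rate_n <- theta
  if (name == "MC") p$S <- theta
  p
}

# deterministic seeded Latin-hypercube start points in [lo, hi]
lhs_starts <- function(n_starts, lo, hi, seed) {
  u <- with_local_seed(seed, (sample(n_starts) - runif(n_starts)) / n_starts)
  lo + u * (hi - lo)
}

fit_one <- function(x, ctx, name, n_starts, seed, bounds = NULL) {
  nllk <- function(theta) {
    V0 <- tryCatch(cov_unit(ctx, name,
                            if (name == "OU") exp(theta) else theta),
                   error = function(e) NULL)
    if (is.null(V0)) return(1e10)
    p <- tryCatch(profile_ll(x, V0, strict = TRUE),
                  error = function(e) NULL)
    if (is.null(p) || !is.finite(p$ll)) return(1e10)
    -p$ll
  }
  if (name == "BM") {
    prof <- profile_ll(x, ctx$C)
    return(list(theta = NULL, prof = prof, loglik = prof$ll,
                converged = TRUE, n_starts_used = 0L))
  }
  b <- if (is.null(bounds)) shape_bounds(name, ctx) else bounds
  run <- function(ns) {
    starts <- lhs_starts(ns, b[1L], b[2L], seed)
    vals <- vapply(starts, nllk, numeric(1))
    best <- order(vals)[seq_len(min(2L, ns))]
    fits <- lapply(starts[best], function(s0) {
      tryCatch(
        optim(s0, nllk, method = "L-BFGS-B", lower = b[1L], upper = b[2L],
              control = list(maxit = 200, factr = 1e9)),
        error = function(e) list(par = s0, value = nllk(s0),
                                 convergence = 99L))
    })
    vv <- vapply(fits, `[[`, numeric(1), "value")
    list(fit = fits[[which.min(vv)]],
         converged = any(vapply(fits, `[[`, numeric(1),
                                "convergence") == 0))
  }
  r <- run(n_starts)
  used <- n_starts
  if (!r$converged) {              # retry with a denser start set
    r <- run(2L * n_starts)
    used <- 2L * n_starts
  }
  theta <- r$fit$par
  V0 <- cov_unit(ctx, name, if (name == "OU") exp(theta) else theta)
  prof <- tryCatch(profile_ll(x, V0, strict = TRUE),
                   error = function(e) list(ll = -Inf, sig2 = NA_real_,
                                            z0 = NA_real_))
  list(theta = theta, prof = prof, loglik = prof$ll,
       converged = r$converged && is.finite(prof$ll),
       n_starts_used = used)
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Fits one of the seven models to a continuous trait on a time-calibrated
#' tree. The root state and base rate are profiled analytically; the
#' remaining shape parameter (if any) is maximized by seeded multi-start
#' quasi-Newton optimization within documented bounds. For competition
#' models a regime map (or a list of sampled maps) restricts interactions;
#' with a list, the model is fitted once per map and the map-mean AICc,
#' log-likelihood and parameters are reported with per-map results retained.
#'
#' @param tree a `phylo` object (ultrametric where the model requires it).
#' @param x named numeric trait vector over the tips.
#' @param model one of `BM`, `OU`, `TDlin`, `TDexp`, `DDlin`, `DDexp`, `MC`.
#' @param regimes `NULL`, a single `regime_map`, or a list of them.
#' @param n_starts number of Latin-hypercube start points (default 5;
#'   doubled automatically when no start converges).
#' @param seed base seed for the deterministic start points.
#' @param ctx optional precomputed context from the internal builder; used
#'   by simulation studies to amortize tree-level work across replicates.
#' @param bounds optional `c(lower, upper)` override of the shape
#'   parameter's optimizer box, on the optimized scale (log alpha for OU,
#'   the natural scale otherwise). The defaults are wide; a narrower box
#'   can emulate the constraint conventions of other comparative-methods
#'   software.
#' @return an object of class `trait_fit`.
#' @export
fit_trait_model <- function(tree, x, model = "BM", regimes = NULL,
                            n_starts = 5, seed = 1, ctx = NULL,
                            bounds = NULL) {
  model <- match.arg(model, MODEL_NAMES)
  x <- align_trait(x, tree)
  n <- length(x)
  if (n < 4) stop("at least 4 tips are required")
  k <- model_k(model)
  if (n - k - 1 <= 0) stop("n - k - 1 must be positive for AICc")

  if (is.list(regimes) && !inherits(regimes, "regime_map")) {
    fits <- lapply(seq_along(regimes), function(i) {
      f <- fit_trait_model(tree, x, model, regimes = regimes[[i]],
                           n_starts = n_starts, seed = seed,
                           bounds = bounds)
      f$map_id <- i
      f
    })
    agg <- fits[[1L]]
    agg$loglik <- mean(vapply(fits, `[[`, numeric(1), "loglik"))
    agg$aicc <- mean(vapply(fits, `[[`, numeric(1), "aicc"))
    pars <- do.call(rbind, lapply(fits, function(f) unlist(f$params)))
    agg$params <- as.list(colMeans(pars))
    agg$converged <- all(vapply(fits, `[[`, logical(1), "converged"))
    agg$map_id <- paste0("mean(", length(fits), ")")
    agg$per_map <- fits
    return(agg)
  }

  if (is.null(ctx)) {
    ctx <- if (model %in% INDEPENDENT_MODELS) {
      tree_ctx(tree, need = "independent")
    } else {
      tree_ctx(tree, regimes = regimes)
    }
  }
  if (model %in% c("OU", "DDlin", "DDexp", "MC") && !ctx$ultrametric) {
    stop(model, " requires an ultrametric tree")
  }
  r <- fit_one(x, ctx, model, n_starts, seed, bounds = bounds)
  params <- shape_to_params(model, r$theta, r$prof)
  structure(list(
    model = model,
    structured = !is.null(regimes),
    params = params,
    loglik = r$loglik,
    k = k, n = n,
    aicc = aicc(r$loglik, k, n),
    converged = r$converged,
    n_starts_used = r$n_starts_used,
    map_id = NA_character_,
    tree = tree, regimes = regimes, data = x
  ), class = "trait_fit")
}

#' Small-sample corrected Akaike information criterion
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations (tips).
#' @return `-2 loglik + 2k + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# ---- trait_fit methods ---------------------------------------------------

#' @export
print.trait_fit <- function(x, ...) {
  cat("Trait-evolution model fit: ", x$model,
      if (x$structured) " (guild-structured)" else "", "\n", sep = "")
  cat("  tips: ", x$n, "   logLik: ", format(x$loglik, digits = 6),
      "   AICc: ", format(x$aicc, digits = 6), "\n", sep = "")
  cat("  parameters: ",
      paste(names(x$params), vapply(x$params, format, "", digits = 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.trait_fit <- function(object, ...) {
  out <- c(list(model = object$model, n = object$n, k = object$k,
                loglik = object$loglik, aicc = object$aicc,
                converged = object$converged,
                n_starts_used = object$n_starts_used,
                map_id = object$map_id),
           object$params)
  class(out) <- "summary.trait_fit"
  out
}

#' @export
print.summary.trait_fit <- function(x, ...) {
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
coef.trait_fit <- function(object, ...) {
  unlist(object$params)
}

#' @export
logLik.trait_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' Fitted model specification
#'
#' Rebuilds a [model_spec()] from a `trait_fit`, usable for simulation or
#' moment computation.
#'
#' @param fit a `trait_fit`.
#' @return a `model_spec`.
#' @export
fitted_spec <- function(fit) {
  p <- fit$params
  do.call(model_spec, c(list(name = fit$model, sig2 = p$sig2, z0 = p$z0,
                             structured = fit$structured &&
                               fit$model %in% COMPETITION_MODELS),
                        p[setdiff(names(p), c("sig2", "z0"))]))
}

#' @export
simulate.trait_fit <- function(object, nsim = 1, seed = NULL, ...) {
  regimes <- object$regimes
  if (is.list(regimes) && !inherits(regimes, "regime_map")) {
    regimes <- regimes[[1L]]
  }
  simulate_trait(object$tree, fitted_spec(object), regimes = regimes,
                 seed = seed, nsim = nsim, ...)
}

#' @export
residuals.trait_fit <- function(object, ...) {
  object$data - object$params$z0
}
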