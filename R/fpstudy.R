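# False-positive study: simulate traits under OU (no competition), fit the
# competition models alongside OU, and tabulate how often each competition
# model is preferred by more than the AICc threshold. Optionally the
# competition models are guild-structured, with guild states simulated
# under an Mk process and regime histories sampled per tree.

#' Configuration of a false-positive study
#'
#' Defaults mirror the reference simulation design: pure-birth trees of
#' 25/51/112/195 tips standardized to depth 1, OU generating process with
#' `sig2 = 0.1` and `alpha` in {1, 5}, and the AICc > 2 preference rule.
#' The replicate count defaults to 1000 and is typically scaled down.
#'
#' @param sizes tree sizes (tips).
#' @param alpha OU constraint strengths to simulate under.
#' @param sig2 generating rate.
#' @param n_reps replicates per tree x alpha.
#' @param models competition models to fit against OU.
#' @param use_guilds fit guild-structured competition models?
#' @param n_maps stochastic maps per tree when `use_guilds` (default 10).
#' @param guild_rate Mk rate per unit depth for simulated guild states.
#' @param n_guilds number of guild states (default 4).
#' @param delta AICc preference threshold (default 2).
#' @param birth,death birth-death rates for simulated trees.
#' @param trees optional list of user-supplied trees overriding `sizes`.
#' @param n_starts optimizer start points per fit.
#' @param ou_alpha_max upper bound on the fitted OU constraint. The default
#'   `exp(1)` reproduces the conventional constraint box of the standard
#'   comparative-methods toolchain whose model-selection behaviour the
#'   false-positive experiment characterizes; on an ultrametric tree the
#'   OU covariance is exactly an accelerating exponential-in-time rate
#'   model, so with an unbounded alpha the true OU fit is essentially
#'   never beaten and strong-constraint false positives vanish (set
#'   `ou_alpha_max = Inf` to see this).
#' @param seed integer seed driving every random draw.
#' @return an object of class `fp_config`.
#' @export
fp_config <- function(sizes = c(25, 51, 112, 195), alpha = c(1, 5),
                      sig2 = 0.1, n_reps = 1000,
                      models = c("DDlin", "DDexp", "MC"),
                      use_guilds = FALSE, n_maps = 10, guild_rate = 0.5,
                      n_guilds = 4, delta = 2, birth = 1, death = 0,
                      trees = NULL, n_starts = 5, ou_alpha_max = exp(1),
                      seed = 1) {
  stopifnot(n_reps >= 1, delta >= 0, all(models %in% COMPETITION_MODELS),
            ou_alpha_max > 0)
  structure(list(sizes = sizes, alpha = alpha, sig2 = sig2,
                 n_reps = n_reps, models = models,
                 use_guilds = use_guilds, n_maps = n_maps,
                 guild_rate = guild_rate, n_guilds = n_guilds,
                 delta = delta, birth = birth, death = death,
                 trees = trees, n_starts = n_starts,
                 ou_alpha_max = ou_alpha_max, seed = seed),
            class = "fp_config")
}

#' Run a false-positive study
#'
#' For every tree and constraint strength, simulates `n_reps` OU datasets
#' (`z0 = 0`), fits OU and the configured competition models (restricted to
#' same-guild interactions when `use_guilds`, aggregated over sampled
#' regime maps by map-mean AICc), and tabulates the rate at which each
#' competition model beats OU by more than `delta` AICc units. Fully
#' deterministic for a given seed.
#'
#' @param config an [fp_config()].
#' @return an object of class `fp_result` with replicate-level `records`,
#'   the `rates` table (with Wilson 95% intervals and non-convergence
#'   rates) and the config.
#' @export
run_fp_study <- function(config) {
  stopifnot(inherits(config, "fp_config"))
  trees <- config$trees
  if (is.null(trees)) {
    trees <- lapply(seq_along(config$sizes), function(i) {
      standardize_depth(
        simulate_tree(config$sizes[i], config$birth, config$death,
                      seed = config$seed + 131L * i), 1)
    })
  } else {
    trees <- lapply(trees, standardize_depth, target = 1)
  }
  sizes <- vapply(trees, ape::Ntip, numeric(1))

  records <- list()
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    ctx_ind <- tree_ctx(tree, need = "independent")
    if (config$use_guilds) {
      gs <- simulate_guild_states(tree, config$guild_rate,
                                  config$n_guilds,
                                  seed = config$seed + 977L * ti)
      mk <- suppressWarnings(fit_mk(tree, gs))
      maps <- sample_maps(tree, mk, gs, n_maps = config$n_maps,
                          seed = config$seed + 977L * ti + 1L)
      ctxs <- lapply(maps, function(m) tree_ctx(tree, regimes = m))
    } else {
      maps <- list(NULL)
      ctxs <- list(tree_ctx(tree))
    }
    for (ai in seq_along(config$alpha)) {
      a <- config$alpha[ai]
      spec <- model_spec("OU", sig2 = config$sig2, alpha = a, z0 = 0)
      for (r in seq_len(config$n_reps)) {
        sim_seed <- (config$seed %% 1000L) * 2000000L +
          ti * 400000L + ai * 200000L + r
        x <- simulate_trait(tree, spec, seed = sim_seed)
        fit_ou <- fit_trait_model(tree, x, "OU", ctx = ctx_ind,
                                  n_starts = config$n_starts,
                                  seed = config$seed,
                                  bounds = c(-10, log(config$ou_alpha_max)))
        row <- list(size = sizes[ti], alpha = a, rep = r,
                    aicc_OU = fit_ou$aicc, conv_OU = fit_ou$converged)
        for (m in config$models) {
          per_map <- vapply(seq_along(ctxs), function(j) {
            f <- fit_trait_model(tree, x, m,
                                 regimes = if (config$use_guilds)
                                   maps[[j]] else NULL,
                                 ctx = ctxs[[j]],
                                 n_starts = config$n_starts,
                                 seed = config$seed)
            c(f$aicc, f$converged)
          }, numeric(2))
          row[[paste0("aicc_", m)]] <- mean(per_map[1L, ])
          row[[paste0("conv_", m)]] <- all(per_map[2L, ] == 1)
        }
        records[[length(records) + 1L]] <- row
      }
    }
  }
  records <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  structure(list(records = records,
                 rates = fp_rates_from_records(records, config$models,
                                               config$delta),
                 config = config),
            class = "fp_result")
}

# guild tip states under a single-rate Mk process; resamples (bounded) if a
# draw leaves fewer than two states observed at the tips
simulate_guild_states <- function(tree, rate_per_depth, n_guilds, seed) {
  depth <- tree_depth(tree)
  states <- as.character(seq_len(n_guilds))
  q <- rate_per_depth / depth
  Q <- matrix(q, n_guilds, n_guilds, dimnames = list(states, states))
  diag(Q) <- -(n_guilds - 1) * q
  for (try in 0:19) {
    h <- with_local_seed(seed + try, quiet_sim_history(tree, Q))
    st <- get_tip_states(h)
    if (length(unique(st)) >= 2) return(align_trait_states(st, tree))
  }
  align_trait_states(st, tree)
}

fp_rates_from_records <- function(records, models, delta) {
  combos <- unique(records[, c("size", "alpha")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- records[records$size == combos$size[i] &
                   records$alpha == combos$alpha[i], ]
    ok <- sub$conv_OU
    do.call(rbind, lapply(models, function(m) {
      fp <- sub[[paste0("aicc_", m)]][ok] < (sub$aicc_OU[ok] - delta)
      ci <- wilson_interval(sum(fp), length(fp))
      data.frame(size = combos$size[i], alpha = combos$alpha[i],
                 model = m, fp_rate = mean(fp), n = length(fp),
                 lower = ci[1L], upper = ci[2L],
                 nonconv_rate = mean(!sub[[paste0("conv_", m)]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Recompute false-positive rates at a different AICc threshold
#'
#' @param result an `fp_result`.
#' @param delta AICc preference threshold.
#' @return the rates table at the requested threshold.
#' @export
fp_rates <- function(result, delta = 2) {
  stopifnot(inherits(result, "fp_result"))
  fp_rates_from_records(result$records, result$config$models, delta)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x successes.
#' @param n trials.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  if (n == 0) return(c(0, 1))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' @export
print.fp_result <- function(x, ...) {
  cat("False-positive study:", nrow(x$records), "replicate records\n")
  print(x$rates, digits = 3, row.names = FALSE)
  invisible(x)
}
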