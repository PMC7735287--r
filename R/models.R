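# Model specifications for the seven trait-evolution processes.
#
# All models share a base rate sig2 (trait^2 per unit time) and a root state
# z0; the focal parameter differs:
#   BM    -- none
#   OU    -- alpha, pull towards the root state
#   TDlin -- slope_t, rate sig2 + slope_t * t
#   TDexp -- rate_t,  rate sig2 * exp(rate_t * t)
#   DDlin -- slope_n, rate sig2 + slope_n * n(t)
#   DDexp -- rate_n,  rate sig2 * exp(rate_n * n(t))
#   MC    -- S <= 0,  drift S * (mean of interacting lineages - own value)

MODEL_NAMES <- c("BM", "OU", "TDlin", "TDexp", "DDlin", "DDexp", "MC")
COMPETITION_MODELS <- c("DDlin", "DDexp", "MC")
INDEPENDENT_MODELS <- c("BM", "OU", "TDlin", "TDexp")

# minimum admissible effective rate; linear models whose rate would fall
# below this anywhere on the tree are rejected during fitting
RATE_FLOOR <- 1e-8

#' Specify a trait-evolution model
#'
#' Builds a validated model specification for one of the seven processes:
#' Brownian motion (`BM`), Ornstein-Uhlenbeck (`OU`), linear/exponential
#' time-dependent rates (`TDlin`, `TDexp`), linear/exponential
#' diversity-dependent rates (`DDlin`, `DDexp`), or the matching competition
#' model (`MC`) in which each lineage's trait is repelled from the mean of
#' its interacting contemporaries with strength `S <= 0`.
#'
#' @param name model name, one of `r paste(MODEL_NAMES, collapse=", ")`.
#' @param sig2 base rate, positive.
#' @param z0 root trait value.
#' @param alpha OU pull strength (>= 0).
#' @param slope_t,rate_t time-dependence slope / exponent.
#' @param slope_n,rate_n diversity-dependence slope / exponent (per lineage).
#' @param S matching-competition strength (<= 0; 0 reduces to BM).
#' @param structured should interactions / lineage counts be restricted by a
#'   regime map? Only meaningful for `DDlin`, `DDexp` and `MC`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(name, sig2 = 1, z0 = 0, alpha = NULL,
                       slope_t = NULL, rate_t = NULL,
                       slope_n = NULL, rate_n = NULL, S = NULL,
                       structured = FALSE) {
  name <- match.arg(name, MODEL_NAMES)
  stopifnot(is.numeric(sig2), length(sig2) == 1, sig2 > 0,
            is.numeric(z0), length(z0) == 1, is.finite(z0))
  if (structured && !name %in% COMPETITION_MODELS) {
    stop("'structured' only applies to DDlin, DDexp and MC")
  }
  spec <- list(name = name, sig2 = sig2, z0 = z0, structured = structured)
  need1 <- function(v, what) {
    if (is.null(v)) stop(name, " requires parameter '", what, "'")
    stopifnot(is.numeric(v), length(v) == 1, is.finite(v))
    v
  }
  spec[[switch(name, BM = "sig2", OU = "alpha",
               TDlin = "slope_t", TDexp = "rate_t",
               DDlin = "slope_n", DDexp = "rate_n", MC = "S")]] <-
    switch(name,
      BM = sig2,
      OU = {
        a <- need1(alpha, "alpha"); if (a < 0) stop("alpha must be >= 0"); a
      },
      TDlin = need1(slope_t, "slope_t"),
      TDexp = need1(rate_t, "rate_t"),
      DDlin = need1(slope_n, "slope_n"),
      DDexp = need1(rate_n, "rate_n"),
      MC = {
        s <- need1(S, "S")
        if (s > 0) stop("S must be <= 0 (repulsion convention)")
        s
      })
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  focal <- focal_param_name(x$name)
  cat("Trait-evolution model: ", x$name,
      if (x$structured) " (guild-structured)" else "", "\n", sep = "")
  cat("  sig2 = ", format(x$sig2), ", z0 = ", format(x$z0), sep = "")
  if (!is.na(focal)) cat(", ", focal, " = ", format(x[[focal]]), sep = "")
  cat("\n")
  invisible(x)
}

focal_param_name <- function(name) {
  switch(name, BM = NA_character_, OU = "alpha", TDlin = "slope_t",
         TDexp = "rate_t", DDlin = "slope_n", DDexp = "rate_n", MC = "S")
}

# number of free parameters entering AICc (z0 and sig2 count everywhere)
model_k <- function(name) if (name == "BM") 2L else 3L

#' Instantaneous rate of trait evolution
#'
#' Evaluates the effective rate sigma^2(t) of a model at given times. For
#' diversity-dependent models the lineage-count step function must be
#' supplied. Rates of linear models falling below the admissible floor are
#' an error (the parameter combination is outside the model's domain).
#'
#' @param spec a [model_spec()].
#' @param t times from the root (vectorized).
#' @param n a [lineage_count()] object (DD models only).
#' @return numeric vector of rates.
#' @export
effective_rate <- function(spec, t, n = NULL) {
  out <- switch(spec$name,
    BM = , OU = , MC = rep(spec$sig2, length(t)),
    TDlin = spec$sig2 + spec$slope_t * t,
    TDexp = spec$sig2 * exp(spec$rate_t * t),
    DDlin = {
      if (is.null(n)) stop("DD models need a lineage_count")
      spec$sig2 + spec$slope_n * n_at(n, t)
    },
    DDexp = {
      if (is.null(n)) stop("DD models need a lineage_count")
      spec$sig2 * exp(spec$rate_n * n_at(n, t))
    })
  if (any(out < RATE_FLOOR)) {
    stop("effective rate falls below ", RATE_FLOOR,
         "; parameter combination outside model domain")
  }
  out
}
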