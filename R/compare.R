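# AICc model comparison and the competition-signal flag: a clade x trait is
# flagged when the best model is a competition model (DDlin, DDexp, MC) and
# it beats the best independent-evolution model by more than 2 AICc units.

#' Compare fitted trait-evolution models by AICc
#'
#' @param fits a list of `trait_fit` objects for the same clade, trait and
#'   tip count (one per model).
#' @param clade,trait identifiers recorded in the table.
#' @param delta AICc threshold for the competition flag (default 2).
#' @return an object of class `model_comparison`: a table of AICc and
#'   delta-AICc per model, the best model (deterministic tie-breaking:
#'   fewer parameters, then alphabetical name), and the competition flag.
#' @export
compare_models <- function(fits, clade = "clade", trait = "trait",
                           delta = 2) {
  if (!length(fits)) stop("no fits supplied")
  stopifnot(all(vapply(fits, inherits, logical(1), "trait_fit")))
  models <- vapply(fits, `[[`, character(1), "model")
  if (anyDuplicated(models)) stop("duplicate model fits")
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) stop("fits have differing tip counts")
  tab <- data.frame(
    clade = clade, trait = trait, model = models,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    n = ns,
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    structured = vapply(fits, `[[`, logical(1), "structured"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  # deterministic best: min AICc, ties (< 1e-8) by fewer parameters then name
  eps <- 1e-8
  cand <- which(tab$aicc <= min(tab$aicc) + eps)
  cand <- cand[order(tab$k[cand], tab$model[cand])]
  best <- tab$model[cand[1L]]
  indep <- tab$model %in% INDEPENDENT_MODELS
  if (!any(indep)) stop("at least one independent-evolution model required")
  flag <- best %in% COMPETITION_MODELS &&
    (min(tab$aicc[indep]) - tab$aicc[tab$model == best]) > delta
  structure(list(table = tab[order(tab$aicc), , drop = FALSE],
                 best_model = best, competition_flag = flag,
                 clade = clade, trait = trait, delta = delta),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (clade ", x$clade, ", trait ", x$trait, ")\n",
      sep = "")
  print(x$table[, c("model", "loglik", "k", "aicc", "delta_aicc")],
        row.names = FALSE, digits = 6)
  cat("best model:", x$best_model,
      "| competition flag:", x$competition_flag, "\n")
  invisible(x)
}

#' Per-clade comparison table across traits
#'
#' Binds per-trait model comparisons for one clade and computes the
#' any-trait competition flag (signal on at least one trait axis).
#'
#' @param comparisons named list of [compare_models()] results, one per
#'   trait, all for the same clade.
#' @param clade clade identifier (defaults to the first comparison's).
#' @return an object of class `comparison_table` with fields `rows`,
#'   `flags` (per trait), `any_trait_flag` and `clade`.
#' @export
comparison_table <- function(comparisons, clade = NULL) {
  stopifnot(length(comparisons) >= 1,
            all(vapply(comparisons, inherits, logical(1),
                       "model_comparison")))
  if (is.null(clade)) clade <- comparisons[[1L]]$clade
  traits <- vapply(comparisons, `[[`, character(1), "trait")
  if (is.null(names(comparisons))) names(comparisons) <- traits
  flags <- vapply(comparisons, `[[`, logical(1), "competition_flag")
  names(flags) <- traits
  rows <- do.call(rbind, lapply(comparisons, `[[`, "table"))
  rows$clade <- clade
  rownames(rows) <- NULL
  structure(list(rows = rows, flags = flags,
                 best_models = vapply(comparisons, `[[`, character(1),
                                      "best_model"),
                 any_trait_flag = any(flags), clade = clade),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Clade ", x$clade, ": competition flag per trait\n", sep = "")
  print(data.frame(trait = names(x$flags), best = x$best_models,
                   flag = x$flags, row.names = NULL))
  cat("any-trait flag:", x$any_trait_flag, "\n")
  invisible(x)
}

#' Prevalence of the competition signal across clades
#'
#' @param tables list of [comparison_table()] objects, one per clade.
#' @return an object of class `prevalence_table`: per trait and for
#'   "any trait", the count of flagged clades out of the total, with the
#'   flagged clade identifiers.
#' @export
prevalence <- function(tables) {
  stopifnot(all(vapply(tables, inherits, logical(1), "comparison_table")))
  clades <- vapply(tables, `[[`, character(1), "clade")
  if (anyDuplicated(clades)) stop("duplicate clade identifiers")
  traits <- unique(unlist(lapply(tables, function(t) names(t$flags))))
  per_trait <- lapply(traits, function(tr) {
    fl <- vapply(tables, function(t) isTRUE(t$flags[[tr]]), logical(1))
    list(flagged = sum(fl), total = length(tables),
         clades = clades[fl])
  })
  names(per_trait) <- traits
  anyfl <- vapply(tables, `[[`, logical(1), "any_trait_flag")
  per_trait[["any trait"]] <- list(flagged = sum(anyfl),
                                   total = length(tables),
                                   clades = clades[anyfl])
  structure(list(counts = per_trait, clades = clades),
            class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat("Competition-signal prevalence across", length(x$clades),
      "clades:\n")
  for (tr in names(x$counts)) {
    ct <- x$counts[[tr]]
    cat(sprintf("  %-12s %d / %d\n", tr, ct$flagged, ct$total))
  }
  invisible(x)
}

#' Phylogenetic GLS residuals
#'
#' Regresses `y` on `x` by generalized least squares with a unit-rate
#' Brownian correlation structure and returns the residuals (e.g. beak size
#' regressed on body mass yields relative beak size).
#'
#' @param tree a `phylo` object.
#' @param y,x named numeric trait vectors over the tips.
#' @return the residual trait vector `y - X beta_hat`, tip-named.
#' @export
pgls_residuals <- function(tree, y, x) {
  y <- align_trait(y, tree)
  x <- align_trait(x, tree)
  if (stats::sd(x) == 0) stop("regressor is constant: singular design")
  C <- ape::vcv(tree)
  L <- chol_jitter(C)
  X <- cbind(`(Intercept)` = 1, x = x)
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  beta <- solve(crossprod(Xs), crossprod(Xs, ys))
  res <- y - as.numeric(X %*% beta)
  names(res) <- tree$tip.label
  attr(res, "coefficients") <- setNames(as.numeric(beta), colnames(X))
  res
}
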