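# Mk modelling of guild membership and stochastic character maps. Rate
# fitting and map sampling are delegated to phytools (fitMk, make.simmap);
# this module wraps them behind the package's regime-map representation and
# adds the degenerate single-state case, determinism and serialization.

#' Fit a continuous-time Markov (Mk) model to tip states
#'
#' @param tree a `phylo` object.
#' @param tip_states named character vector of discrete states over tips.
#' @param model `"ER"` (single rate; the default, chosen for
#'   identifiability on small clades), `"SYM"` or `"ARD"`.
#' @param root_prior `"equal"` (default) or `"stationary"`.
#' @return an object of class `mk_model` with the rate matrix `Q`, the root
#'   prior and the maximized log-likelihood. A single observed state yields
#'   a zero-rate model with a warning.
#' @export
fit_mk <- function(tree, tip_states, model = c("ER", "SYM", "ARD"),
                   root_prior = c("equal", "stationary")) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  validate_tree(tree)
  tip_states <- align_trait_states(tip_states, tree)
  states <- sort(unique(tip_states))
  if (length(states) < 2) {
    warning("single observed state; zero-rate Mk model")
    Q <- matrix(0, 1, 1, dimnames = list(states, states))
    return(structure(list(states = states, Q = Q, root_prior = 1,
                          loglik = 0, model = model, tree = tree),
                     class = "mk_model"))
  }
  fit <- phytools::fitMk(tree, tip_states, model = model, pi = "equal")
  Q <- as.Qmatrix_to_matrix(fit)
  pi <- switch(root_prior,
    equal = rep(1 / length(states), length(states)),
    stationary = stationary_dist(Q))
  names(pi) <- states
  structure(list(states = states, Q = Q, root_prior = pi,
                 loglik = as.numeric(stats::logLik(fit)), model = model,
                 tree = tree),
            class = "mk_model")
}

#' Construct an Mk model from a known rate matrix
#'
#' @param Q rate matrix with state dimnames; rows must sum to zero.
#' @param root_prior probability vector over states (default equal).
#' @param tree optional tree the model refers to.
#' @return an object of class `mk_model`.
#' @export
mk_model <- function(Q, root_prior = NULL, tree = NULL) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q),
            !is.null(rownames(Q)), max(abs(rowSums(Q))) < 1e-10,
            all(Q[row(Q) != col(Q)] >= 0))
  states <- rownames(Q)
  if (is.null(root_prior)) {
    root_prior <- rep(1 / length(states), length(states))
  }
  stopifnot(abs(sum(root_prior) - 1) < 1e-10)
  names(root_prior) <- states
  structure(list(states = states, Q = Q, root_prior = root_prior,
                 loglik = NA_real_, model = "fixed", tree = tree),
            class = "mk_model")
}

as.Qmatrix_to_matrix <- function(fit) {
  Q <- matrix(fit$rates[fit$index.matrix], length(fit$states),
              length(fit$states),
              dimnames = list(fit$states, fit$states))
  Q[is.na(Q)] <- 0
  diag(Q) <- -rowSums(Q, na.rm = TRUE)
  Q
}

stationary_dist <- function(Q) {
  e <- eigen(t(Q))
  v <- Re(e$vectors[, which.min(abs(e$values))])
  v / sum(v)
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Mk model (", x$model, "), states {",
      paste(x$states, collapse = ", "), "}, logLik ",
      format(x$loglik, digits = 6), "\n", sep = "")
  print(round(x$Q, 6))
  invisible(x)
}

align_trait_states <- function(x, tree) {
  if (is.factor(x)) x <- setNames(as.character(x), names(x))
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree)) stop("unnamed states of wrong length")
    names(x) <- tree$tip.label
  }
  if (!setequal(names(x), tree$tip.label)) {
    stop("state names do not match tree tips")
  }
  x[tree$tip.label]
}

#' Sample stochastic character maps of guild membership
#'
#' Draws regime histories conditional on the tip states under a fitted Mk
#' model (node states from the joint conditional distribution, edge
#' histories conditional on endpoints), deterministically for a given seed.
#'
#' @param tree a `phylo` object.
#' @param mk a fitted [fit_mk()] model.
#' @param tip_states named character vector of tip states.
#' @param n_maps number of maps (default 50).
#' @param seed optional integer seed.
#' @return a list of `regime_map` objects.
#' @export
sample_maps <- function(tree, mk, tip_states, n_maps = 50, seed = NULL) {
  stopifnot(inherits(mk, "mk_model"), n_maps >= 1)
  tip_states <- align_trait_states(tip_states, tree)
  if (length(mk$states) < 2 || all(abs(mk$Q) < 1e-14)) {
    # no transitions possible: every map is the single observed history
    m <- regime_map(tree, lapply(seq_len(nrow(tree$edge)), function(i) {
      setNames(tree$edge.length[i], tip_states[[1L]])
    }))
    return(rep(list(m), n_maps))
  }
  smaps <- with_local_seed(seed,
    phytools::make.simmap(tree, tip_states, Q = mk$Q, pi = mk$root_prior,
                          nsim = n_maps, message = FALSE))
  if (inherits(smaps, "simmap") && !inherits(smaps, "multiSimmap")) {
    smaps <- list(smaps)
  }
  lapply(smaps, as_regime_map)
}

#' Serialize a regime map in SIMMAP dialect
#'
#' Writes the tree in Newick form with `{state,duration:...}` edge
#' annotations (rootward segment first), invertible by [read_simmap()].
#'
#' @param map a `regime_map`.
#' @param file optional path; when `NULL` the string is returned.
#' @return the SIMMAP string (invisibly when written to file).
#' @export
write_simmap <- function(map, file = NULL) {
  tree <- map$tree
  ntip <- ape::Ntip(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  ann <- function(ei) {
    m <- map$maps[[ei]]
    paste0(":{", paste(names(m), sprintf("%.10g", m), sep = ",",
                       collapse = ":"), "}")
  }
  rec <- function(node) {
    if (node <= ntip) return(gsub("[(),:;{} ]", "_", tree$tip.label[node]))
    es <- kids[[as.character(node)]]
    paste0("(", paste(vapply(es, function(ei) {
      paste0(rec(tree$edge[ei, 2L]), ann(ei))
    }, character(1)), collapse = ","), ")")
  }
  s <- paste0(rec(ntip + 1L), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a SIMMAP-dialect tree into a regime map
#'
#' @param source a file path or a SIMMAP string.
#' @return a `regime_map`.
#' @export
read_simmap <- function(source) {
  is_path <- length(source) == 1L && !grepl("[(;]", source) &&
    file.exists(source)
  s <- if (is_path) phytools::read.simmap(file = source, format = "phylip")
       else phytools::read.simmap(text = source, format = "phylip")
  if (inherits(s, "multiSimmap")) s <- s[[1L]]
  as_regime_map(s)
}
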