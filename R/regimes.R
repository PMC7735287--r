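# Regime maps: piecewise-constant discrete-state histories along every edge,
# used to restrict which lineages interact (MC) or are counted (DD).
#
# Representation follows the simmap convention: per edge an ordered, named
# numeric vector of segment durations (names = states, rootward segment
# first). Time is measured from the crown root.

#' Construct a regime map
#'
#' @param tree a `phylo` object.
#' @param maps a list with one element per edge row of `tree$edge`: a named
#'   numeric vector of segment durations (names are states, ordered from the
#'   rootward end of the edge).
#' @return an object of class `regime_map`.
#' @export
regime_map <- function(tree, maps) {
  validate_tree(tree)
  if (length(maps) != nrow(tree$edge)) stop("one maps entry per edge required")
  T <- tree_depth(tree)
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (is.null(names(m)) || any(!is.finite(m)) || any(m < 0)) {
      stop("edge ", i, ": segments must be named nonnegative durations")
    }
    if (abs(sum(m) - tree$edge.length[i]) > 1e-9 * max(T, 1)) {
      stop("edge ", i, ": segment durations do not sum to the edge length")
    }
    r <- rle(names(m))
    if (any(r$lengths > 1) && length(m) > 1) {
      # merge adjacent equal-state segments rather than reject
      maps[[i]] <- setNames(as.numeric(tapply(m, rep(seq_along(r$lengths),
                                                     r$lengths), sum)),
                            r$values)
    }
  }
  structure(list(tree = tree, maps = maps,
                 states = sort(unique(unlist(lapply(maps, names))))),
            class = "regime_map")
}

#' Convert a phytools simmap tree to a regime map
#'
#' @param smap an object of class `simmap` (e.g. from
#'   [phytools::make.simmap()] or [phytools::sim.history()]).
#' @return a `regime_map`.
#' @export
as_regime_map <- function(smap) {
  if (!inherits(smap, "phylo") || is.null(smap$maps)) {
    stop("input is not a simmap-style tree")
  }
  tree <- smap
  attr(tree, "map.order") <- NULL
  tree$maps <- NULL; tree$mapped.edge <- NULL
  tree$node.states <- NULL; tree$states <- NULL
  tree$Q <- NULL; tree$logL <- NULL
  class(tree) <- "phylo"
  regime_map(tree, smap$maps)
}

#' Single-regime map (everyone interacts)
#'
#' @param tree a `phylo` object.
#' @param state the state label to use everywhere.
#' @return a `regime_map` in which all lineages share one state.
#' @export
single_regime_map <- function(tree, state = "1") {
  regime_map(tree, lapply(tree$edge.length, function(l) setNames(l, state)))
}

#' @export
print.regime_map <- function(x, ...) {
  cat("Regime map on a ", ape::Ntip(x$tree), "-tip tree: states {",
      paste(x$states, collapse = ", "), "}, ",
      count_changes(x), " state changes\n", sep = "")
  invisible(x)
}

#' Regime state of an edge at a time point
#'
#' @param map a `regime_map`.
#' @param edge edge row index in `map$tree$edge`.
#' @param t time from the root; must fall within the edge's span.
#' @return the state label.
#' @export
state_at <- function(map, edge, t) {
  nt <- node_times(map$tree)
  t0 <- nt[map$tree$edge[edge, 1L]]
  m <- map$maps[[edge]]
  ends <- t0 + cumsum(m)
  if (t < t0 - 1e-9 || t > ends[length(ends)] + 1e-9) {
    stop("time outside the edge's span")
  }
  names(m)[min(which(t <= ends + 1e-12), length(m))]
}

#' Number of state changes on a regime map
#'
#' @param map a `regime_map`.
#' @return total count of within-edge state changes.
#' @export
count_changes <- function(map) {
  sum(vapply(map$maps, function(m) length(m) - 1L, integer(1)))
}

#' Flag suspect regime reconstructions
#'
#' A set of sampled maps is flagged when the map-mean number of state
#' changes per unit tree depth exceeds a threshold, mirroring the exclusion
#' of reconstructions with many back-and-forth transitions on single edges.
#'
#' @param maps list of `regime_map` objects.
#' @param threshold changes per unit tree depth (default 10).
#' @return logical: is the reconstruction suspect?
#' @export
flag_suspect_maps <- function(maps, threshold = 10) {
  stopifnot(length(maps) >= 1)
  depth <- tree_depth(maps[[1L]]$tree)
  mean(vapply(maps, count_changes, numeric(1))) / depth > threshold
}

# ---- time grid shared by all regime-aware computations -------------------

# Cuts [0, T] at every node time and every within-edge regime change,
# merged within a relative tolerance. Returns, per edge x interval, which
# state the edge carries (NA when the edge is not alive), per-state lineage
# counts per interval, and interval lengths. Every interval lies entirely
# within or outside each edge's span because node times are grid points.
regime_grid <- function(map, tol = 1e-9) {
  tree <- map$tree
  nt <- node_times(tree)
  T <- tree_depth(tree)
  edge <- tree$edge
  ne <- nrow(edge)
  e_t0 <- nt[edge[, 1L]]
  bnds <- unlist(lapply(seq_len(ne), function(i) {
    m <- map$maps[[i]]
    if (length(m) > 1) e_t0[i] + cumsum(m)[-length(m)] else numeric(0)
  }))
  times <- sort(c(0, T, nt, bnds))
  # merge near-duplicates
  keep <- c(TRUE, diff(times) > tol * max(T, 1))
  grid <- times[keep]
  K <- length(grid) - 1L
  mids <- (grid[-1L] + grid[-length(grid)]) / 2
  lens <- diff(grid)
  states <- map$states
  SM <- matrix(NA_integer_, ne, K)
  for (i in seq_len(ne)) {
    m <- map$maps[[i]]
    t1 <- e_t0[i] + sum(m)
    js <- which(mids > e_t0[i] & mids < t1)
    if (!length(js)) next
    seg_ends <- e_t0[i] + cumsum(m)
    seg <- findInterval(mids[js], seg_ends, left.open = FALSE) + 1L
    seg[seg > length(m)] <- length(m)
    SM[i, js] <- match(names(m)[seg], states)
  }
  counts <- matrix(0L, length(states), K)
  for (j in seq_len(K)) {
    alive <- SM[, j]
    tb <- tabulate(alive[!is.na(alive)], nbins = length(states))
    counts[, j] <- tb
  }
  list(grid = grid, lens = lens, SM = SM, counts = counts,
       states = states, tree = tree, nt = nt, depth = T, tol = tol)
}

# ---- per-node root-path rate integrals (structured DD) -------------------

# For every node v, the durations along the root->v path spent at each
# same-regime lineage count k. Row v of the returned matrix D satisfies
#   sum_k D[v, k]               = time(v)
#   sum_k k * D[v, k]           = \int_0^{t_v} n_{g(u)}(u) du
# where n_g is the count of lineages sharing the path's regime state.
node_path_integrals <- function(rg) {
  tree <- rg$tree
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kmax <- ntip
  D <- matrix(0, nn, kmax)
  edge <- tree$edge
  # preorder so parents are filled before children
  ord <- rev(ape::postorder(tree))
  for (ei in ord) {
    p <- edge[ei, 1L]; ch <- edge[ei, 2L]
    js <- which(!is.na(rg$SM[ei, ]))
    row <- D[p, ]
    if (length(js)) {
      k <- rg$counts[cbind(rg$SM[ei, js], js)]
      add <- vapply(split(rg$lens[js], k), sum, numeric(1))
      kk <- as.integer(names(add))
      row[kk] <- row[kk] + add
    }
    D[ch, ] <- row
  }
  D
}

# ---- matching-competition event mesh -------------------------------------

# Precomputes everything the MC covariance propagation and the MC simulator
# need: per interval the group structure of alive lineages, and the split
# instructions applied at interval boundaries. Lineages are tracked as an
# ordered vector; a split replaces position p by one daughter and appends
# the other at the end. `tip_perm` maps final lineage positions to tips.
mc_mesh <- function(rg) {
  tree <- rg$tree
  edge <- tree$edge
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nt <- rg$nt
  tol <- rg$tol * max(rg$depth, 1)
  children_of <- split(seq_len(nrow(edge)), edge[, 1L])
  edge_below <- integer(ntip + tree$Nnode)
  edge_below[edge[, 2L]] <- seq_len(nrow(edge))

  lin <- children_of[[as.character(root)]]
  if (length(lin) != 2L) stop("tree must be binary at the root")
  K <- length(rg$lens)
  steps <- vector("list", K)
  splits <- vector("list", K)
  for (j in seq_len(K)) {
    st <- rg$SM[lin, j]
    if (anyNA(st)) stop("internal error: dead lineage inside interval")
    g <- as.integer(factor(st))
    sz <- tabulate(g)
    B <- matrix(0, length(g), length(sz))
    B[cbind(seq_along(g), g)] <- 1
    steps[[j]] <- list(h = rg$lens[j], g = g, sz = sz, B = B,
                       Pm = outer(g, g, `==`) / sz[g])
    # process branching events at the interval's right boundary
    b <- rg$grid[j + 1L]
    sp <- list()
    repeat {
      ends <- edge[lin, 2L]
      hit <- which(ends > ntip & abs(nt[ends] - b) <= tol)
      if (!length(hit)) break
      p <- hit[1L]
      ch <- children_of[[as.character(ends[p])]]
      if (length(ch) != 2L) stop("tree must be binary")
      sp[[length(sp) + 1L]] <- p
      lin[p] <- ch[1L]
      lin <- c(lin, ch[2L])
    }
    splits[[j]] <- as.integer(unlist(sp))
  }
  tip_perm <- match(edge_below[seq_len(ntip)], lin)
  if (anyNA(tip_perm)) stop("internal error: tips unreachable in mesh")
  list(steps = steps, splits = splits, tip_perm = tip_perm, ntip = ntip)
}

# one interval of the unit-rate MC covariance propagation:
#   dV/dt = A V + V A' + I,  A = S (P - I),  P = block row-means incl. self
# A is constant within the interval; P is a symmetric projection, so
#   e^{Ah} = P + e^{-Sh} (I - P)
# and the update is exact. Group aggregation goes through rowsum() so the
# inner loop stays at C speed; g holds each lineage's group id (1..G),
# sz the group sizes.
mc_step_cov <- function(V, st, S) {
  ee <- exp(-S * st$h)
  R1 <- crossprod(st$B, V)                 # G x n group row sums
  W <- st$B %*% (R1 / st$sz)               # W = P V
  Ssm <- R1 %*% st$B                       # G x G block sums of V
  PVP <- (Ssm / outer(st$sz, st$sz))[st$g, st$g, drop = FALSE]
  ee^2 * V + (ee * (1 - ee)) * (W + t(W)) + (1 - ee)^2 * PVP
}

# unit-rate (sig2 = 1) MC tip covariance for a given S, from a mesh
mc_cov_unit <- function(mesh, S) {
  V <- matrix(0, 2, 2)
  for (j in seq_along(mesh$steps)) {
    st <- mesh$steps[[j]]
    if (st$h > 0) {
      V <- mc_step_cov(V, st, S)
      # process noise over the interval: h P + q (I - P)
      q <- if (S == 0) st$h else (exp(-2 * S * st$h) - 1) / (-2 * S)
      V <- V + (st$h - q) * st$Pm
      diag(V) <- diag(V) + q
    }
    for (p in mesh$splits[[j]]) {
      n <- nrow(V)
      V <- V[c(seq_len(n), p), c(seq_len(n), p)]
    }
  }
  V <- V[mesh$tip_perm, mesh$tip_perm]
  dimnames(V) <- NULL
  (V + t(V)) / 2
}
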