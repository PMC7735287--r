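# ---- basic tree geometry -----------------------------------------------

#' Node times measured from the crown root
#'
#' Returns the time of every node in the tree on the model time axis: 0 at
#' the crown root, increasing towards the present. Entries 1..Ntip are tip
#' times, the rest internal-node times.
#'
#' @param tree a `phylo` object.
#' @return numeric vector of length `Ntip + Nnode`.
#' @export
node_times <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Tree depth (root-to-present distance)
#'
#' @param tree a `phylo` object.
#' @return the maximum root-to-tip distance.
#' @export
tree_depth <- function(tree) {
  max(node_times(tree)[seq_len(ape::Ntip(tree))])
}

is_ultrametric_tol <- function(tree, tol = 1e-6) {
  tt <- node_times(tree)[seq_len(ape::Ntip(tree))]
  T <- max(tt)
  T > 0 && (max(tt) - min(tt)) <= tol * T
}

#' Validate a phylogeny for model fitting
#'
#' Checks rootedness, unique tip labels, nonnegative edge lengths, and
#' (optionally) ultrametricity within a relative tolerance of `1e-6` times
#' the tree depth.
#'
#' @param tree a `phylo` object.
#' @param ultrametric require ultrametricity?
#' @return the tree, invisibly, or an error.
#' @export
validate_tree <- function(tree, ultrametric = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (ape::Ntip(tree) < 2) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  if (any(tree$edge.length < 0)) stop("negative edge lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (ultrametric && !is_ultrametric_tol(tree)) {
    stop("tree is not ultrametric (relative tolerance 1e-6)")
  }
  invisible(tree)
}

# ---- I/O ----------------------------------------------------------------

#' Read a time-calibrated tree
#'
#' Parses Newick or NEXUS input from a file path or a literal string.
#' Polytomies are resolved to a binary tree with zero-length edges
#' (deterministically, in input order) with a warning.
#'
#' @param source a file path, or a string containing the tree.
#' @param format `"newick"` or `"nexus"`.
#' @return a validated binary `phylo` object.
#' @export
read_tree <- function(source, format = c("newick", "nexus")) {
  format <- match.arg(format)
  is_path <- length(source) == 1L && !grepl("[(;]", source) && file.exists(source)
  tree <- switch(format,
    newick = if (is_path) ape::read.tree(source) else ape::read.tree(text = source),
    nexus = {
      if (!is_path) {
        tf <- tempfile(fileext = ".nex")
        on.exit(unlink(tf), add = TRUE)
        writeLines(source, tf)
        source <- tf
      }
      ape::read.nexus(source)
    }
  )
  if (is.null(tree)) stop("failed to parse tree [", format, "]")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!ape::is.binary(tree)) {
    warning("polytomies resolved to binary with zero-length edges")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  validate_tree(tree)
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
write_tree <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Rescale a tree to a target depth
#'
#' Multiplies every edge length by `target / depth` so the returned tree
#' has root-to-present distance exactly `target`.
#'
#' @param tree a `phylo` object with positive depth.
#' @param target new depth (positive).
#' @return the rescaled tree.
#' @export
standardize_depth <- function(tree, target = 1) {
  stopifnot(target > 0)
  T <- tree_depth(tree)
  if (T <= 0) stop("zero-depth tree cannot be standardized")
  tree$edge.length <- tree$edge.length * (target / T)
  tree
}

# ---- lineages-through-time ----------------------------------------------

#' Lineage-count step function n(t)
#'
#' Counts reconstructed lineages through time on an ultrametric tree,
#' starting at 2 just after the crown root and ending at the tip count.
#' Breakpoints sit at internal-node times (time measured from the root).
#'
#' @param tree an ultrametric `phylo` object.
#' @return an object of class `lineage_count` with fields `breakpoints`
#'   (times from the root, starting at 0), `counts` (lineages on each
#'   interval), and `depth`.
#' @export
lineage_count <- function(tree) {
  validate_tree(tree, ultrametric = TRUE)
  nt <- node_times(tree)
  ntip <- ape::Ntip(tree)
  T <- tree_depth(tree)
  itimes <- sort(nt[(ntip + 1L):length(nt)])
  bp <- unique(itimes)
  counts <- 1L + vapply(bp, function(b) sum(itimes <= b), integer(1))
  structure(list(breakpoints = bp, counts = counts, depth = T),
            class = "lineage_count")
}

#' Evaluate n(t)
#'
#' @param lc a `lineage_count` object.
#' @param t times in `[0, depth]` (vectorized).
#' @return integer lineage counts at each time.
#' @export
n_at <- function(lc, t) {
  idx <- findInterval(t, lc$breakpoints, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  lc$counts[idx]
}

#' Cumulative lineage integral
#'
#' Computes the running integral of the lineage-count step function,
#' `N(t) = \int_0^t n(u) du`, vectorized over `t`.
#'
#' @param lc a `lineage_count` object.
#' @param t times in `[0, depth]`.
#' @return numeric vector of the same shape as `t`.
#' @export
cum_lineage_integral <- function(lc, t) {
  bp <- lc$breakpoints
  k <- length(bp)
  ends <- c(bp[-1L], lc$depth)
  cum <- c(0, cumsum(lc$counts * (ends - bp)))
  idx <- findInterval(t, bp, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  out <- cum[idx] + lc$counts[idx] * (t - bp[idx])
  dim(out) <- dim(t)
  out
}

#' @export
print.lineage_count <- function(x, ...) {
  cat("Lineage-count step function on a depth-", format(x$depth),
      " tree\n", sep = "")
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

# ---- mid-point subclades -------------------------------------------------

#' Extract young subclades by midpoint time slicing
#'
#' Slices an ultrametric tree at half the root-to-tip distance and returns
#' every maximal monophyletic subtree whose crown age is younger than the
#' slice and which holds at least `min_tips` species. Nested candidates are
#' discarded in favour of the most inclusive clade, so the result is a set
#' of disjoint recent radiations.
#'
#' @param tree an ultrametric `phylo` object.
#' @param min_tips minimum subclade size (default 20).
#' @return a (possibly empty) list of `phylo` subtrees.
#' @export
extract_midpoint_subclades <- function(tree, min_tips = 20) {
  validate_tree(tree, ultrametric = TRUE)
  ntip <- ape::Ntip(tree)
  nt <- node_times(tree)
  T <- tree_depth(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  ndesc <- tabulate_descendants(tree)
  cand <- internal[nt[internal] > T / 2 & ndesc[internal] >= min_tips]
  if (!length(cand)) return(list())
  # keep only candidates none of whose ancestors are candidates
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  keep <- vapply(cand, function(v) {
    a <- parent[v]
    while (a != 0L) {
      if (a %in% cand) return(FALSE)
      a <- parent[a]
    }
    TRUE
  }, logical(1))
  lapply(cand[keep], function(v) ape::extract.clade(tree, v))
}

# number of descendant tips below every node
tabulate_descendants <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  out <- c(rep(1L, ntip), rep(0L, tree$Nnode))
  # postorder edge traversal: children before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(eo))) {
    out[eo[i, 1L]] <- out[eo[i, 1L]] + out[eo[i, 2L]]
  }
  out
}

# ---- trait tables --------------------------------------------------------

#' Read a species trait table aligned to a tree
#'
#' Reads a CSV/TSV file with a `species` column and one or more numeric
#' trait columns, and aligns the values to the tree's tip order. Species in
#' the table but not on the tree are dropped (with a message). Tips lacking
#' data are an error unless `prune = TRUE`, in which case the tree is pruned
#' and returned alongside the traits.
#'
#' @param path file path (delimiter inferred: `.tsv`/`.txt` tab, else comma).
#' @param tree a `phylo` object.
#' @param prune drop tips without data instead of erroring?
#' @return a list with `traits` (named list of aligned numeric vectors),
#'   `tree` (possibly pruned) and `dropped_species` (rows not on the tree).
#' @export
read_trait_table <- function(path, tree, prune = FALSE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"species" %in% names(tab)) stop("table must have a 'species' column")
  align_trait_table(tab, tree, prune = prune)
}

align_trait_table <- function(tab, tree, prune = FALSE) {
  extra <- setdiff(tab$species, tree$tip.label)
  if (length(extra)) {
    message(length(extra), " species in table but not on tree; dropped")
    tab <- tab[!tab$species %in% extra, , drop = FALSE]
  }
  if (anyDuplicated(tab$species)) stop("duplicate species rows in table")
  missing <- setdiff(tree$tip.label, tab$species)
  if (length(missing)) {
    if (!prune) {
      stop(length(missing),
           " tips lack trait data; use prune = TRUE to drop them")
    }
    tree <- ape::drop.tip(tree, missing)
  }
  if (nrow(tab) < 2) stop("fewer than 2 species overlap tree and table")
  num_cols <- names(tab)[vapply(tab, is.numeric, logical(1))]
  if (!length(num_cols)) stop("no numeric trait columns found")
  ord <- match(tree$tip.label, tab$species)
  traits <- lapply(num_cols, function(cn) {
    v <- tab[[cn]][ord]
    if (any(!is.finite(v))) stop("non-finite values in trait '", cn, "'")
    names(v) <- tree$tip.label
    v
  })
  names(traits) <- num_cols
  list(traits = traits, tree = tree, dropped_species = extra)
}

# align a named trait vector to the tree's tip order
align_trait <- function(x, tree) {
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree)) stop("unnamed trait of wrong length")
    names(x) <- tree$tip.label
    return(x)
  }
  if (!setequal(names(x), tree$tip.label)) {
    stop("trait names do not match tree tips")
  }
  x[tree$tip.label]
}
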