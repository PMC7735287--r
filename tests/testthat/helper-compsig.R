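# shared fixtures, all built in code

# cross-test cache (e.g. the false-positive study reused by two checks)
acceptance_cache <- new.env(parent = emptyenv())

tree3 <- function() read_tree("((A:1,B:1):1,C:2);")
tree2 <- function() read_tree("(A:1,B:1);")
tree4 <- function() read_tree("((A:1,B:1):1,(C:1,D:1):1);")

# balanced 2-guild map on the balanced 4-tip tree: {A,B} vs {C,D}, never
# mixing (each cherry and its stem share one state)
two_guild_map <- function() {
  tr <- tree4()
  sts <- c("g1", "g1", "g1", "g2", "g2", "g2")
  regime_map(tr, lapply(seq_len(6), function(i) {
    setNames(tr$edge.length[i], sts[i])
  }))
}

# a depth-1 pure-birth tree, seeded
unit_tree <- function(n, seed) standardize_depth(simulate_tree(n, seed = seed), 1)

# empirical covariance standard error: se(cov_ij) for Gaussian data
cov_se <- function(V, R) {
  sqrt((outer(diag(V), diag(V)) + V^2) / R)
}

# minimal comparison_table stand-in for prevalence tests
fake_table <- function(clade, flags) {
  structure(list(rows = data.frame(), flags = flags,
                 best_models = setNames(rep("BM", length(flags)),
                                        names(flags)),
                 any_trait_flag = any(flags), clade = clade),
            class = "comparison_table")
}
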