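test_that("newick parsing, polytomy resolution and round-trips", {
  tr <- tree3()
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tree_depth(tr), 2)

  expect_warning(tp <- read_tree("((A:1,B:1,C:1):1,D:2);"),
                 "polytomies")
  expect_equal(ape::Ntip(tp), 4)
  expect_true(ape::is.binary(tp))
  expect_true(any(tp$edge.length == 0))

  expect_error(read_tree("((A:1,A:1):1,C:2);"), "duplicate")

  tr2 <- unit_tree(20, seed = 5)
  back <- read_tree(write_tree(tr2))
  expect_equal(sort(back$tip.label), sort(tr2$tip.label))
  # identical topology and lengths up to representation
  expect_equal(suppressWarnings(as.numeric(ape::dist.topo(back, tr2))), 0)
  expect_equal(sort(back$edge.length), sort(tr2$edge.length),
               tolerance = 1e-12)
  # parsing is idempotent
  expect_equal(write_tree(read_tree(write_tree(back))), write_tree(back))

  # NEXUS input resolves to the same tree
  nex <- tempfile(fileext = ".nex")
  ape::write.nexus(tr2, file = nex)
  tn <- read_tree(nex, format = "nexus")
  expect_setequal(tn$tip.label, tr2$tip.label)
  expect_equal(sort(tn$edge.length), sort(tr2$edge.length),
               tolerance = 1e-6)
  unlink(nex)
})

test_that("depth standardization scales edges linearly and inverts", {
  tr <- unit_tree(10, seed = 2)
  tr50 <- tr
  tr50$edge.length <- tr50$edge.length * 50
  s <- standardize_depth(tr50, 1)
  expect_equal(tree_depth(s), 1, tolerance = 1e-12)
  expect_equal(s$edge.length, tr50$edge.length * 0.02, tolerance = 1e-12)
  expect_equal(standardize_depth(tr50, tree_depth(tr50))$edge.length,
               tr50$edge.length)
  rt <- standardize_depth(s, tree_depth(tr50))
  expect_equal(rt$edge.length, tr50$edge.length, tolerance = 1e-9)
})

test_that("lineage counts step at internal nodes and conserve length", {
  lc <- lineage_count(tree4())
  expect_equal(lc$counts, c(2, 4))
  expect_equal(lc$breakpoints, c(0, 1))
  expect_equal(n_at(lc, c(0.5, 1.5)), c(2L, 4L))

  expect_equal(lineage_count(tree2())$counts, 2)

  tr <- simulate_tree(20, seed = 9)
  lc <- lineage_count(tr)
  expect_equal(lc$counts[length(lc$counts)], 20)
  # brute force: count edges crossing each midpoint between breakpoints
  nt <- node_times(tr)
  e0 <- nt[tr$edge[, 1]]; e1 <- nt[tr$edge[, 2]]
  mids <- (c(lc$breakpoints, lc$depth)[-1] + lc$breakpoints) / 2
  brute <- vapply(mids, function(m) sum(e0 < m & e1 > m), numeric(1))
  expect_equal(lc$counts, as.integer(brute))
  # conservation: sum over intervals of (length x count) = total edge length
  ends <- c(lc$breakpoints[-1], lc$depth)
  expect_equal(sum((ends - lc$breakpoints) * lc$counts),
               sum(tr$edge.length), tolerance = 1e-9)
  # cumulative integral agrees at the depth
  expect_equal(cum_lineage_integral(lc, lc$depth), sum(tr$edge.length),
               tolerance = 1e-9)

  expect_error(lineage_count(read_tree("((A:1,B:2):1,C:2);")),
               "ultrametric")
})

test_that("midpoint subclade extraction filters by age and size", {
  # clade of 25 with crown age 0.4 T passes; old clades are excluded
  old <- read_tree("((A:6,B:6):4,(C:6,D:6):4);")  # crown ages 0.6 T
  expect_length(extract_midpoint_subclades(old, min_tips = 2), 0)

  tr <- unit_tree(100, seed = 31)
  sub <- extract_midpoint_subclades(tr, min_tips = 10)
  # brute-force oracle: scan all internal nodes, apply both filters,
  # discard nested candidates
  nt <- node_times(tr)
  T <- tree_depth(tr)
  ntip <- ape::Ntip(tr)
  desc <- vapply((ntip + 1):(ntip + tr$Nnode), function(v) {
    length(ape::extract.clade(tr, v)$tip.label)
  }, numeric(1))
  cand <- ((ntip + 1):(ntip + tr$Nnode))[nt[(ntip + 1):(ntip + tr$Nnode)] >
                                           T / 2 & desc >= 10]
  anc_sets <- lapply(cand, function(v) {
    ape::extract.clade(tr, v)$tip.label
  })
  keep <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      j != i && all(anc_sets[[i]] %in% anc_sets[[j]])
    }, logical(1)))
  }, logical(1))
  oracle_sets <- lapply(anc_sets[keep], sort)
  got_sets <- lapply(sub, function(s) sort(s$tip.label))
  expect_setequal(vapply(got_sets, paste, "", collapse = "|"),
                  vapply(oracle_sets, paste, "", collapse = "|"))
  # disjoint
  all_tips <- unlist(got_sets)
  expect_equal(anyDuplicated(all_tips), 0)
  # invariant to uniform rescaling
  tr10 <- tr; tr10$edge.length <- tr10$edge.length * 10
  sub10 <- extract_midpoint_subclades(tr10, min_tips = 10)
  expect_setequal(vapply(sub10, function(s) paste(sort(s$tip.label),
                                                  collapse = "|"), ""),
                  vapply(got_sets, paste, "", collapse = "|"))
})

test_that("trait tables align, drop extras and prune on request", {
  tr <- tree3()
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = c("C", "A", "B", "Z"),
                       mass = c(3, 1, 2, 9), pc1 = c(0.3, 0.1, 0.2, 0.9)),
            f, row.names = FALSE)
  expect_message(res <- read_trait_table(f, tr), "dropped")
  expect_equal(res$traits$mass, c(A = 1, B = 2, C = 3))
  expect_equal(names(res$traits), c("mass", "pc1"))
  expect_equal(res$dropped_species, "Z")

  write.csv(data.frame(species = c("A", "B"), mass = c(1, 2)),
            f, row.names = FALSE)
  expect_error(read_trait_table(f, tr), "prune")
  res2 <- read_trait_table(f, tr, prune = TRUE)
  expect_equal(ape::Ntip(res2$tree), 2)
  expect_equal(res2$traits$mass, c(A = 1, B = 2))
  unlink(f)
})
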