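test_that("BM maximum likelihood matches the closed-form GLS estimator", {
  tr <- unit_tree(40, seed = 14)
  x <- simulate_trait(tr, model_spec("BM", sig2 = 0.1, z0 = 0.5),
                      seed = 15)
  f <- fit_trait_model(tr, x, "BM")
  C1 <- ape::vcv(tr)
  Ci <- solve(C1)
  one <- rep(1, 40)
  z0 <- as.numeric(t(one) %*% Ci %*% x) / as.numeric(t(one) %*% Ci %*% one)
  s2 <- as.numeric(t(x - z0) %*% Ci %*% (x - z0)) / 40
  expect_equal(f$params$sig2, s2, tolerance = 1e-6)
  expect_equal(f$params$z0, z0, tolerance = 1e-6)
  expect_equal(f$aicc, aicc(f$loglik, 2, 40))
})

test_that("fitted likelihood dominates the generating parameters", {
  tr <- unit_tree(25, seed = 16)
  specs <- list(model_spec("OU", sig2 = 0.1, alpha = 1, z0 = 0),
                model_spec("DDexp", sig2 = 0.1, rate_n = 0.05, z0 = 0),
                model_spec("MC", sig2 = 0.1, S = -2, z0 = 0))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    x <- simulate_trait(tr, spec, seed = 20 + i)
    f <- fit_trait_model(tr, x, spec$name)
    ll_true <- loglik_mvnorm(x, model_moments(tr, spec))
    expect_gte(f$loglik, ll_true)
  }
})

test_that("AICc formula, large-n limit and domain", {
  expect_equal(aicc(-10, 2, 20), 24 + 12 / 17)
  expect_equal(aicc(-10, 3, 1e9), -2 * -10 + 6, tolerance = 1e-6)
  expect_error(aicc(-10, 3, 4), "AICc undefined")
  expect_error(fit_trait_model(unit_tree(4, seed = 1),
                               setNames(rnorm(4), unit_tree(4, seed = 1)$tip.label),
                               "OU"), "positive")
})

test_that("MC fitted to interaction-free data stays near S = 0", {
  tr <- unit_tree(25, seed = 17)
  n_bad <- 0
  for (r in 1:25) {
    x <- simulate_trait(tr, model_spec("BM", sig2 = 0.1), seed = 300 + r)
    fb <- fit_trait_model(tr, x, "BM")
    fm <- fit_trait_model(tr, x, "MC")
    if (fm$aicc < fb$aicc - 2) n_bad <- n_bad + 1
  }
  expect_lte(n_bad, 2)  # nesting: spurious MC preference must be rare
})

test_that("model comparison applies the delta-AICc competition rule", {
  mkfit <- function(model, aicc_val, n = 30) {
    k <- if (model == "BM") 2 else 3
    ll <- -(aicc_val - 2 * k - 2 * k * (k + 1) / (n - k - 1)) / 2
    structure(list(model = model, structured = FALSE,
                   params = list(sig2 = 1, z0 = 0), loglik = ll, k = k,
                   n = n, aicc = aicc_val, converged = TRUE,
                   n_starts_used = 5L, map_id = NA_character_),
              class = "trait_fit")
  }
  cmp <- compare_models(list(mkfit("BM", 100), mkfit("OU", 99),
                             mkfit("DDexp", 96.5)))
  expect_equal(cmp$best_model, "DDexp")
  expect_true(cmp$competition_flag)

  cmp2 <- compare_models(list(mkfit("BM", 100), mkfit("DDexp", 98.5)))
  expect_false(cmp2$competition_flag)

  # pure function of the fits: permutation invariance
  fits <- list(mkfit("MC", 97), mkfit("BM", 100), mkfit("TDexp", 99),
               mkfit("DDlin", 98))
  c1 <- compare_models(fits)
  c2 <- compare_models(rev(fits))
  expect_equal(c1$best_model, c2$best_model)
  expect_equal(c1$competition_flag, c2$competition_flag)
  expect_equal(c1$table[order(c1$table$model), "delta_aicc"],
               c2$table[order(c2$table$model), "delta_aicc"])

  # exact ties resolve to fewer parameters, then name
  ct <- compare_models(list(mkfit("OU", 90), mkfit("BM", 90)))
  expect_equal(ct$best_model, "BM")

  # any-trait flag is the OR over traits
  comps <- list(
    `shape PC2` = compare_models(list(mkfit("OU", 99), mkfit("DDexp", 96))),
    size = compare_models(list(mkfit("OU", 99), mkfit("DDexp", 98.5))),
    mass = compare_models(list(mkfit("BM", 90), mkfit("MC", 95))))
  tab <- comparison_table(comps, clade = "cl1")
  expect_equal(unname(tab$flags), c(TRUE, FALSE, FALSE))
  expect_true(tab$any_trait_flag)
})

test_that("fitting aggregates over a list of regime maps", {
  tr <- unit_tree(21, seed = 18)
  x <- simulate_trait(tr, model_spec("BM", sig2 = 0.1), seed = 19)
  gs <- setNames(rep(c("1", "2"), length.out = 21), tr$tip.label)
  mk <- fit_mk(tr, gs)
  maps <- sample_maps(tr, mk, gs, n_maps = 3, seed = 20)
  f <- fit_trait_model(tr, x, "DDexp", regimes = maps)
  expect_length(f$per_map, 3)
  expect_equal(f$aicc,
               mean(vapply(f$per_map, `[[`, numeric(1), "aicc")))
  expect_equal(f$map_id, "mean(3)")
})

test_that("PGLS residuals reduce to OLS on a star and vanish on exact fits", {
  star <- suppressWarnings(read_tree("(A:1,B:1,C:1,D:1,E:1);"))
  y <- c(A = 1, B = 3, C = 2, D = 5, E = 4)
  x <- c(A = 0.5, B = 1.5, C = 1.1, D = 2.4, E = 2.0)
  r <- pgls_residuals(star, y, x)
  ols <- residuals(lm(y ~ x))
  expect_equal(as.numeric(r), unname(ols), tolerance = 1e-10)

  tr <- unit_tree(10, seed = 21)
  xx <- simulate_trait(tr, model_spec("BM", sig2 = 1), seed = 22)
  expect_equal(as.numeric(pgls_residuals(tr, 2 * xx + 1, xx)),
               rep(0, 10), tolerance = 1e-10)

  # dense-matrix GLS oracle on a 5-tip tree
  t5 <- read_tree("(((A:1,B:1):1,C:2):1,(D:2,E:2):1);")
  y5 <- c(A = 0.3, B = 0.1, C = -0.4, D = 1.2, E = 0.8)
  x5 <- c(A = 1.0, B = 0.8, C = 0.2, D = 2.0, E = 1.7)
  C <- ape::vcv(t5)
  X <- cbind(1, x5)
  beta <- solve(t(X) %*% solve(C) %*% X, t(X) %*% solve(C) %*% y5)
  expect_equal(as.numeric(pgls_residuals(t5, y5, x5)),
               unname(y5 - as.numeric(X %*% beta)), tolerance = 1e-10)

  expect_error(pgls_residuals(t5, y5, setNames(rep(1, 5), names(x5))),
               "singular")
})
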