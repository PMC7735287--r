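test_that("BM, OU and TD covariances match their closed forms", {
  tr <- tree3()
  bm <- moments_independent(tr, model_spec("BM", sig2 = 0.5))
  expect_equal(bm$cov["A", "A"], 1.0)
  expect_equal(bm$cov["A", "B"], 0.5)
  expect_equal(bm$cov["A", "C"], 0)

  ou <- moments_independent(tr, model_spec("OU", sig2 = 2, alpha = 1))
  expect_equal(ou$cov["A", "B"], (1 - exp(-2)) * exp(-2),
               tolerance = 1e-12)
  expect_equal(ou$cov["A", "A"], 1 - exp(-4), tolerance = 1e-12)

  td <- moments_independent(tree2(),
                            model_spec("TDlin", sig2 = 1, slope_t = 1))
  # depth-1 2-tip tree: variance = sig2 * 1 + slope * 1/2
  expect_equal(td$cov[1, 1], 1.5)
  expect_equal(td$cov[1, 2], 0)
})

test_that("OU covariance agrees with numerical branch-ODE integration", {
  # dv/dt = sig2 - 2 alpha v integrated by RK4 along shared and total time
  tr <- tree3()
  sig2 <- 2; alpha <- 1
  rk4 <- function(v0, t0, t1, f, n = 4000) {
    h <- (t1 - t0) / n; v <- v0
    for (i in seq_len(n)) {
      k1 <- f(v); k2 <- f(v + h / 2 * k1)
      k3 <- f(v + h / 2 * k2); k4 <- f(v + h * k3)
      v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    v
  }
  f <- function(v) sig2 - 2 * alpha * v
  var_num <- rk4(0, 0, 2, f)
  # shared part accumulates variance to t_ij = 1 then decays at rate
  # 2*alpha over the remaining (T - t_ij) of independent evolution
  cov_num <- rk4(0, 0, 1, f) * exp(-2 * alpha * 1)
  ou <- moments_independent(tr, model_spec("OU", sig2 = sig2,
                                           alpha = alpha))
  expect_equal(ou$cov["A", "A"], var_num, tolerance = 1e-8)
  expect_equal(ou$cov["A", "B"], cov_num, tolerance = 1e-8)
})

test_that("diversity-dependent covariances integrate the lineage count", {
  dd <- moments_diversity(tree4(),
                          model_spec("DDlin", sig2 = 1, slope_n = 0.5))
  expect_equal(dd$cov[1, 1], 5.0)  # (1+1)*1 + (1+2)*1
  # numerical quadrature oracle
  lc <- lineage_count(tree4())
  quad <- integrate(function(u) 1 + 0.5 * n_at(lc, u), 0, 2,
                    subdivisions = 1000)$value
  expect_equal(dd$cov[1, 1], quad, tolerance = 1e-4)
  # slope 0 reduces exactly to BM
  dd0 <- moments_diversity(tree4(),
                           model_spec("DDlin", sig2 = 0.7, slope_n = 0))
  bm <- moments_independent(tree4(), model_spec("BM", sig2 = 0.7))
  expect_equal(dd0$cov, bm$cov)
})

test_that("never-mixing guilds decompose DDexp into induced subtrees", {
  tr <- tree4()
  rmap <- two_guild_map()
  spec <- model_spec("DDexp", sig2 = 0.5, rate_n = 0.3, structured = TRUE)
  m <- moments_diversity(tr, spec, regimes = rmap)
  # oracle: each guild is a 2-tip depth-2 subtree with its own n(t):
  # one lineage on [0,1), two on [1,2]
  v_or <- 0.5 * (exp(0.3 * 1) * 1 + exp(0.3 * 2) * 1)
  c_or <- 0.5 * exp(0.3 * 1) * 1
  expect_equal(m$cov[1, 1], v_or, tolerance = 1e-9)
  expect_equal(m$cov[1, 2], c_or, tolerance = 1e-9)
  expect_equal(m$cov[1, 3], 0)
  expect_equal(m$cov[2, 4], 0)
})

test_that("MC moments match closed forms and degenerate correctly", {
  # S = 0 is exactly BM
  tr <- unit_tree(10, seed = 6)
  m0 <- moments_mc(tr, model_spec("MC", sig2 = 1.3, S = 0))
  expect_equal(unname(m0$cov),
               unname(1.3 * ape::vcv(tr)), tolerance = 1e-12)
  # 2-tip sum/difference decoupling: var = (Var(w) + Var(s))/4
  m <- moments_mc(tree2(), model_spec("MC", sig2 = 1, S = -1))
  expect_equal(m$cov[1, 1], ((exp(2) - 1) + 2) / 4, tolerance = 1e-10)
  expect_equal(m$cov[1, 2], (2 - (exp(2) - 1)) / 4, tolerance = 1e-10)
  # two singleton guilds never interact: BM again
  t2 <- tree2()
  sep <- regime_map(t2, list(setNames(1, "a"), setNames(1, "b")))
  ms <- moments_mc(t2, model_spec("MC", sig2 = 1, S = -2), regimes = sep)
  expect_equal(unname(ms$cov), diag(2), tolerance = 1e-12)
  # everyone in one guild equals regimes = NULL
  one <- single_regime_map(tr)
  ma <- moments_mc(tr, model_spec("MC", sig2 = 1, S = -1.5), regimes = one)
  mb <- moments_mc(tr, model_spec("MC", sig2 = 1, S = -1.5))
  expect_equal(ma$cov, mb$cov, tolerance = 1e-12)
  expect_error(model_spec("MC", S = 1), "<= 0")
})

test_that("log-likelihood matches dense multivariate-normal algebra", {
  expect_equal(loglik_mvnorm(0, tip_moments(0, diag(1))),
               -0.5 * log(2 * pi))
  tr <- tree3()
  x <- c(A = 0.2, B = -0.1, C = 0.4)
  mom <- moments_independent(tr, model_spec("BM", sig2 = 0.5, z0 = 0.1))
  # dense oracle via explicit inverse and determinant
  V <- 0.5 * matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3)
  r <- x - 0.1
  ll_or <- -0.5 * (3 * log(2 * pi) + determinant(V)$modulus +
                   t(r) %*% solve(V) %*% r)
  expect_equal(loglik_mvnorm(x, mom), as.numeric(ll_or),
               tolerance = 1e-10)
  # translation invariance
  mom2 <- tip_moments(mom$mean + 3, mom$cov)
  expect_equal(loglik_mvnorm(x + 3, mom2), loglik_mvnorm(x, mom))
})

test_that("all reductions to BM hold as exact likelihood equalities", {
  tr <- unit_tree(15, seed = 8)
  x <- simulate_trait(tr, model_spec("BM", sig2 = 0.2), seed = 9)
  ll <- function(spec) loglik_mvnorm(x, model_moments(tr, spec))
  base <- ll(model_spec("BM", sig2 = 0.2, z0 = 0))
  specs <- list(
    model_spec("OU", sig2 = 0.2, alpha = 0),
    model_spec("TDlin", sig2 = 0.2, slope_t = 0),
    model_spec("TDexp", sig2 = 0.2, rate_t = 0),
    model_spec("DDlin", sig2 = 0.2, slope_n = 0),
    model_spec("DDexp", sig2 = 0.2, rate_n = 0),
    model_spec("MC", sig2 = 0.2, S = 0))
  for (s in specs) expect_equal(ll(s), base, tolerance = 1e-6)
})

test_that("covariances are equivariant under tip reordering", {
  tr <- unit_tree(12, seed = 10)
  m1 <- model_moments(tr, model_spec("MC", sig2 = 1, S = -2))
  tr2 <- ape::rotate(tr, ape::Ntip(tr) + 1)
  tr2 <- read_tree(write_tree(tr2))  # renumber
  m2 <- model_moments(tr2, model_spec("MC", sig2 = 1, S = -2))
  perm <- match(rownames(m2$cov), rownames(m1$cov))
  expect_equal(unname(m2$cov), unname(m1$cov[perm, perm]),
               tolerance = 1e-9)
})

test_that("likelihood moments match simulation moments for every model", {
  # the module's central oracle: exact tip moments vs empirical moments of
  # ensembles of exact/Euler simulations. Summary statistics (mean, trace)
  # are held to 3 Monte-Carlo standard errors; elementwise covariance
  # agreement uses a 4.5-SE bound to account for testing ~30 entries at
  # once (an a priori multiplicity correction).
  tr <- unit_tree(8, seed = 12)
  rmap <- NULL
  R <- 4000
  cfgs <- list(
    list(spec = model_spec("BM", sig2 = 0.5, z0 = 0.3)),
    list(spec = model_spec("OU", sig2 = 0.5, alpha = 2, z0 = -1)),
    list(spec = model_spec("TDlin", sig2 = 0.5, slope_t = 0.4)),
    list(spec = model_spec("TDexp", sig2 = 0.5, rate_t = 1.2)),
    list(spec = model_spec("DDlin", sig2 = 0.5, slope_n = 0.2)),
    list(spec = model_spec("DDexp", sig2 = 0.3, rate_n = 0.25)),
    list(spec = model_spec("MC", sig2 = 0.5, S = -2)))
  for (cfg in cfgs) {
    spec <- cfg$spec
    mom <- model_moments(tr, spec)
    x <- simulate_trait(tr, spec, seed = 77, nsim = R)
    Vemp <- cov(t(x))
    se <- cov_se(mom$cov, R)
    expect_lt(max(abs(Vemp - mom$cov) / se), 4.5,
              label = paste("cov mismatch for", spec$name))
    se_tr <- sqrt(2 * sum(mom$cov^2) / R)
    expect_lt(abs(sum(diag(Vemp)) - sum(diag(mom$cov))) / se_tr, 3,
              label = paste("trace mismatch for", spec$name))
    se_mean <- sqrt(mean(diag(mom$cov)) / R)
    expect_lt(abs(mean(x) - spec$z0) / se_mean, 3,
              label = paste("mean mismatch for", spec$name))
  }
  # guild-structured DD and MC against Euler/structured simulation
  trs <- tree4()
  rmap <- two_guild_map()
  for (spec in list(model_spec("DDexp", sig2 = 0.4, rate_n = 0.3,
                               structured = TRUE),
                    model_spec("MC", sig2 = 0.6, S = -1.5,
                               structured = TRUE))) {
    mom <- model_moments(trs, spec, regimes = rmap)
    x <- simulate_trait(trs, spec, regimes = rmap, seed = 78, nsim = R)
    Vemp <- cov(t(x))
    se <- cov_se(mom$cov, R)
    expect_lt(max(abs(Vemp - mom$cov) / se), 4.5,
              label = paste("structured cov mismatch for", spec$name))
  }
})
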