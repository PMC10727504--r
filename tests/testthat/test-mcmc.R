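test_that("chain settings enforce their invariants", {
  expect_error(chain_settings(n_iter = 0))
  expect_error(chain_settings(n_iter = 100, burnin = 100))
  expect_error(chain_settings(sample_every = 0))
  s <- chain_settings(n_iter = 100, burnin = 10)
  expect_s3_class(s, "chain_settings")
})

test_that("a fixed seed reproduces the sample stream exactly", {
  net <- three_tip_tree()
  loci <- sim_loci(net, three_tip_params(), 5, 100)
  st <- chain_settings(n_iter = 120, burnin = 40, sample_every = 2, seed = 8)
  f1 <- run_mcmc(loci, net, settings = st)
  f2 <- run_mcmc(loci, net, settings = st)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$topology, f2$topology)
})

test_that("the posterior of theta matches grid quadrature on a toy locus", {
  one <- parse_network("A;")
  p <- param_set(numeric(), c(A = 0.01))
  set.seed(3)
  aln <- sim_alignment_jc69(sim_gene_tree(one, p, 2L), 50)
  x <- strsplit(aln$seqs[1], "")[[1]]
  y <- strsplit(aln$seqs[2], "")[[1]]
  nd <- sum(x != y); ns <- sum(x == y)
  # log-space grid quadrature over (theta, coalescent age)
  th <- exp(seq(log(1e-5), log(1), length.out = 2000))
  tt <- exp(seq(log(1e-7), log(1), length.out = 2000))
  loglik_t <- function(t) {
    e <- exp(-8 * t / 3)
    ns * log(0.25 * (0.25 + 0.75 * e)) + nd * log(0.25 * (0.25 - 0.25 * e))
  }
  lg <- outer(stats::dgamma(th, 4, 200, log = TRUE) + log(2 / th),
              loglik_t(tt), "+") - outer(2 / th, tt)
  w_th <- th * diff(log(th[1:2])); w_t <- tt * diff(log(tt[1:2]))
  P <- exp(lg - max(lg))
  e_theta <- as.numeric((w_th * th) %*% P %*% w_t) /
    as.numeric(w_th %*% P %*% w_t)
  fit <- run_mcmc(list(aln), one,
                  settings = chain_settings(n_iter = 20000, burnin = 2000,
                                            sample_every = 4, seed = 4))
  expect_lt(abs(mean(fit$samples$theta_A) - e_theta) / e_theta, 0.02)
})

test_that("a two-taxon block has a single topology with probability one", {
  net2 <- parse_network("(A,B)r;")
  p2 <- param_set(c(r = 0.01),
                  stats::setNames(rep(0.01, 3), c("A", "B", "r")))
  loci <- sim_loci(net2, p2, 4, 80)
  bp <- infer_block_species_tree(
    loci, settings = chain_settings(n_iter = 150, burnin = 50, n_runs = 2,
                                    seed = 5))
  expect_equal(length(bp$table), 1L)
  expect_equal(unname(bp$map_prob), 1)
  expect_equal(sum(bp$table), 1)
  expect_error(infer_block_species_tree(list(), taxa = "A"), "two taxa")
})

test_that("convergence assessment discards the deviant run and keeps ties", {
  same <- stats::setNames(c(0.8, 0.2), c("t1;", "t2;"))
  expect_equal(assess_convergence(rep(list(same), 5)), 1:5)
  runs <- c(rep(list(same), 9), list(stats::setNames(1, "t3;")))
  expect_equal(assess_convergence(runs), 1:9)
  # constructed boundary: TV to the median exactly at the threshold -> kept
  a <- stats::setNames(c(0.9, 0.1), c("x;", "y;"))
  b <- stats::setNames(c(0.8, 0.2), c("x;", "y;")) # TV to a = 0.1
  expect_equal(assess_convergence(list(a, a, b), threshold = 0.1), 1:3)
  # at least one run is always kept
  expect_equal(assess_convergence(list(a), threshold = 0), 1L)
})

test_that("zero-point and zero-locus marginal likelihoods behave", {
  one <- parse_network("A;")
  expect_equal(marginal_loglik_ti(list(), one)$logml, 0)
  expect_error(marginal_loglik_ti(list(), one, n_points = 0), "positive")
})

test_that("log Bayes factors are differences of log marginal likelihoods", {
  # identity check on the reported quantities
  mlA <- list(logml = -120.3)
  mlB <- list(logml = -118.1)
  expect_equal(mlA$logml - mlB$logml, -2.2)
})

test_that("Bayes-factor smoothing reproduces polynomials and an oracle", {
  x <- seq_len(20)
  expect_equal(smooth_bayes_factors(x, rep(3.5, 20)), rep(3.5, 20))
  y <- 2 - 0.5 * x + 0.03 * x^2
  expect_equal(smooth_bayes_factors(x, y), y, tolerance = 1e-9)
  expect_error(smooth_bayes_factors(1:2, 1:2), "3 points")
  # independent oracle: per-point weighted quadratic via lm()
  set.seed(11)
  yn <- sin(x / 3) + stats::rnorm(20, 0, 0.3)
  span <- 0.4
  q <- max(3L, ceiling(span * 20))
  oracle <- vapply(seq_along(x), function(i) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(q)]
    dmax <- max(d[idx])
    w <- if (dmax > 0) (1 - pmin(1, d[idx] / dmax)^3)^3 else rep(1, q)
    w[w <= 0] <- 1e-12
    fit <- stats::lm(yn[idx] ~ I(x[idx] - x[i]) + I((x[idx] - x[i])^2),
                     weights = w)
    unname(stats::coef(fit)[1])
  }, 0)
  expect_equal(smooth_bayes_factors(x, yn, span), oracle, tolerance = 1e-6)
  # and is in the same ballpark as loess with matching span and degree
  lo <- stats::predict(stats::loess(yn ~ x, span = span, degree = 2,
                                    surface = "direct"))
  expect_lt(max(abs(smooth_bayes_factors(x, yn, span) - lo)), 0.25)
})

test_that("whole-model scaling keeps the gene-tree density identity", {
  # the mixing move relies on: scaling all times and thetas by c changes the
  # log density by -(#coalescences) log c
  net <- three_tip_tree()
  p <- three_tip_params()
  tr <- sim_gene_tree(net, p, 2L, seed = 6)
  d0 <- msc_logdensity(tr, net, p)
  cc <- 1.37
  p2 <- param_set(p$tau * cc, p$theta * cc)
  tr2 <- tr
  tr2$age <- tr$age * cc
  d1 <- msc_logdensity(tr2, net, p2)
  expect_equal(d1, d0 - (length(tr$labels) - 1) * log(cc), tolerance = 1e-10)
})
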