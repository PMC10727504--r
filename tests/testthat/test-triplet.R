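test_that("class probabilities normalize, nest and respect symmetry", {
  par <- c(tau1 = 0.005, tau0 = 0.01, theta1 = 0.01, theta2 = 0.008,
           theta4 = 0.012, theta5 = 0.006, M12 = 0.3, M21 = 0.1)
  p <- mscflow:::triplet_class_probs(par)
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-8)
  par0 <- par; par0[c("M12", "M21")] <- 0
  expect_equal(mscflow:::triplet_class_probs(par0),
               mscflow:::triplet_class_probs(par[1:6]), tolerance = 1e-12)
  sym <- c(tau1 = 0.007, tau0 = 0.007, theta1 = 0.012, theta2 = 0.012,
           theta4 = 0.01, theta5 = 0.01)
  ps <- mscflow:::triplet_class_probs(sym)
  expect_equal(ps["113", ], ps["223", ], tolerance = 1e-10)
  expect_equal(ps["123", 3], ps["123", 4], tolerance = 1e-12)
})

test_that("the genealogy-averaged class probabilities match a MC oracle", {
  net <- triplet_net()
  p <- triplet_params(tau1 = 0.005, tau0 = 0.012, theta = 0.01,
                      M12 = 0.5, M21 = 0.2)
  par <- c(tau1 = 0.005, tau0 = 0.012, theta1 = 0.01, theta2 = 0.01,
           theta4 = 0.01, theta5 = 0.01, M12 = 0.5, M21 = 0.2)
  set.seed(42)
  n <- 1500
  draws <- matrix(0, n, 5)
  for (i in seq_len(n)) {
    tr <- sim_gene_tree(net, p, c(S1 = 1, S2 = 1, S3 = 1))
    ages <- sort(tr$age[4:5])
    first <- (4:5)[order(tr$age[4:5])[1]]
    ch <- which(tr$parent == first)
    pair <- sort(match(tr$species[ch[ch <= 3]], c("S1", "S2", "S3")))
    draws[i, ] <- matrix_class_probs(ages[1], ages[2], pair)
  }
  mc <- colMeans(draws)
  se <- apply(draws, 2, stats::sd) / sqrt(n)
  cl <- mscflow:::triplet_class_probs(par)["123", ]
  expect_true(all(abs(mc - cl) <= 3 * se + 1e-6))
})

test_that("triplet sampling respects configuration probabilities", {
  net <- triplet_net()
  p <- triplet_params()
  set.seed(2)
  loci <- sim_loci(net, p, 1200, 30, samples = c(S1 = 2, S2 = 2, S3 = 1))
  td <- sample_triplets(loci, c("S1", "S2"), "S3", seed = 9)
  fr <- table(td$config) / td$n_loci
  expect_lt(abs(fr[["123"]] - 0.5), 3 * sqrt(0.25 / 1200) + 0.01)
  expect_lt(abs(fr[["113"]] - 0.25), 3 * sqrt(0.25 / 1200) + 0.01)
  # determinism
  td2 <- sample_triplets(loci, c("S1", "S2"), "S3", seed = 9)
  expect_identical(td$counts, td2$counts)
  expect_identical(td$config, td2$config)
  # single haploid per ingroup species: only 123 is feasible
  loci1 <- sim_loci(net, p, 50, 30, samples = 1L)
  td1 <- sample_triplets(loci1, c("S1", "S2"), "S3", seed = 3)
  expect_true(all(td1$config == "123"))
})

test_that("M0 exposes six parameters and M2 nests M0", {
  net <- triplet_net()
  p <- triplet_params()
  set.seed(5)
  loci <- sim_loci(net, p, 150, 300, samples = c(S1 = 2, S2 = 2, S3 = 1))
  td <- sample_triplets(loci, c("S1", "S2"), "S3", seed = 1)
  f0 <- fit_triplet(td, "M0", n_restarts = 2, seed = 2,
                    control = list(rel.tol = 1e-7, iter.max = 120))
  expect_named(coef(f0), c("tau1", "tau0", "theta1", "theta2", "theta4",
                           "theta5"))
  expect_equal(attr(logLik(f0), "df"), 6)
  expect_true(all(f0$restarts$loglik <= f0$loglik + 1e-6))
  # nesting: M2 at the M0 optimum with M = 0 gives the same likelihood
  par2 <- c(coef(f0), M12 = 0, M21 = 0)
  expect_equal(triplet_loglik(par2, td), triplet_loglik(coef(f0), td),
               tolerance = 1e-9)
  f2 <- suppressWarnings(fit_triplet(td, "M2", n_restarts = 1, seed = 3,
                                     start = coef(f0)))
  expect_gte(f2$loglik, f0$loglik - 1e-3)
})

test_that("the LRT has the documented boundary behaviour", {
  f0 <- structure(list(model = "M0", loglik = -100), class = "triplet_fit")
  f2 <- structure(list(model = "M2", loglik = -100), class = "triplet_fit")
  r <- lrt_m0_m2(f0, f2)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant_at_1pct)
  f2$loglik <- -100 + 9.210340 / 2
  r2 <- lrt_m0_m2(f0, f2)
  expect_equal(r2$p_value, 0.01, tolerance = 1e-4)
  f2$loglik <- -101
  expect_warning(lrt_m0_m2(f0, f2), "optimization failure")
})

test_that("the internal-branch diagnostic flags star trees", {
  f <- structure(list(par = c(tau1 = 0.01, tau0 = 0.01)),
                 class = "triplet_fit")
  d <- internal_branch_diag(f)
  expect_equal(d$delta_tau, 0)
  expect_true(d$star_flag)
  f2 <- structure(list(par = c(tau1 = 0.005, tau0 = 0.01)),
                  class = "triplet_fit")
  expect_false(internal_branch_diag(f2)$star_flag)
})

test_that("a misassigned outgroup collapses the fitted internal branch", {
  # true tree ((S1,S3),S2) analysed as ((S1,S2),S3): expect star-tree flags;
  # correctly assigned data with dtau/theta = 1 should rarely flag
  net_wrong <- parse_network("((S1,S3)anc,S2)r;")
  p_wrong <- param_set(stats::setNames(c(0.012, 0.006), c("r", "anc")),
                       stats::setNames(c(0.01, 1e-6, 0.01, 0.01, 0.01),
                                       c("S1", "S2", "S3", "anc", "r")))
  net_right <- triplet_net()
  p_right <- triplet_params(tau1 = 0.005, tau0 = 0.015)
  flags_wrong <- flags_right <- logical(10)
  set.seed(17)
  ctl <- list(rel.tol = 1e-6, iter.max = 50, eval.max = 400)
  for (i in 1:10) {
    lw <- sim_loci(net_wrong, p_wrong, 120, 300,
                   samples = c(S1 = 2, S2 = 1, S3 = 2))
    tdw <- sample_triplets(lw, c("S1", "S2"), "S3")
    fw <- suppressWarnings(fit_triplet(tdw, "M0", n_restarts = 2,
                                       nq = 10, nl = 5, control = ctl))
    flags_wrong[i] <- internal_branch_diag(fw)$star_flag
    lr <- sim_loci(net_right, p_right, 120, 300,
                   samples = c(S1 = 2, S2 = 2, S3 = 1))
    tdr <- sample_triplets(lr, c("S1", "S2"), "S3")
    fr <- suppressWarnings(fit_triplet(tdr, "M0", n_restarts = 2,
                                       nq = 10, nl = 5, control = ctl))
    flags_right[i] <- internal_branch_diag(fr)$star_flag
  }
  expect_gte(sum(flags_wrong), 9)
  expect_lte(sum(flags_right), 1)
})

test_that("migration estimates vanish on no-gene-flow data", {
  net <- triplet_net()
  p <- triplet_params()
  set.seed(23)
  ctl <- list(rel.tol = 1e-6, iter.max = 50, eval.max = 400)
  m_hat <- replicate(5, {
    loci <- sim_loci(net, p, 200, 250, samples = c(S1 = 2, S2 = 2, S3 = 1))
    td <- sample_triplets(loci, c("S1", "S2"), "S3")
    f0 <- fit_triplet(td, "M0", n_restarts = 2, nq = 10, nl = 5,
                      control = ctl)
    f2 <- suppressWarnings(fit_triplet(td, "M2", n_restarts = 1,
                                       start = coef(f0), nq = 10, nl = 5,
                                       control = ctl))
    max(coef(f2)[c("M12", "M21")])
  })
  expect_lt(stats::median(m_hat), 0.05)
})
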