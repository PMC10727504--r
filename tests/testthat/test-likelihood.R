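test_that("jc69_transition matches the matrix exponential of the generator", {
  expect_equal(jc69_transition(0), diag(4), ignore_attr = TRUE)
  expect_equal(unname(jc69_transition(100)), matrix(0.25, 4, 4),
               tolerance = 1e-10)
  Q <- matrix(1 / 3, 4, 4); diag(Q) <- -1
  expect_equal(unname(jc69_transition(0.1)), pracma::expm(Q * 0.1),
               tolerance = 1e-6)
  expect_true(all(abs(rowSums(jc69_transition(0.37)) - 1) < 1e-12))
  expect_error(jc69_transition(-1), "negative")
})

test_that("gamma priors expose the right mean and normalize", {
  expect_equal(make_gamma_prior(7, 200)$mean, 0.035)
  expect_equal(make_gamma_prior(2, 10)$mean, 0.2)
  expect_equal(make_gamma_prior(1, 1)$mean, 1)
  g <- make_gamma_prior(4, 200)
  expect_equal(stats::integrate(function(x) exp(g$logpdf(x)), 0, Inf)$value,
               1, tolerance = 1e-6)
  expect_error(make_gamma_prior(-1, 2), "positive")
})

test_that("pruning equals brute-force enumeration and base-case formulas", {
  net <- four_tip_tree()
  p <- four_tip_params()
  set.seed(21)
  for (rep in 1:3) {
    tr <- sim_gene_tree(net, p, 1L)
    aln <- sim_alignment_jc69(tr, 3)
    expect_equal(locus_loglik(tr, aln), brute_force_loglik(tr, aln),
                 tolerance = 1e-10)
  }
  # with an IUPAC heterozygote in the data
  tr <- sim_gene_tree(net, p, 1L)
  aln <- sim_alignment_jc69(tr, 3)
  s <- aln$seqs
  substr(s[1], 2, 2) <- "R"
  aln2 <- locus_alignment(s, aln$species)
  expect_equal(locus_loglik(tr, aln2), brute_force_loglik(tr, aln2),
               tolerance = 1e-10)
  # zero-length tree, identical sequences: n * log(1/4)
  z <- new_gene_tree_for_test(0)
  alnz <- sim_alignment_jc69(z, 40, seed = 3)
  expect_equal(locus_loglik(z, alnz), 40 * log(1 / 4))
})

test_that("pruning is invariant to tip reordering", {
  net <- four_tip_tree()
  tr <- sim_gene_tree(net, four_tip_params(), 1L, seed = 4)
  aln <- sim_alignment_jc69(tr, 200, seed = 5)
  aln_rev <- locus_alignment(rev(aln$seqs), rev(aln$species))
  expect_equal(locus_loglik(tr, aln), locus_loglik(tr, aln_rev))
})

test_that("MSC density matches the closed form for one population", {
  one <- parse_network("A;")
  p <- param_set(numeric(), c(A = 0.01))
  t <- 0.004
  tr <- new_gene_tree_for_test(2 * t) # coalescence age t
  tr$pop0 <- c(1L, 1L)
  expect_equal(msc_logdensity(tr, one, p),
               log(2 / 0.01) - 2 * t / 0.01)
})

test_that("MSC density integrates to the topology probability", {
  # ((A,B),C): P(first coalescence is A-B and happens below the root)
  net <- three_tip_tree()
  dt <- 0.006; th <- 0.01
  p <- three_tip_params(tau_ab = 0.01, tau_r = 0.01 + dt, theta = th)
  # joint density of (u, v): u = A-B age in (tau_ab, tau_r), v root age
  tip_id <- stats::setNames(net$nodes$id[net$nodes$type == "tip"],
                            net$nodes$label[net$nodes$type == "tip"])
  f <- function(u, v) {
    tr <- mscflow:::new_gene_tree(c(4L, 4L, 5L, 5L, 0L), c(0, 0, 0, u, v),
                                  tip_id[c("A", "B", "C")],
                                  c("A^1", "B^1", "C^1"), c("A", "B", "C"))
    exp(msc_logdensity(tr, net, p))
  }
  inner <- Vectorize(function(u)
    stats::integrate(Vectorize(function(v) f(u, v)), 0.01 + dt, Inf,
                     rel.tol = 1e-9)$value)
  pr <- stats::integrate(inner, 0.01, 0.01 + dt, rel.tol = 1e-8)$value
  expect_equal(pr, 1 - exp(-2 * dt / th), tolerance = 1e-5)
  # impossible tree: cross-species coalescence below the split
  bad <- mscflow:::new_gene_tree(c(4L, 4L, 5L, 5L, 0L),
                                 c(0, 0, 0, 0.005, 0.03),
                                 tip_id[c("A", "C", "B")],
                                 c("A^1", "C^1", "B^1"), c("A", "C", "B"))
  expect_equal(msc_logdensity(bad, net, p), -Inf)
})

test_that("MSC-I marginal over path indicators matches a hand enumeration", {
  # pair between the A and B branches; two sequences from A
  net <- parse_network("(((A)ha#H1,(B)hb#H1)ab,C)r;")
  th_a <- 0.008; th_b <- 0.02
  tau_h <- 0.004; tau_ab <- 0.012; tau_r <- 0.02
  p <- param_set(c(r = tau_r, ab = tau_ab, H1 = tau_h),
                 c(A = th_a, B = th_b, C = 0.01, ab = 0.01, r = 0.01),
                 c(ha = 0.3, hb = 0.6))
  t <- 0.007 # A-A coalescence age between tau_h and tau_ab
  ha <- net$nodes$id[net$nodes$label == "ha"]
  mk <- function(d1, d2) {
    tr <- mscflow:::new_gene_tree(c(3L, 3L, 0L), c(0, 0, t), c(4L, 4L),
                                  c("A^1", "A^2"), c("A", "A"))
    tr$pop0 <- rep(net$nodes$id[net$nodes$label == "A"], 2)
    tr$crossings <- matrix(c(1L, ha, d1, 2L, ha, d2), 2, 3, byrow = TRUE)
    tr
  }
  marg <- sum(vapply(list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)),
                     function(d) {
                       dd <- msci_logdensity(mk(d[1], d[2]), net, p)
                       if (is.finite(dd)) exp(dd) else 0
                     }, 0))
  # hand-derived: both-ancestral stays in the A branch (theta_a), both-donor
  # moves to the B branch (theta_b), split paths cannot coalesce before tau_ab
  phi <- 0.3
  pre <- exp(-2 * tau_h / th_a) # both lineages wait in the A branch first
  f_x <- function(th) (2 / th) * exp(-2 * (t - tau_h) / th)
  expect_equal(marg,
               pre * ((1 - phi)^2 * f_x(th_a) + phi^2 * f_x(th_b)),
               tolerance = 1e-12)
  # a missing indicator is an error, not a silent zero
  tr_bad <- mk(0L, 0L)
  tr_bad$crossings <- tr_bad$crossings[1, , drop = FALSE]
  expect_error(msci_logdensity(tr_bad, net, p), "indicator|inconsistent")
})

test_that("simulated MSC gene trees match the density (chi-squared binning)", {
  one <- parse_network("A;")
  p <- param_set(numeric(), c(A = 0.01))
  set.seed(31)
  ages <- replicate(4000, max(sim_gene_tree(one, p, 2L)$age))
  br <- stats::qexp(seq(0, 1, length.out = 11), rate = 200)
  cnt <- table(cut(ages, br))
  expect_gt(stats::chisq.test(cnt)$p.value, 0.001)
})

test_that("prior density normalizes over divergence times", {
  # caterpillar 4-tip tree: non-root times flat with density 2/tau0^2
  net <- four_tip_tree()
  priors <- prior_spec()
  th <- stats::setNames(rep(0.01, 7), c("A", "B", "C", "D", "ab", "abc", "r"))
  tau0 <- 0.02
  f <- function(t_ab, t_abc) {
    p <- param_set(c(r = tau0, abc = t_abc, ab = t_ab), th)
    exp(prior_logdensity(p, priors, net) -
          priors$root$logpdf(tau0) - sum(priors$theta$logpdf(th)))
  }
  inner <- Vectorize(function(t_abc)
    stats::integrate(Vectorize(function(t_ab) f(t_ab, t_abc)), 0, t_abc)$value)
  total <- stats::integrate(inner, 0, tau0, rel.tol = 1e-8)$value
  expect_equal(total, 1, tolerance = 1e-6)
  # phi outside [0,1] gives -Inf, not an error
  netp <- phi_net()
  pp <- phi_params()
  pp$phi["hb"] <- 1.2
  expect_equal(prior_logdensity(pp, priors, netp), -Inf)
})
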