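#' Maximum-likelihood isolation-with-migration analysis for species triplets
#'
#' Implements the triplet IM machinery for a species tree ((S1,S2),S3) with
#' continuous gene flow between S1 and S2 since their divergence: triplet
#' subsampling of phased sequences, exact likelihood for the no-gene-flow
#' model M0 (6 parameters: tau1, tau0, theta1, theta2, theta4 for the root
#' and theta5 for the S1-S2 ancestor; no theta3 because at most one sequence
#' per locus comes from S3) and the bidirectional IM model M2 (M0 plus M12,
#' M21 expected migrants per generation), multi-restart fitting, the
#' likelihood-ratio test with a chi-squared(2) null at the 1% level, and the
#' internal-branch (Delta tau = tau0 - tau1) star-tree diagnostic.
#'
#' The per-locus likelihood integrates the JC69 site-pattern probabilities
#' over the two coalescent ages against the genealogy density of a
#' structured coalescent: a continuous-time Markov chain on the populations
#' occupied by the two ingroup lineages (backward migration rate 4*M/theta,
#' pairwise coalescent rate 2/theta), evaluated by eigendecomposition /
#' matrix exponentials between time slices with Gauss-Legendre and
#' Gauss-Laguerre quadrature over the ages.
#'
#' @name triplet_im_model
NULL

# JC69 site-pattern class probabilities for a 3-taxon tree ((x,y):u, z):v,
# contemporary tips.  Classes: 1 xxx, 2 xxy (x=y!=z), 3 xyx, 4 yxx, 5 xyz.
# Closed forms in E2=exp(-4u/3) (tip branches), E1=exp(-4(v-u)/3) (internal),
# E3=exp(-4v/3) (z branch); c3 = c4 by tip exchangeability.
jc3_class_probs <- function(u, v) {
  E2 <- exp(-4 * u / 3)
  E1 <- exp(-4 * (v - u) / 3)
  E3 <- exp(-4 * v / 3)
  A <- E1 * E2^2 * E3
  B <- E1 * E2 * E3
  c1 <- 1 / 16 + 3 * E2^2 / 16 + 3 * A / 8 + 3 * B / 8
  c2 <- 3 / 16 + 9 * E2^2 / 16 - 3 * A / 8 - 3 * B / 8
  c3 <- 3 / 16 - 3 * E2^2 / 16 - 3 * A / 8 + 3 * B / 8
  c5 <- 3 / 8 - 3 * E2^2 / 8 + 3 * A / 4 - 3 * B / 4
  cbind(c1, c2, c3, c3, c5)
}

# map the pair-first topology onto the (s1,s2,s3) class order used in data
# rows of the return: class 1..5 as seen for ordered (s1, s2, outgroup)
pair_class_map <- function(cp, pair) {
  switch(pair,
         "12" = cp[, c(1, 2, 3, 4, 5), drop = FALSE],
         "13" = cp[, c(1, 3, 2, 4, 5), drop = FALSE],
         "23" = cp[, c(1, 3, 4, 2, 5), drop = FALSE])
}

# absorption density / survival of the 2-lineage migration CTMC.  The full
# chain over (pop of a, pop of b) has four states, but (1,2) and (2,1) are
# dynamically identical, so the chain lumps to three states:
# together-in-1, split, together-in-2.  m1: pop1 -> pop2 backward rate.
# Near-degenerate eigenvector bases (e.g. M -> 0 with theta1 = theta2) are
# broken by a tiny relative jitter of the rates; a direct matrix-exponential
# fallback remains for the residual cases.
triplet_ctmc <- function(th1, th2, M12, M21) {
  m1 <- 4 * M21 / th1 # lineage in pop 1 jumps backward into pop 2
  m2 <- 4 * M12 / th2
  c1 <- 2 / th1; c2 <- 2 / th2
  build <- function(m1, m2, c1, c2)
    matrix(c(-(2 * m1 + c1), 2 * m1, 0,
             m2, -(m1 + m2), m1,
             0, 2 * m2, -(2 * m2 + c2)), 3, 3, byrow = TRUE)
  for (eps in c(0, 1e-9, 1e-7, 1e-5)) {
    Q <- build(m1 * (1 + eps), m2 * (1 - eps),
               c1 * (1 + eps / 2), c2 * (1 - eps / 2))
    eg <- eigen(Q)
    rc <- tryCatch(rcond(eg$vectors), error = function(e) 0)
    if (all(is.finite(Re(eg$values))) && is.finite(rc) && rc > 1e-8)
      return(list(Q = Q, cvec = c(c1, 0, c2), eg = eg, ok = TRUE))
  }
  Q <- build(m1, m2, c1, c2)
  list(Q = Q, cvec = c(c1, 0, c2), eg = NULL, ok = FALSE)
}

# rows of exp(Q u) %*% w for many u, via the eigendecomposition (fallback:
# direct matrix exponentials)
ctmc_apply <- function(ct, pi0, w, us) {
  if (!length(us)) return(numeric(0))
  if (ct$ok) {
    V <- ct$eg$vectors
    a <- as.vector(pi0 %*% V) * as.vector(solve(V, w))
    out <- vapply(us, function(u) Re(sum(a * exp(ct$eg$values * u))), 0)
    pmax(out, 0)
  } else {
    vapply(us, function(u)
      max(0, as.numeric(pi0 %*% pracma::expm(ct$Q * u) %*% w)), 0)
  }
}

quad_nodes <- local({
  cache <- list()
  function(nq = 32, nl = 16) {
    key <- paste(nq, nl)
    if (is.null(cache[[key]])) {
      gl <- pracma::gaussLegendre(nq, 0, 1)
      la <- pracma::gaussLaguerre(nl)
      cache[[key]] <<- list(glx = gl$x, glw = gl$w, lax = la$x, law = la$w)
    }
    cache[[key]]
  }
})

# Quadrature grid for the triplet IM likelihood: genealogy "atoms"
# (u, v, first pair) with their JC69 class probabilities (shared across
# configurations) and per-configuration genealogy-measure weights.  The
# per-locus likelihood is sum_g w_g(config) * prod_class p_gc^(n_lc),
# i.e. the joint probability of the locus site patterns integrated over
# the two coalescent ages with Gauss-Legendre / Gauss-Laguerre nodes.
triplet_grid <- function(par, nq = 32, nl = 16) {
  tau1 <- par[["tau1"]]; tau0 <- par[["tau0"]]
  th1 <- par[["theta1"]]; th2 <- par[["theta2"]]
  th4 <- par[["theta4"]]; th5 <- par[["theta5"]]
  M12 <- if ("M12" %in% names(par)) par[["M12"]] else 0
  M21 <- if ("M21" %in% names(par)) par[["M21"]] else 0
  qn <- quad_nodes(nq, nl)
  ct <- triplet_ctmc(th1, th2, M12, M21)
  inits <- list("123" = c(0, 1, 0), "113" = c(1, 0, 0),
                "223" = c(0, 0, 1))
  ones <- rep(1, 3)
  v_off <- th4 * qn$lax / 2
  logp <- vector("list", 2 * nl + 3 * nl)
  Wl <- vector("list", length(logp))
  blk <- 0L
  # regions A and B: u nodes x v nodes, ingroup pair first
  if (tau1 > 0) {
    uA <- tau1 * qn$glx
    gA <- sapply(inits, function(pi0) ctmc_apply(ct, pi0, ct$cvec, uA))
    for (j in seq_len(nl)) {
      blk <- blk + 1L
      logp[[blk]] <- log(pmax(pair_class_map(
        jc3_class_probs(uA, tau0 + v_off[j]), "12"), 1e-300))
      Wl[[blk]] <- qn$law[j] * tau1 * qn$glw * gA
    }
    S1 <- vapply(inits, function(pi0) ctmc_apply(ct, pi0, ones, tau1), 0)
  } else S1 <- c("123" = 1, "113" = 1, "223" = 1)
  if (tau0 > tau1) {
    uB <- tau1 + (tau0 - tau1) * qn$glx
    dB <- (2 / th5) * exp(-2 * (uB - tau1) / th5)
    for (j in seq_len(nl)) {
      blk <- blk + 1L
      logp[[blk]] <- log(pmax(pair_class_map(
        jc3_class_probs(uB, tau0 + v_off[j]), "12"), 1e-300))
      Wl[[blk]] <- outer(qn$law[j] * (tau0 - tau1) * qn$glw * dB, S1)
    }
    S2 <- S1 * exp(-2 * (tau0 - tau1) / th5)
  } else S2 <- S1
  # region C: all three lineages in the root population
  uC <- tau0 + th4 * qn$lax / 6
  for (j in seq_len(nl)) {
    vC <- uC + th4 * qn$lax[j] / 2
    cp0 <- jc3_class_probs(uC, vC)
    wC <- outer(qn$law * qn$law[j] / 3, S2)
    for (pr in c("12", "13", "23")) {
      blk <- blk + 1L
      logp[[blk]] <- log(pmax(pair_class_map(cp0, pr), 1e-300))
      Wl[[blk]] <- wC
    }
  }
  W <- do.call(rbind, Wl[seq_len(blk)])
  colnames(W) <- names(inits)
  list(logp = do.call(rbind, logp[seq_len(blk)]), W = W)
}

# marginal site-pattern class probabilities (3 configs x 5 classes)
triplet_class_probs <- function(par, nq = 32, nl = 16) {
  g <- triplet_grid(par, nq, nl)
  out <- t(g$W) %*% exp(g$logp)
  dimnames(out) <- list(colnames(g$W), NULL)
  out
}

#' Triplet IM log-likelihood
#'
#' Sum over loci of the log joint probability of the locus site-pattern
#' counts, each locus integrating the site likelihood over the shared
#' genealogy (the two coalescent ages and the identity of the first
#' coalescing pair) under the structured-coalescent density.
#'
#' @param par named parameter vector: `tau1`, `tau0`, `theta1`, `theta2`,
#'   `theta4`, `theta5` and (model M2) `M12`, `M21`.
#' @param data a `triplet_data` from [sample_triplets()].
#' @param nq,nl Gauss-Legendre / Gauss-Laguerre node counts per dimension.
#' @return total log-likelihood over loci.
#' @export
triplet_loglik <- function(par, data, nq = 32, nl = 16) {
  if (par[["tau0"]] < par[["tau1"]]) stop("tau0 must be >= tau1")
  if (any(par[c("theta1", "theta2", "theta4", "theta5")] <= 0))
    stop("theta parameters must be positive")
  g <- triplet_grid(par, nq, nl)
  keep <- rowSums(g$W) > 0
  cfg <- match(data$config, colnames(g$W))
  mult <- if (is.null(data$mult)) rep(1, nrow(data$counts_locus))
          else data$mult
  cpp_triplet_loglik(data$counts_locus, cfg, mult,
                     g$logp[keep, , drop = FALSE],
                     log(pmax(g$W[keep, , drop = FALSE], 1e-300)))
}

# collapse loci with identical (configuration, class counts) into weighted
# records; the likelihood is unchanged but evaluations scale with the
# number of distinct records
aggregate_triplet_data <- function(data) {
  key <- paste(data$config, apply(data$counts_locus, 1, paste, collapse = ","))
  idx <- !duplicated(key)
  mult <- as.numeric(table(key)[key[idx]])
  out <- data
  out$counts_locus <- data$counts_locus[idx, , drop = FALSE]
  out$config <- data$config[idx]
  out$mult <- mult
  out
}

# site-pattern class counts for three aligned sequences
count_site_classes <- function(s1, s2, s3) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  c <- strsplit(toupper(s3), "")[[1]]
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T") &
    c %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]; c <- c[keep]
  cls <- ifelse(a == b & b == c, 1L,
         ifelse(a == b, 2L, ifelse(a == c, 3L, ifelse(b == c, 4L, 5L))))
  tabulate(cls, 5L)
}

#' Sample sequence triplets from a phased multilocus dataset
#'
#' At each locus one of three triplet configurations is drawn: `123` (one
#' sequence from each species) with probability 0.5, `113` (two from S1 plus
#' the outgroup) and `223` (two from S2) each with probability 0.25;
#' sequences are then chosen at random within the drawn configuration.  When
#' a configuration is infeasible at a locus (too few sequences) the draw is
#' renormalized over the feasible ones.
#'
#' @param loci list of `locus_alignment` objects with phased (haploid)
#'   sequences and species assignments.
#' @param ingroup character of length 2: the species treated as S1 and S2.
#' @param outgroup the outgroup species (S3).
#' @param seed optional integer seed.
#' @return a `triplet_data`: `counts` (3 x 5 site-pattern class counts
#'   summed over loci), `config` (per-locus configuration), `n_loci`.
#' @export
sample_triplets <- function(loci, ingroup, outgroup, seed = NULL) {
  stopifnot(length(ingroup) == 2, length(outgroup) == 1)
  with_seed(seed, {
    counts <- matrix(0, 3, 5, dimnames = list(c("123", "113", "223"), NULL))
    counts_locus <- matrix(0, length(loci), 5)
    config <- character(length(loci))
    base_p <- c("123" = 0.5, "113" = 0.25, "223" = 0.25)
    for (i in seq_along(loci)) {
      aln <- loci[[i]]
      i1 <- names(aln$seqs)[aln$species == ingroup[1]]
      i2 <- names(aln$seqs)[aln$species == ingroup[2]]
      io <- names(aln$seqs)[aln$species == outgroup]
      feas <- c("123" = length(i1) >= 1 && length(i2) >= 1 && length(io) >= 1,
                "113" = length(i1) >= 2 && length(io) >= 1,
                "223" = length(i2) >= 2 && length(io) >= 1)
      if (!any(feas)) stop("locus ", i, ": no feasible triplet configuration")
      pr <- base_p * feas
      cfg <- sample(names(base_p), 1, prob = pr / sum(pr))
      pick <- function(x, k) if (length(x) == 1L && k == 1L) x
                             else sample(x, k)
      trip <- switch(cfg,
        "123" = c(pick(i1, 1), pick(i2, 1), pick(io, 1)),
        "113" = c(pick(i1, 2), pick(io, 1)),
        "223" = c(pick(i2, 2), pick(io, 1)))
      cc <- count_site_classes(aln$seqs[[trip[1]]], aln$seqs[[trip[2]]],
                               aln$seqs[[trip[3]]])
      counts[cfg, ] <- counts[cfg, ] + cc
      counts_locus[i, ] <- cc
      config[i] <- cfg
    }
    structure(list(counts = counts, counts_locus = counts_locus,
                   config = config, n_loci = length(loci),
                   ingroup = ingroup, outgroup = outgroup),
              class = "triplet_data")
  })
}

#' @export
print.triplet_data <- function(x, ...) {
  cat("triplet_data:", x$n_loci, "loci; configuration fractions:\n")
  print(round(table(factor(x$config, c("123", "113", "223"))) /
              max(1, x$n_loci), 4))
  invisible(x)
}

triplet_bounds <- function(model) {
  nm <- c("tau1", "dtau", "theta1", "theta2", "theta4", "theta5")
  lo <- c(1e-7, 1e-7, rep(1e-5, 4))
  hi <- c(0.2, 0.2, rep(0.2, 4))
  if (model == "M2") {
    nm <- c(nm, "M12", "M21")
    lo <- c(lo, 0, 0)
    hi <- c(hi, 20, 20)
  }
  list(names = nm, lower = stats::setNames(lo, nm),
       upper = stats::setNames(hi, nm))
}

to_natural <- function(x) {
  par <- c(tau1 = x[["tau1"]], tau0 = x[["tau1"]] + x[["dtau"]],
           theta1 = x[["theta1"]], theta2 = x[["theta2"]],
           theta4 = x[["theta4"]], theta5 = x[["theta5"]])
  if ("M12" %in% names(x)) par <- c(par, M12 = x[["M12"]], M21 = x[["M21"]])
  par
}

#' Fit a triplet model by maximum likelihood with restarts
#'
#' Box-constrained quasi-Newton optimization (`nlminb`) from dispersed
#' random starting points.  Restarts whose optimum has any parameter within
#' a relative distance of 1e-4 of its box bound are flagged "extreme" and
#' excluded from the argmax; if all restarts are extreme the best overall is
#' returned with a warning.
#'
#' @param data a `triplet_data`.
#' @param model `"M0"` (no gene flow) or `"M2"` (bidirectional migration).
#' @param n_restarts independent optimization runs.
#' @param seed optional integer seed.
#' @param nq,nl quadrature node counts used during optimization (smaller
#'   than the reporting default for speed; both models in a comparison must
#'   use the same values).
#' @param start optional named vector of natural parameters used as one
#'   additional (first) starting point, e.g. an M0 fit warm-starting M2.
#' @param control passed to [stats::nlminb()].
#' @return a `triplet_fit` with elements `par` (named natural parameters
#'   including `tau0`), `loglik`, `model`, `restarts` (per-run table),
#'   `extreme` flags, `data`.
#' @export
fit_triplet <- function(data, model = c("M0", "M2"), n_restarts = 10,
                        seed = NULL, nq = 16, nl = 8, start = NULL,
                        control = list(rel.tol = 1e-8, iter.max = 500)) {
  model <- match.arg(model)
  b <- triplet_bounds(model)
  adata <- aggregate_triplet_data(data)
  obj <- function(x) {
    names(x) <- b$names
    -triplet_loglik(to_natural(x), adata, nq = nq, nl = nl)
  }
  with_seed(seed, {
    runs <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      x0 <- stats::setNames(exp(log(pmax(b$lower, 1e-6)) +
        stats::runif(length(b$names)) *
          (log(b$upper) - log(pmax(b$lower, 1e-6)))), b$names)
      # bias starts towards plausible magnitudes
      x0[c("tau1", "dtau")] <- stats::runif(2, 0.001, 0.03)
      x0[grep("theta", b$names)] <- stats::runif(4, 0.002, 0.03)
      if (model == "M2") x0[c("M12", "M21")] <- stats::runif(2, 0.01, 2)
      if (r == 1L && !is.null(start)) {
        sM <- function(k) if (k %in% names(start)) max(start[[k]], 0.01)
                          else 0.05
        x0[] <- pmin(pmax(c(start[["tau1"]],
                            max(start[["tau0"]] - start[["tau1"]], 1e-6),
                            start[["theta1"]], start[["theta2"]],
                            start[["theta4"]], start[["theta5"]],
                            if (model == "M2") c(sM("M12"), sM("M21"))),
                          b$lower + 1e-6), b$upper - 1e-6)
      }
      fit <- tryCatch(stats::nlminb(x0, obj, lower = b$lower,
                                    upper = b$upper, control = control),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        x <- stats::setNames(fit$par, b$names)
        rel_lo <- (x - b$lower) / (b$upper - b$lower)
        rel_hi <- (b$upper - x) / (b$upper - b$lower)
        # M = 0 is a legitimate boundary of the hypothesis space (the M0
        # null), not an optimization failure: only the upper bound counts
        rel_lo[grep("^M", b$names)] <- Inf
        runs[[r]] <- list(par = x, loglik = -fit$objective,
                          extreme = any(pmin(rel_lo, rel_hi) < 1e-4),
                          convergence = fit$convergence)
      }
    }
    runs <- runs[!vapply(runs, is.null, TRUE)]
    if (!length(runs)) stop("all optimization restarts failed")
    lls <- vapply(runs, `[[`, 0, "loglik")
    ext <- vapply(runs, `[[`, TRUE, "extreme")
    if (all(ext)) {
      warning("all restarts had boundary ('extreme') estimates; ",
              "returning the best overall")
      best <- which.max(lls)
    } else best <- which(!ext)[which.max(lls[!ext])]
    tab <- data.frame(restart = seq_along(runs), loglik = lls,
                      extreme = ext)
    structure(list(par = to_natural(runs[[best]]$par),
                   loglik = runs[[best]]$loglik, model = model,
                   restarts = tab, extreme = ext[best],
                   n_loci = data$n_loci),
              class = "triplet_fit")
  })
}

#' @export
print.triplet_fit <- function(x, ...) {
  cat("triplet_fit (", x$model, "): log-likelihood ",
      format(x$loglik, digits = 8), " over ", x$n_loci, " loci\n", sep = "")
  print(signif(x$par, 4))
  invisible(x)
}

#' @export
coef.triplet_fit <- function(object, ...) object$par

#' @export
logLik.triplet_fit <- function(object, ...) {
  # par reports (tau1, tau0, thetas, [M]); tau0 stands in for the free
  # internal-branch length, so the count of free parameters equals length(par)
  structure(object$loglik, df = length(object$par), class = "logLik")
}

#' Likelihood-ratio test of migration (M0 vs M2)
#'
#' `2 (l2 - l0)` referred to a chi-squared distribution with 2 degrees of
#' freedom at a 1% significance threshold.  A negative statistic beyond
#' numerical tolerance triggers a warning (suspected optimization failure)
#' and is floored at zero.
#'
#' @param fit0,fit2 `triplet_fit` objects for models M0 and M2 on the same
#'   data.
#' @return list with `statistic`, `p_value`, `significant_at_1pct`.
#' @export
lrt_m0_m2 <- function(fit0, fit2) {
  stopifnot(fit0$model == "M0", fit2$model == "M2")
  stat <- 2 * (fit2$loglik - fit0$loglik)
  if (stat < -1e-6)
    warning("log-likelihood of M2 below M0 (", format(stat),
            "); optimization failure suspected")
  stat <- max(0, stat)
  p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  list(statistic = stat, p_value = p, significant_at_1pct = p < 0.01)
}

#' Internal-branch (star-tree) diagnostic
#'
#' Near-zero internal branch length `Delta tau = tau0 - tau1` signals a
#' misspecified branching order (the fitted triplet collapses to a star
#' tree).
#'
#' @param fit a `triplet_fit`.
#' @param frac flag when `Delta tau` is below this fraction of `tau0`.
#' @return list with `delta_tau` and `star_flag`.
#' @export
internal_branch_diag <- function(fit, frac = 0.01) {
  dt <- fit$par[["tau0"]] - fit$par[["tau1"]]
  flag <- fit$par[["tau0"]] <= 0 || dt < frac * fit$par[["tau0"]]
  list(delta_tau = unname(dt), star_flag = flag)
}

#' Full triplet IM analysis (fit M0 and M2, test, diagnose)
#'
#' Convenience front end mirroring the per-species-pair analysis: fits both
#' models, runs the LRT at the 1% level and the star-tree diagnostic.
#'
#' @inheritParams fit_triplet
#' @return a `triplet_im` object with `fit0`, `fit2`, `lrt`, `diag`.
#' @export
triplet_im <- function(data, n_restarts = 10, seed = NULL) {
  with_seed(seed, {
    fit0 <- fit_triplet(data, "M0", n_restarts)
    # warm-start M2 at the M0 optimum so nesting holds even with few restarts
    fit2 <- fit_triplet(data, "M2", n_restarts, start = coef(fit0))
    structure(list(fit0 = fit0, fit2 = fit2, lrt = lrt_m0_m2(fit0, fit2),
                   diag = internal_branch_diag(fit0)),
              class = "triplet_im")
  })
}

#' @export
print.triplet_im <- function(x, ...) {
  print(x$fit0); print(x$fit2)
  cat(sprintf("LRT: 2dl = %.3f, p = %.4g (%ssignificant at 1%%)\n",
              x$lrt$statistic, x$lrt$p_value,
              if (x$lrt$significant_at_1pct) "" else "not "))
  cat(sprintf("Delta tau = %.5f%s\n", x$diag$delta_tau,
              if (x$diag$star_flag) " [star-tree flag]" else ""))
  invisible(x)
}

#' @export
summary.triplet_im <- function(object, ...) {
  data.frame(model = c("M0", "M2"),
             loglik = c(object$fit0$loglik, object$fit2$loglik),
             n_par = c(6, 8),
             row.names = NULL)
}
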