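#' MCMC chain settings
#'
#' Desk-scale defaults; analyses of real genomic blocks typically use far
#' longer chains (millions of iterations, thinning in the hundreds, 10
#' independent runs).
#'
#' @param n_iter post-burn-in iterations (sweeps).
#' @param burnin burn-in sweeps (step sizes are tuned here, then frozen).
#' @param sample_every thinning interval.
#' @param n_runs independent runs used by [infer_block_species_tree()].
#' @param seed optional integer seed.
#' @return a `chain_settings` list.
#' @export
chain_settings <- function(n_iter = 4000L, burnin = 1000L, sample_every = 2L,
                           n_runs = 4L, seed = NULL) {
  stopifnot(n_iter > 0, burnin > 0, sample_every > 0, n_runs > 0,
            burnin < n_iter)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 sample_every = as.integer(sample_every),
                 n_runs = as.integer(n_runs), seed = seed),
            class = "chain_settings")
}

# per-locus data prepared for the C++ kernels
prep_loci <- function(loci, net) {
  spm <- spm_build_ids(net)
  lapply(loci, function(aln) {
    sp <- aln$species
    bad <- setdiff(sp, net$tips)
    if (length(bad)) stop("alignment species not in the species tree: ",
                          paste(unique(bad), collapse = ","))
    pat <- alignment_patterns(aln$seqs)
    list(partials = as.numeric(pat$partials), weights = pat$weights,
         n_seq = length(aln$seqs),
         pop0 = as.integer(spm[sp]))
  })
}

spm_build_ids <- function(net) {
  nd <- net$nodes
  stats::setNames(nd$id[nd$type == "tip"], nd$label[nd$type == "tip"])
}

# flat-over-polytope initial parameter draw (validity is all that matters)
init_params_draw <- function(net, priors) {
  nd <- net$nodes
  for (try in 1:100) {
    tau <- numeric(0)
    tm <- rep(0, nrow(nd))
    root <- net$root
    assign_rec <- function(v, upper) {
      if (nd$type[v] == "tip") return()
      if (nd$type[v] == "div") {
        t <- if (is.na(nd$parent[v])) upper else stats::runif(1, 0.5, 0.95) * upper
        tm[v] <<- t; tau[nd$label[v]] <<- t
        for (k in nd$id[which(nd$parent == v)]) assign_rec(k, t)
      } else for (k in nd$id[which(nd$parent == v)]) assign_rec(k, upper)
    }
    t0 <- priors$root$sample(1)
    assign_rec(root, t0)
    ok <- TRUE
    if (nrow(net$pairs)) for (j in seq_len(nrow(net$pairs))) {
      win <- pair_window(net, tm, j)
      if (win[1] >= win[2]) { ok <- FALSE; break }
      t <- stats::runif(1, win[1], win[2])
      tau[net$pairs$label[j]] <- t
      tm[c(net$pairs$a[j], net$pairs$b[j])] <- t
    }
    if (!ok) next
    keys <- unique(theta_keys(net))
    theta <- stats::setNames(priors$theta$sample(length(keys)), keys)
    hlab <- nd$label[nd$type == "hyb"]
    phi <- stats::setNames(stats::runif(length(hlab)), hlab)
    p <- param_set(tau, theta, phi)
    if (!length(validate_params(net, p))) return(p)
  }
  stop("failed to draw valid initial parameters")
}

# Precomputed topology-dependent context: everything spm_build and
# prior_logdensity need except the current parameter values.  Rebuilt only
# when the species topology changes.
build_ctx <- function(net, priors) {
  nd <- net$nodes
  parent0 <- ifelse(is.na(nd$parent), 0L, nd$parent)
  div <- which(nd$type == "div")
  hyb <- which(nd$type == "hyb")
  h <- div_subtree_sizes(net)
  root <- net$root
  nonroot <- setdiff(div, root)
  np <- nrow(net$pairs)
  bots <- tops <- vector("list", np)
  if (np) for (j in seq_len(np)) {
    bb <- tt <- integer(0)
    for (hh in c(net$pairs$a[j], net$pairs$b[j])) {
      bot <- nd$id[which(parent0 == hh)][1]
      while (nd$type[bot] == "hyb") bot <- nd$id[which(parent0 == bot)][1]
      top <- parent0[hh]
      while (top > 0 && nd$type[top] == "hyb") top <- parent0[top]
      bb <- c(bb, bot); tt <- c(tt, top)
    }
    bots[[j]] <- bb; tops[[j]] <- tt
  }
  depth <- integer(nrow(nd))
  for (v in seq_len(nrow(nd))) {
    u <- v; d <- 0L
    while (parent0[u] > 0L) { u <- parent0[u]; d <- d + 1L }
    depth[v] <- d
  }
  list(net = net, parent0 = parent0, donor = nd$donor, depth = depth,
       div = div, div_labels = nd$label[div],
       hyb = hyb, hyb_labels = nd$label[hyb],
       keys_per_node = theta_keys(net),
       root = root, logh = sum(log(h[nonroot])), k = length(nonroot),
       np = np, pair_a = net$pairs$a, pair_b = net$pairs$b,
       pair_labels = net$pairs$label, pair_bots = bots, pair_tops = tops,
       ev_nodes = c(div, net$pairs$a),
       ev_kind = c(rep(0L, length(div)), rep(1L, np)),
       ev_n2 = c(rep(0L, length(div)), net$pairs$b))
}

ctx_times <- function(ctx, params) {
  tm <- numeric(length(ctx$parent0))
  tm[ctx$div] <- params$tau[ctx$div_labels]
  if (ctx$np) {
    pt <- params$tau[ctx$pair_labels]
    tm[ctx$pair_a] <- pt; tm[ctx$pair_b] <- pt
  }
  tm
}

spm_fast <- function(ctx, params, tm = NULL) {
  if (is.null(tm)) tm <- ctx_times(ctx, params)
  phi <- numeric(length(tm))
  if (length(ctx$hyb)) phi[ctx$hyb] <- params$phi[ctx$hyb_labels]
  evt <- tm[ctx$ev_nodes]
  # ties: process events deeper in the tree (closer to the tips) first
  o <- order(evt, -ctx$depth[ctx$ev_nodes])
  list(time = tm, parent = ctx$parent0, donor = ctx$donor, phi = phi,
       theta_above = unname(params$theta[ctx$keys_per_node]),
       ev_time = evt[o], ev_kind = ctx$ev_kind[o],
       ev_n1 = as.integer(ctx$ev_nodes[o]), ev_n2 = as.integer(ctx$ev_n2[o]))
}

prior_fast <- function(params, priors, ctx, tm = NULL) {
  if (length(params$phi) && any(params$phi < 0 | params$phi > 1)) return(-Inf)
  if (is.null(tm)) tm <- ctx_times(ctx, params)
  if (any(tm < 0)) return(-Inf)
  idx <- which(ctx$parent0 > 0)
  if (any(tm[ctx$parent0[idx]] < tm[idx])) return(-Inf)
  lp <- 0
  if (length(ctx$div)) {
    t0 <- tm[ctx$root]
    lp <- priors$root$logpdf(t0) + ctx$logh - ctx$k * log(t0)
  }
  if (ctx$np) for (j in seq_len(ctx$np)) {
    lo <- max(tm[ctx$pair_bots[[j]]])
    tt <- ctx$pair_tops[[j]]
    hi <- min(ifelse(tt > 0, tm[pmax(tt, 1L)], Inf))
    tj <- tm[ctx$pair_a[j]]
    if (!(tj > lo && tj < hi) || hi <= lo) return(-Inf)
    lp <- lp - log(hi - lo)
  }
  lp <- lp + sum(priors$theta$logpdf(params$theta))
  if (length(params$M)) lp <- lp + sum(priors$M$logpdf(params$M))
  lp
}

# canonical topology identifier (internal labels ignored)
topology_string <- function(net) {
  nd <- net$nodes
  kids <- split(nd$id, factor(ifelse(is.na(nd$parent), 0L, nd$parent),
                              levels = 0:nrow(nd)))
  rec <- function(v) {
    ks <- kids[[v + 1L]]
    if (!length(ks)) return(nd$label[v])
    ss <- sort(vapply(ks, rec, ""))
    if (length(ss) == 1L) return(ss) # skip degree-2 attachment nodes
    paste0("(", paste(ss, collapse = ","), ")")
  }
  paste0(rec(net$root), ";")
}

#' Metropolis-Hastings sampler for MSC / MSC-I models
#'
#' Blockwise Bayesian sampler over model parameters and per-locus gene
#' trees.  Moves: multiplier updates for theta and the root age,
#' sliding-window updates for non-root divergence times and shared
#' introgression times (with Bernoulli completion of hybrid-path
#' indicators), Gibbs updates for introgression probabilities, per-locus
#' gene-tree updates (independence resimulation from the coalescent prior
#' plus within-epoch node-age slides), a whole-model scaling ("mixing")
#' move, and an optional rooted nearest-neighbour-interchange move on the
#' species topology.  Step sizes are tuned towards 30% acceptance during
#' burn-in and then frozen.  With `beta < 1` the likelihood is tempered
#' (power posterior), which [marginal_loglik_ti()] uses.
#'
#' @param loci list of `locus_alignment` objects (may be empty: the chain
#'   then samples the prior).
#' @param net the species tree / network (fixed topology unless
#'   `estimate_topology`).
#' @param priors a [prior_spec()].
#' @param settings a [chain_settings()].
#' @param estimate_topology sample the species-tree topology (trees without
#'   introgression pairs only).
#' @param beta likelihood power in (0, 1].
#' @param init_params optional starting [param_set()].
#' @return an object of class `msc_fit` with elements `samples` (data frame
#'   of parameter draws, log-likelihood and log prior+density), `topology`
#'   (sampled topology strings), `accept` (acceptance rates), `net`,
#'   `settings`.
#' @export
run_mcmc <- function(loci, net, priors = prior_spec(),
                     settings = chain_settings(), estimate_topology = FALSE,
                     beta = 1, init_params = NULL) {
  stopifnot(beta > 0, beta <= 1)
  if (estimate_topology && nrow(net$pairs))
    stop("topology estimation is supported for trees without introgression")
  with_seed(settings$seed, {
    L <- length(loci)
    ld_loci <- prep_loci(loci, net)
    params <- if (is.null(init_params)) init_params_draw(net, priors)
              else init_params
    ctx <- build_ctx(net, priors)
    ctx$kids <- split(seq_len(nrow(net$nodes)),
                      factor(ctx$parent0, levels = 0:nrow(net$nodes)))[-1]
    ctx$theta_nodes <- split(seq_along(ctx$keys_per_node),
                             ctx$keys_per_node)
    spm <- spm_fast(ctx, params)
    lp <- prior_fast(params, priors, ctx)
    if (!is.finite(lp)) stop("initial parameters have zero prior density")
    trees <- lapply(ld_loci, function(d) cpp_sim_gene_tree(spm, d$pop0))
    ll <- vapply(seq_len(L), function(i)
      cpp_pruning(trees[[i]]$parent, trees[[i]]$age, ld_loci[[i]]$partials,
                  ld_loci[[i]]$weights, ld_loci[[i]]$n_seq), 0)
    ld <- if (L) as.numeric(cpp_density_many(spm, trees)) else numeric(0)
    n_div <- sum(net$nodes$type == "div")
    parts <- lapply(ld_loci, `[[`, "partials")
    wts <- lapply(ld_loci, `[[`, "weights")
    nseq <- vapply(ld_loci, `[[`, 0L, "n_seq")
    step <- list(theta = 0.6, tau = 0.4, root = 0.3, age = 0.8, mix = 0.25)
    acc <- list(); prop <- list()
    addn <- function(name, hits, props) {
      acc[[name]] <<- (if (is.null(acc[[name]])) 0 else acc[[name]]) + hits
      prop[[name]] <<- (if (is.null(prop[[name]])) 0 else prop[[name]]) + props
    }
    bump <- function(name, hit) {
      acc[[name]] <<- (if (is.null(acc[[name]])) 0 else acc[[name]]) + hit
      prop[[name]] <<- (if (is.null(prop[[name]])) 0 else prop[[name]]) + 1
    }
    tune <- function() {
      for (nm in names(step)) {
        key <- paste0("t_", nm)
        if (!is.null(prop[[key]]) && prop[[key]] >= 20) {
          rate <- acc[[key]] / prop[[key]]
          step[[nm]] <<- max(1e-3, min(50, step[[nm]] * exp(0.5 * (rate - 0.3))))
          acc[[key]] <<- 0; prop[[key]] <<- 0
        }
      }
    }
    # generic fixed-tree parameter move (tau / theta / hybrid tau)
    try_params <- function(params2, extra_lhr = 0, complete = FALSE,
                           family = "tau") {
      tm2 <- ctx_times(ctx, params2)
      lp2 <- prior_fast(params2, priors, ctx, tm2)
      hit <- 0
      if (is.finite(lp2)) {
        spm2 <- spm_fast(ctx, params2, tm2)
        logq <- 0
        if (complete && L) {
          ld2 <- numeric(L); used <- vector("list", L)
          bad <- FALSE
          for (i in seq_len(L)) {
            r <- cpp_density_complete(spm2, trees[[i]]$parent,
                                      trees[[i]]$age, trees[[i]]$pop0,
                                      trees[[i]]$crossings)
            ld2[i] <- r$logdens
            if (!is.finite(ld2[i])) { bad <- TRUE; break }
            used[[i]] <- r$used
            logq <- logq - r$logq # forward draw penalty
            # reverse move would redraw the crossings we drop now
            old <- trees[[i]]$crossings
            if (nrow(old)) {
              keep <- paste(r$used[, 1], r$used[, 2])
              dropped <- !(paste(old[, 1], old[, 2]) %in% keep)
              if (any(dropped)) {
                ph <- spm$phi[old[dropped, 2]]
                fl <- old[dropped, 3]
                logq <- logq + sum(ifelse(fl == 1, log(ph), log1p(-ph)))
              }
            }
          }
          if (!bad) {
            a <- (lp2 - lp) + (sum(ld2) - sum(ld)) + extra_lhr + logq
            if (log(stats::runif(1)) < a) {
              params <<- params2; spm <<- spm2; ld <<- ld2; lp <<- lp2
              for (i in seq_len(L))
                trees[[i]]$crossings <<- used[[i]][, 1:3, drop = FALSE]
              hit <- 1
            }
          }
        } else {
          ld2 <- if (L) as.numeric(cpp_density_many(spm2, trees))
                 else numeric(0)
          if (all(is.finite(ld2)) || !L) {
            a <- (lp2 - lp) + (sum(ld2) - sum(ld)) + extra_lhr
            if (is.finite(a) && log(stats::runif(1)) < a) {
              params <<- params2; spm <<- spm2; ld <<- ld2; lp <<- lp2
              hit <- 1
            }
          }
        }
      }
      bump(family, hit); bump(paste0("t_", sub("h$", "", family)), hit)
      invisible(hit)
    }
    nd0 <- net$nodes
    div_ids <- nd0$id[nd0$type == "div"]
    root_id <- net$root
    keys <- unique(theta_keys(net))
    hlabs <- nd0$label[nd0$type == "hyb"]
    n_rec <- floor(settings$n_iter / settings$sample_every)
    par_names <- c(if (length(params$tau)) paste0("tau_", names(params$tau)),
                   if (length(params$theta))
                     paste0("theta_", names(params$theta)),
                   if (length(params$phi)) paste0("phi_", names(params$phi)))
    samples <- matrix(NA_real_, n_rec, length(par_names) + 2,
                      dimnames = list(NULL, c(par_names, "loglik", "logpost")))
    topo <- character(n_rec)
    rec <- 0L
    total_iter <- settings$burnin + settings$n_iter
    for (it in seq_len(total_iter)) {
      tuning <- it <= settings$burnin
      ## --- per-locus gene-tree moves (resimulation + age slides), in C++
      if (L) {
        sw <- cpp_locus_sweep(spm, trees, parts, wts, nseq, ll, ld,
                              beta, step$age)
        trees <- sw$trees
        ll <- as.numeric(sw$ll); ld <- as.numeric(sw$ld)
        addn("resim", sw$acc_resim, L)
        addn("age", sw$acc_age, L)
        addn("t_age", sw$acc_mult, sw$prop_mult)
      }
      ## --- coalescent sufficient statistics (make theta / phi updates
      ##     independent of the number of loci)
      stats <- if (L) cpp_coal_stats(spm, trees) else NULL
      ## --- theta multiplier moves
      for (k in keys) {
        th0 <- params$theta[[k]]
        th2 <- th0 * exp(step$theta * (stats::runif(1) - 0.5))
        dld <- 0
        if (L) {
          S <- ctx$theta_nodes[[k]]
          cS <- if (length(S) == 1L) stats$C[, S]
                else rowSums(stats$C[, S, drop = FALSE])
          aS <- if (length(S) == 1L) stats$A[, S]
                else rowSums(stats$A[, S, drop = FALSE])
          dld <- cS * log(th0 / th2) + aS * (1 / th0 - 1 / th2)
        }
        a <- priors$theta$logpdf(th2) - priors$theta$logpdf(th0) +
          sum(dld) + log(th2 / th0)
        hit <- 0
        if (is.finite(a) && log(stats::runif(1)) < a) {
          params$theta[k] <- th2
          if (L) ld <- ld + dld
          hit <- 1
        }
        bump("theta", hit); bump("t_theta", hit)
      }
      spm <- spm_fast(ctx, params)
      lp <- prior_fast(params, priors, ctx)
      ## --- phi Gibbs updates from crossing counts
      if (length(hlabs)) {
        hid <- nd0$id[match(hlabs, nd0$label)]
        cnt1 <- if (L) colSums(stats$H1[, hid, drop = FALSE]) else
          numeric(length(hid))
        cnt0 <- if (L) colSums(stats$H0[, hid, drop = FALSE]) else
          numeric(length(hid))
        phi2 <- stats::rbeta(length(hid), 1 + cnt1, 1 + cnt0)
        if (L) {
          old <- unname(params$phi[hlabs])
          ld <- ld + as.numeric(
            stats$H1[, hid, drop = FALSE] %*% log(phi2 / old) +
            stats$H0[, hid, drop = FALSE] %*% log((1 - phi2) / (1 - old)))
        }
        params$phi <- stats::setNames(phi2, hlabs)
        spm <- spm_fast(ctx, params)
      }
      ## --- whole-model scaling (mixing) move
      {
        cc <- exp(step$mix * (stats::runif(1) - 0.5))
        p2 <- params
        p2$tau <- params$tau * cc
        p2$theta <- params$theta * cc
        lp2 <- prior_fast(p2, priors, ctx)
        hit <- 0
        if (is.finite(lp2)) {
          # scaling all ages and thetas leaves waiting terms invariant and
          # subtracts log(c) per coalescence from the gene-tree density
          ld2 <- if (L) ld - (nseq - 1) * log(cc) else numeric(0)
          ll2 <- if (L) as.numeric(cpp_pruning_many(trees, parts, wts,
                                                    nseq, cc))
                 else numeric(0)
          nsc <- length(params$tau) + length(params$theta) +
            sum(nseq - 1)
          a <- (lp2 - lp) + (sum(ld2) - sum(ld)) +
            beta * (sum(ll2) - sum(ll)) + nsc * log(cc)
          if (is.finite(a) && log(stats::runif(1)) < a) {
            params <- p2
            trees <- lapply(trees, function(tr) {
              tr$age <- tr$age * cc
              tr
            })
            spm <- spm_fast(ctx, params)
            ld <- ld2; ll <- ll2; lp <- lp2; hit <- 1
          }
        }
        bump("mix", hit); bump("t_mix", hit)
      }
      ## --- divergence-time moves
      tm <- ctx_times(ctx, params)
      for (dv in div_ids) {
        lab <- nd0$label[dv]
        ch <- ctx$kids[[dv]]
        lo <- if (length(ch)) max(tm[ch]) else 0
        if (dv == root_id) {
          t0 <- params$tau[[lab]]
          t2 <- t0 * exp(step$root * (stats::runif(1) - 0.5))
          if (t2 > lo) {
            p2 <- params; p2$tau[lab] <- t2
            if (try_params(p2, extra_lhr = log(t2 / t0), family = "root"))
              tm <- ctx_times(ctx, params)
          } else bump("root", 0)
        } else {
          pa <- nd0$parent[dv]
          hi <- tm[pa]
          if (hi > lo) {
            w <- step$tau * (hi - lo)
            t2 <- reflect_into(params$tau[[lab]] +
                                 w * (stats::runif(1) - 0.5), lo, hi)
            p2 <- params; p2$tau[lab] <- t2
            if (try_params(p2, family = "tau"))
              tm <- ctx_times(ctx, params)
          } else bump("tau", 0)
        }
      }
      ## --- shared introgression-time moves (with indicator completion)
      if (ctx$np) for (j in seq_len(ctx$np)) {
        tm <- ctx_times(ctx, params)
        win <- c(max(tm[ctx$pair_bots[[j]]]),
                 min(ifelse(ctx$pair_tops[[j]] > 0,
                            tm[pmax(ctx$pair_tops[[j]], 1L)], Inf)))
        if (win[2] > win[1]) {
          lab <- net$pairs$label[j]
          w <- step$tau * (win[2] - win[1])
          t2 <- reflect_into(params$tau[[lab]] +
                               w * (stats::runif(1) - 0.5), win[1], win[2])
          p2 <- params; p2$tau[lab] <- t2
          try_params(p2, complete = TRUE, family = "tauh")
        }
      }
      ## --- rooted NNI move on the species topology
      if (estimate_topology && length(net$tips) >= 3) {
        net2 <- nni_propose(net)
        hit <- 0
        if (!is.null(net2)) {
          ctx2 <- build_ctx(net2, priors)
          lp2 <- prior_fast(params, priors, ctx2)
          if (is.finite(lp2)) {
            spm2 <- spm_fast(ctx2, params)
            ld2 <- if (L) as.numeric(cpp_density_many(spm2, trees))
                   else numeric(0)
            a <- (lp2 - lp) + (sum(ld2) - sum(ld))
            if (is.finite(a) && log(stats::runif(1)) < a) {
              net <- net2; spm <- spm2; ld <- ld2; lp <- lp2; hit <- 1
              ctx <- ctx2
              ctx$kids <- split(seq_len(nrow(net$nodes)),
                                factor(ctx$parent0,
                                       levels = 0:nrow(net$nodes)))[-1]
              ctx$theta_nodes <- split(seq_along(ctx$keys_per_node),
                                       ctx$keys_per_node)
              nd0 <- net$nodes
            }
          }
        }
        bump("nni", hit)
      }
      if (tuning && it %% 20 == 0) tune()
      if (!tuning) {
        k <- it - settings$burnin
        if (k %% settings$sample_every == 0 && rec < n_rec) {
          rec <- rec + 1L
          samples[rec, ] <- c(params$tau, params$theta,
                              if (length(params$phi)) params$phi,
                              sum(ll), lp + sum(ld))
          topo[rec] <- topology_string(net)
        }
      }
    }
    rates <- stats::setNames(
      vapply(names(acc), function(k)
        if (prop[[k]] > 0) acc[[k]] / prop[[k]] else NA_real_, 0),
      names(acc))
    structure(list(samples = as.data.frame(samples[seq_len(rec), ,
                                                   drop = FALSE]),
                   topology = topo[seq_len(rec)],
                   accept = rates[!startsWith(names(rates), "t_")],
                   net = net, settings = settings, beta = beta,
                   n_loci = L),
              class = "msc_fit")
  })
}

reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  if (y < 0) y <- y + 2 * w
  lo + if (y <= w) y else 2 * w - y
}

# symmetric rooted NNI proposal; NULL when the tree has no internal edge
nni_propose <- function(net) {
  nd <- net$nodes
  cand <- nd$id[nd$type == "div" & !is.na(nd$parent)]
  cand <- cand[nd$type[nd$parent[cand]] == "div"]
  if (!length(cand)) return(NULL)
  v <- if (length(cand) == 1L) cand else sample(cand, 1L)
  u <- nd$parent[v]
  ch_v <- nd$id[which(nd$parent == v)]
  sib <- setdiff(nd$id[which(nd$parent == u)], v)
  if (length(ch_v) != 2L || length(sib) != 1L) return(NULL)
  c1 <- if (stats::runif(1) < 0.5) ch_v[1] else ch_v[2]
  nd$parent[c1] <- u
  nd$parent[sib] <- v
  new_species_network(nd, net$root, net$pairs, net$annotations)
}

#' @export
print.msc_fit <- function(x, ...) {
  cat("msc_fit:", nrow(x$samples), "posterior samples,", x$n_loci,
      "loci, beta =", x$beta, "\n")
  if (length(unique(x$topology)) > 1L)
    cat("  topologies visited:", length(unique(x$topology)), "\n")
  print(utils::head(summary(x)), ...)
  invisible(x)
}

#' @export
summary.msc_fit <- function(object, prob = 0.95, ...) {
  s <- object$samples
  pars <- setdiff(colnames(s), c("loglik", "logpost"))
  a <- (1 - prob) / 2
  out <- data.frame(
    mean = vapply(pars, function(p) mean(s[[p]]), 0),
    lower = vapply(pars, function(p) stats::quantile(s[[p]], a), 0),
    upper = vapply(pars, function(p) stats::quantile(s[[p]], 1 - a), 0))
  rownames(out) <- pars
  out
}

#' @export
plot.msc_fit <- function(x, pars = NULL, ...) {
  s <- x$samples
  if (is.null(pars))
    pars <- utils::head(setdiff(colnames(s), c("loglik", "logpost")), 4)
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars)
    graphics::plot(s[[p]], type = "l", ylab = p, xlab = "", ...)
  invisible(x)
}

#' Blockwise species-tree posterior
#'
#' Runs `settings$n_runs` independent MCMC chains with topology estimation
#' from random starting trees, discards non-convergent runs by comparing
#' their topology posteriors ([assess_convergence()]), and combines the
#' remaining samples into one posterior summary with the MAP tree.
#'
#' @param loci list of `locus_alignment` objects (one block).
#' @param taxa character vector of species analysed (tips of the start
#'   trees); defaults to all species seen in the data.
#' @inheritParams run_mcmc
#' @return a `block_posterior`: posterior probabilities per topology,
#'   the MAP tree and its probability, and per-run posteriors.
#' @export
infer_block_species_tree <- function(loci, taxa = NULL,
                                     priors = prior_spec(),
                                     settings = chain_settings()) {
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(loci, function(a) a$species))))
  if (length(taxa) < 2) stop("need at least two taxa")
  with_seed(settings$seed, {
    run_tabs <- vector("list", settings$n_runs)
    for (r in seq_len(settings$n_runs)) {
      start <- random_network(length(taxa), 0L, tips = sample(taxa))
      s1 <- settings; s1$seed <- NULL
      fit <- run_mcmc(loci, start, priors, s1, estimate_topology = TRUE)
      tab <- table(fit$topology)
      run_tabs[[r]] <- as.numeric(tab) / sum(tab)
      names(run_tabs[[r]]) <- names(tab)
    }
    kept <- assess_convergence(run_tabs)
    topos <- sort(unique(unlist(lapply(run_tabs[kept], names))))
    mat <- sapply(run_tabs[kept], function(p) {
      v <- stats::setNames(numeric(length(topos)), topos)
      v[names(p)] <- p
      v
    })
    mat <- matrix(mat, nrow = length(topos), dimnames = list(topos, NULL))
    post <- rowMeans(mat)
    post <- post / sum(post)
    map <- which.max(post)
    structure(list(table = sort(post, decreasing = TRUE),
                   map_tree = names(post)[map],
                   map_prob = unname(post[map]),
                   runs = run_tabs, kept = kept),
              class = "block_posterior")
  })
}

#' @export
print.block_posterior <- function(x, ...) {
  cat("block_posterior: MAP", x$map_tree, "( P =",
      format(x$map_prob, digits = 3), ");", length(x$kept), "of",
      length(x$runs), "runs kept\n")
  print(utils::head(round(x$table, 4)))
  invisible(x)
}

#' Discard non-convergent MCMC runs
#'
#' A run is discarded when the total-variation distance between its
#' topology posterior and the coordinate-wise median posterior across runs
#' exceeds `threshold` (boundary inclusive: a run exactly at the threshold
#' is kept).  At least one run (the closest) is always kept.
#'
#' @param run_tabs list of named probability vectors (topology posteriors).
#' @param threshold total-variation distance cutoff.
#' @return integer indices of the kept runs.
#' @export
assess_convergence <- function(run_tabs, threshold = 0.1) {
  stopifnot(length(run_tabs) >= 1)
  if (length(run_tabs) == 1L) return(1L)
  topos <- sort(unique(unlist(lapply(run_tabs, names))))
  mat <- sapply(run_tabs, function(p) {
    v <- stats::setNames(numeric(length(topos)), topos)
    v[names(p)] <- p
    v
  })
  mat <- matrix(mat, nrow = length(topos))
  med <- apply(mat, 1L, stats::median)
  tv <- apply(mat, 2L, function(p) 0.5 * sum(abs(p - med)))
  kept <- which(tv <= threshold + 1e-12)
  if (!length(kept)) kept <- which.min(tv)
  kept
}

#' Marginal likelihood by thermodynamic integration
#'
#' Power-posterior chains are run at Gauss-Legendre quadrature points
#' `beta` on (0,1); the log marginal likelihood is the quadrature estimate
#' of the integral over `beta` of the posterior mean log-likelihood.
#'
#' @inheritParams run_mcmc
#' @param n_points number of Gauss-Legendre points (32 matches common
#'   practice; small problems are insensitive to this).
#' @return list with `logml`, and per-point `beta` / `mean_loglik`.
#' @export
marginal_loglik_ti <- function(loci, net, priors = prior_spec(),
                               settings = chain_settings(), n_points = 32) {
  if (n_points <= 0) stop("n_points must be positive")
  if (!length(loci)) return(list(logml = 0, beta = numeric(0),
                                 mean_loglik = numeric(0)))
  gl <- pracma::gaussLegendre(n_points, 0, 1)
  with_seed(settings$seed, {
    m <- numeric(n_points)
    for (i in seq_len(n_points)) {
      s1 <- settings; s1$seed <- NULL
      fit <- run_mcmc(loci, net, priors, s1, beta = gl$x[i])
      m[i] <- mean(fit$samples$loglik)
    }
    list(logml = sum(gl$w * m), beta = gl$x, mean_loglik = m)
  })
}

#' Smooth a series of log Bayes factors
#'
#' Local quadratic regression with tricube weights over the nearest
#' `span`-fraction of points, evaluated at each input position; the
#' standard treatment for noisy blockwise marginal-likelihood differences.
#'
#' @param position numeric positions (e.g. chromosome region index).
#' @param logbf log Bayes factors at those positions.
#' @param span fraction of points in each local window.
#' @return numeric vector of adjusted values at `position`.
#' @export
smooth_bayes_factors <- function(position, logbf, span = 0.4) {
  n <- length(position)
  if (n < 3) stop("need at least 3 points")
  stopifnot(length(logbf) == n)
  q <- max(3L, ceiling(span * n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(position - position[i])
    idx <- order(d)[seq_len(q)]
    dmax <- max(d[idx])
    w <- if (dmax > 0) (1 - pmin(1, d[idx] / dmax)^3)^3 else rep(1, q)
    w[w <= 0] <- 1e-12
    x <- position[idx] - position[i]
    X <- cbind(1, x, x^2)
    fit <- stats::lm.wfit(X, logbf[idx], w)
    out[i] <- fit$coefficients[1]
  }
  out
}
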