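#' JC69 transition probability table
#'
#' Equal-rates substitution model on the substitutions-per-site time scale:
#' `P(same) = 1/4 + (3/4) exp(-4t/3)`, off-diagonals equal.
#'
#' @param t branch length in expected substitutions per site (>= 0).
#' @return a 4x4 row-stochastic matrix over A,C,G,T.
#' @export
jc69_transition <- function(t) {
  if (t < 0) stop("negative branch length")
  e <- exp(-4 * t / 3)
  p <- matrix(0.25 - 0.25 * e, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(p) <- 0.25 + 0.75 * e
  p
}

# IUPAC partial-likelihood vectors: 1 over the compatible base set
iupac_partials <- function() {
  sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
               "?" = c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")
  out <- sapply(sets, function(s) as.numeric(bases %in% s))
  rownames(out) <- bases
  out
}

# collapse an alignment (in tree tip order) into tip partials over unique
# site patterns; returns list(partials = array[4, P, n], weights)
alignment_patterns <- function(seq_strings) {
  n <- length(seq_strings)
  chars <- do.call(rbind, strsplit(toupper(seq_strings), ""))
  pat <- apply(chars, 2L, paste, collapse = "")
  tab <- table(pat)
  upat <- names(tab)
  P <- length(upat)
  codes <- iupac_partials()
  partials <- array(0, c(4, P, n))
  for (p in seq_len(P)) {
    cs <- strsplit(upat[p], "")[[1]]
    bad <- !(cs %in% colnames(codes))
    if (any(bad)) stop("unknown residue '", cs[bad][1], "' in alignment")
    partials[, p, ] <- codes[, cs]
  }
  list(partials = partials, weights = as.numeric(tab))
}

#' Exact per-locus log-likelihood by pruning
#'
#' Felsenstein pruning under the JC69 model with per-pattern scaling.  IUPAC
#' ambiguity codes (including unphased diploid heterozygotes) and missing
#' symbols contribute a partial likelihood of 1 over their compatible base
#' set.
#'
#' @param tree a `gene_tree` whose tips cover the alignment labels.
#' @param aln a `locus_alignment` (labels must be a subset of the tree tips;
#'   here they must match the tree's tips exactly, order free).
#' @return the log-likelihood (finite for any non-degenerate input).
#' @export
locus_loglik <- function(tree, aln) {
  if (!length(aln$seqs)) stop("empty alignment")
  idx <- match(tree$labels, names(aln$seqs))
  if (anyNA(idx))
    stop("alignment is missing sequences for tips: ",
         paste(tree$labels[is.na(idx)], collapse = ","))
  pat <- alignment_patterns(aln$seqs[idx])
  cpp_pruning(tree$parent, tree$age, as.numeric(pat$partials), pat$weights,
              length(tree$labels))
}

#' MSC log-density of a gene tree within a species tree
#'
#' Product over populations of coalescent terms: each coalescence in a
#' population of size theta contributes `2/theta`, and each inter-event
#' interval with `k` lineages contributes `exp(-k(k-1) dt / theta)`.
#' Impossible trees (e.g. cross-species coalescence younger than the species
#' split) get `-Inf`.
#'
#' @inheritParams validate_params
#' @param tree a `gene_tree` with tip-to-species assignments.
#' @return log density.
#' @export
msc_logdensity <- function(tree, net, params) {
  if (nrow(net$pairs))
    stop("msc_logdensity is for networks without introgression; ",
         "use msci_logdensity")
  gene_density(tree, net, params)
}

#' MSC-I log-density of a gene tree with hybrid-path indicators
#'
#' Equals the MSC density on the path-expanded tree plus `log(phi)` for each
#' donor-path crossing and `log(1-phi)` for each ancestral-path crossing.
#' Every lineage present at a hybrid node must carry an indicator (the
#' simulator records them); a missing indicator is an error.
#'
#' @inheritParams msc_logdensity
#' @return log density.
#' @export
msci_logdensity <- function(tree, net, params) {
  gene_density(tree, net, params)
}

gene_density <- function(tree, net, params, spm = NULL) {
  if (is.null(spm)) {
    viol <- validate_params(net, params)
    if (length(viol)) stop("invalid parameters: ", paste(viol, collapse = "; "))
    spm <- spm_build(net, params)
  }
  d <- cpp_gene_density(spm, tree$parent, tree$age, tree$pop0, tree$crossings)
  if (is.na(d))
    stop("gene tree is inconsistent with the species model ",
         "(missing hybrid-path indicator or malformed tree)")
  d
}

# ---- priors ----------------------------------------------------------------

#' Gamma prior object
#'
#' @param shape,rate gamma parameters (> 0); the mean is `shape/rate`.
#' @return a `gamma_prior` with elements `shape`, `rate`, `mean`, `logpdf(x)`
#'   and `sample(n)`.
#' @examples
#' make_gamma_prior(7, 200)$mean   # 0.035
#' @export
make_gamma_prior <- function(shape, rate) {
  if (shape <= 0 || rate <= 0) stop("shape and rate must be positive")
  structure(list(shape = shape, rate = rate, mean = shape / rate,
                 logpdf = function(x) stats::dgamma(x, shape, rate, log = TRUE),
                 sample = function(n) stats::rgamma(n, shape, rate)),
            class = "gamma_prior")
}

#' Prior specification for MSC / MSC-I models
#'
#' Defaults follow the diffuse priors used for butterfly-scale data: root age
#' `tau0 ~ G(7, 200)` (mean 0.035 substitutions/site), `theta ~ G(4, 200)`
#' (mean 0.02), introgression probabilities `phi ~ U(0,1)`, migration rates
#' `M ~ G(2, 10)` (mean 0.2).  Given `tau0`, non-root divergence times are
#' uniform-Dirichlet: flat over the order-constrained feasible region.
#'
#' @param root,theta,M `gamma_prior` objects.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(root = make_gamma_prior(7, 200),
                       theta = make_gamma_prior(4, 200),
                       M = make_gamma_prior(2, 10)) {
  structure(list(root = root, theta = theta, M = M), class = "prior_spec")
}

# number of divergence nodes in the divergence subtree of each div node;
# used in the uniform-Dirichlet normalization (flat density over the age
# polytope = prod(h(v)) / tau0^k over non-root divergence nodes v)
div_subtree_sizes <- function(net) {
  nd <- net$nodes
  kids <- split(nd$id, factor(ifelse(is.na(nd$parent), 0L, nd$parent),
                              levels = 0:nrow(nd)))
  h <- integer(nrow(nd))
  rec <- function(v) {
    tot <- if (nd$type[v] == "div") 1L else 0L
    for (k in kids[[v + 1L]]) tot <- tot + rec(k)
    h[v] <<- tot
    tot
  }
  rec(net$root)
  h
}

#' Joint prior log-density of a parameter set
#'
#' Gamma log-density for the root age and every theta (and M if present),
#' the uniform-Dirichlet log-density for non-root divergence times given the
#' root age (flat over the feasible order-constrained region, normalized to
#' integrate to 1), an independent uniform density over the feasible window
#' for each shared introgression time, and 0 for each phi inside `[0,1]`
#' (`-Inf` outside, returned rather than raised).
#'
#' @inheritParams validate_params
#' @param priors a [prior_spec()].
#' @return log prior density (possibly `-Inf`).
#' @export
prior_logdensity <- function(params, priors, net) {
  nd <- net$nodes
  if (length(params$phi) && any(params$phi < 0 | params$phi > 1)) return(-Inf)
  tm <- node_times(net, params)
  if (any(tm < 0)) return(-Inf)
  p <- nd$parent
  ok <- is.na(p) | tm[ifelse(is.na(p), 1L, p)] >= tm
  if (!all(ok)) return(-Inf)
  lp <- 0
  div <- which(nd$type == "div")
  if (length(div)) {
    root_div <- nd$id[is.na(nd$parent)]
    if (nd$type[root_div] == "div") {
      lp <- lp + priors$root$logpdf(tm[root_div])
      k <- length(div) - 1L
      if (k > 0) {
        h <- div_subtree_sizes(net)
        nonroot <- setdiff(div, root_div)
        lp <- lp + sum(log(h[nonroot])) - k * log(tm[root_div])
      }
    }
  }
  # shared introgression times: uniform on the feasible window given div times
  if (nrow(net$pairs)) for (j in seq_len(nrow(net$pairs))) {
    win <- pair_window(net, tm, j)
    tj <- tm[net$pairs$a[j]]
    if (!(tj > win[1] && tj < win[2]) || win[2] <= win[1]) return(-Inf)
    lp <- lp - log(win[2] - win[1])
  }
  lp <- lp + sum(priors$theta$logpdf(params$theta))
  if (length(params$M)) lp <- lp + sum(priors$M$logpdf(params$M))
  lp
}

# feasible time window of introgression pair j given current node times:
# (highest non-hybrid node below either attachment, lowest above)
pair_window <- function(net, tm, j) {
  nd <- net$nodes
  lo <- -Inf; hi <- Inf
  for (h in c(net$pairs$a[j], net$pairs$b[j])) {
    bot <- nd$id[which(nd$parent == h)][1]
    while (nd$type[bot] == "hyb") bot <- nd$id[which(nd$parent == bot)][1]
    top <- nd$parent[h]
    while (!is.na(top) && nd$type[top] == "hyb") top <- nd$parent[top]
    lo <- max(lo, tm[bot])
    hi <- min(hi, if (is.na(top)) Inf else tm[top])
  }
  c(lo, hi)
}
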