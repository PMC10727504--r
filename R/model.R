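# Flattened species-model arrays consumed by the C++ kernels, plus the
# gene-tree container shared by the simulator, densities and MCMC.

# Build once per (net, params): cheap enough to rebuild inside MCMC proposals.
spm_build <- function(net, params, skeleton = NULL) {
  nd <- net$nodes
  tm <- node_times(net, params)
  keys <- theta_keys(net)
  theta_above <- unname(params$theta[keys])
  phi <- numeric(nrow(nd))
  hyb <- nd$type == "hyb"
  if (any(hyb)) phi[hyb] <- params$phi[nd$label[hyb]]
  div <- which(nd$type == "div")
  ev_time <- tm[div]; ev_kind <- rep(0L, length(div))
  ev_n1 <- div; ev_n2 <- rep(0L, length(div))
  if (nrow(net$pairs)) {
    ev_time <- c(ev_time, tm[net$pairs$a])
    ev_kind <- c(ev_kind, rep(1L, nrow(net$pairs)))
    ev_n1 <- c(ev_n1, net$pairs$a)
    ev_n2 <- c(ev_n2, net$pairs$b)
  }
  parent0 <- ifelse(is.na(nd$parent), 0L, nd$parent)
  depth <- integer(nrow(nd))
  for (v in seq_len(nrow(nd))) {
    u <- v; d <- 0L
    while (parent0[u] > 0L) { u <- parent0[u]; d <- d + 1L }
    depth[v] <- d
  }
  ev_node_for_depth <- c(div, if (nrow(net$pairs)) net$pairs$a)
  o <- order(ev_time, -depth[ev_node_for_depth])
  list(time = tm,
       parent = ifelse(is.na(nd$parent), 0L, nd$parent),
       donor = nd$donor,
       phi = phi,
       theta_above = theta_above,
       ev_time = ev_time[o], ev_kind = ev_kind[o],
       ev_n1 = as.integer(ev_n1[o]), ev_n2 = as.integer(ev_n2[o]),
       tip_id = stats::setNames(nd$id[nd$type == "tip"],
                                nd$label[nd$type == "tip"]))
}

new_gene_tree <- function(parent, age, pop0, labels, species,
                          crossings = NULL) {
  if (is.null(crossings)) crossings <- matrix(0L, 0, 3)
  structure(list(parent = as.integer(parent), age = as.numeric(age),
                 pop0 = as.integer(pop0), labels = labels, species = species,
                 crossings = crossings),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree:", length(x$labels), "tips, root age",
      signif(max(x$age), 4), "\n")
  cat(" ", gene_tree_newick(x), "\n")
  invisible(x)
}

#' Newick string of a gene tree (with branch lengths)
#'
#' @param tree a `gene_tree`.
#' @return a Newick string.
#' @export
gene_tree_newick <- function(tree) {
  m <- length(tree$parent)
  n <- (m + 1) / 2
  kids <- split(seq_len(m), factor(tree$parent, levels = 0:m))
  root <- which(tree$parent == 0L)
  rec_bl <- function(v) {
    lab <- if (v <= n) tree$labels[v] else ""
    sub <- if (v > n)
      paste0("(", paste(vapply(kids[[v + 1L]], rec_bl, ""), collapse = ","), ")")
    else ""
    bl <- if (tree$parent[v] > 0)
      paste0(":", format(tree$age[tree$parent[v]] - tree$age[v], digits = 8))
    else ""
    paste0(sub, lab, bl)
  }
  paste0(rec_bl(root), ";")
}

# unlabelled rooted topology of a gene tree, canonical form
gene_tree_topology <- function(tree) {
  m <- length(tree$parent)
  n <- (m + 1) / 2
  kids <- split(seq_len(m), factor(tree$parent, levels = 0:m))
  rec <- function(v) {
    if (v <= n) return(tree$labels[v])
    ss <- sort(vapply(kids[[v + 1L]], rec, ""))
    paste0("(", paste(ss, collapse = ","), ")")
  }
  paste0(rec(which(tree$parent == 0L)), ";")
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-locus stream seed from a master seed and a locus index
derive_seed <- function(master, idx) {
  as.integer((as.double(master) * 69069 + idx * 7919) %% 2147483647)
}
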