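#' Species trees and introgression networks
#'
#' A `species_network` is a rooted species tree plus zero or more pairs of
#' bidirectional introgression ("hybridization") edges.  Each pair connects
#' two branches of the tree at one shared event time and carries two directed
#' arrows, one per direction of gene flow.  Internally an introgression pair
#' is stored as two degree-2 attachment nodes, one inserted on each of the two
#' branches; the population above each attachment node is the continuation of
#' the original branch, and under the linked population-size convention it
#' shares that branch's theta.
#'
#' The text form is an extended Newick dialect: each attachment node of pair
#' `k` is written as a degree-2 node whose label ends in `#Hk`, so every
#' bidirectional pair contributes exactly two `#Hk` occurrences, e.g.
#' `"(((A)ha#H1,B),((C)hc#H1,D))r;"` places one pair between the branches
#' above `A` and `C`.  Optional `[&...]` comment blocks after a label (for
#' example `[&phi=0.1]`) are parsed and kept as annotations.  Branch lengths
#' (`:x`) are accepted and ignored: all times live in a [param_set()].
#'
#' @name species_network
NULL

new_species_network <- function(nodes, root, pairs, annotations = list()) {
  structure(list(nodes = nodes, root = root,
                 tips = nodes$label[nodes$type == "tip"],
                 pairs = pairs, annotations = annotations),
            class = "species_network")
}

#' Parse an extended-Newick species network
#'
#' @param text a Newick or extended-Newick string (see [species_network]).
#' @return a validated `species_network` object.
#' @examples
#' net <- parse_network("((A,B)ab,C)r;")
#' net2 <- parse_network("(((A)ha#H1,B)ab,((C)hc#H1,D)cd)r;")
#' @export
parse_network <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s+", "", text)
  if (!nzchar(s)) stop("empty network string")
  if (!grepl(";$", s)) stop("network string must end with ';'")
  s <- sub(";$", "", s)
  n <- nchar(s)
  pos <- 1L
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  # node storage
  labs <- character(); pars <- integer(); nch <- integer(); anns <- list()
  add_node <- function(label, parent) {
    labs[[length(labs) + 1L]] <<- label
    pars[[length(pars) + 1L]] <<- parent
    nch[[length(nch) + 1L]] <<- 0L
    anns[[length(anns) + 1L]] <<- list()
    length(labs)
  }
  read_label <- function() {
    rest <- substr(s, pos, n)
    m <- regmatches(rest, regexpr("^[A-Za-z0-9_.#-]+", rest))
    if (length(m)) { pos <<- pos + nchar(m); m } else ""
  }
  read_decorations <- function(id) {
    lab <- read_label()
    if (nzchar(lab)) labs[id] <<- lab
    if (peek() == "[") {
      close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
      if (close < 0) stop("unterminated comment block at position ", pos)
      com <- substr(s, pos + 1L, pos + close - 2L)
      pos <<- pos + close
      com <- sub("^&", "", com)
      kv <- strsplit(strsplit(com, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      ann <- list()
      for (p in kv) if (length(p) == 2L) {
        v <- suppressWarnings(as.numeric(p[2]))
        ann[[p[1]]] <- if (is.na(v)) p[2] else v
      }
      anns[[id]] <<- ann
    }
    if (peek() == ":") { # branch length: accepted and ignored
      pos <<- pos + 1L
      rest <- substr(s, pos, n)
      m <- regmatches(rest, regexpr("^[0-9.eE+-]+", rest))
      if (!length(m)) stop("malformed branch length at position ", pos)
      pos <<- pos + nchar(m)
    }
    id
  }
  parse_clade <- function(parent) {
    if (peek() == "(") {
      pos <<- pos + 1L
      id <- add_node("", parent)
      repeat {
        child <- parse_clade(id)
        nch[id] <<- nch[id] + 1L
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("parse error at position ", pos, ": expected ',' or ')' near '",
             peek(), "'")
      }
      read_decorations(id)
    } else {
      lab <- read_label()
      if (!nzchar(lab)) stop("parse error at position ", pos,
                             ": expected a taxon label, got '", peek(), "'")
      id <- add_node(lab, parent)
      read_decorations(id)
      labs[id] <<- lab # label already consumed; keep
      id
    }
  }
  root <- parse_clade(0L)
  if (pos <= n) stop("trailing characters after network: '",
                     substr(s, pos, n), "'")
  # classify nodes, resolve #H pairs
  type <- ifelse(nch == 0L, "tip", "div")
  hk <- rep(NA_integer_, length(labs))
  hm <- regmatches(labs, regexec("^(.*)#H([0-9]+)$", labs))
  for (i in seq_along(hm)) if (length(hm[[i]])) {
    hk[i] <- as.integer(hm[[i]][3])
    labs[i] <- hm[[i]][2]
  }
  if (any(!is.na(hk) & nch == 0L))
    stop("a #H hybrid label cannot sit on a tip")
  if (any(is.na(hk) & nch == 1L))
    stop("degree-2 nodes must carry a #H hybrid label")
  pair_ids <- sort(unique(hk[!is.na(hk)]))
  pairs <- data.frame(pair = integer(), a = integer(), b = integer(),
                      label = character(), stringsAsFactors = FALSE)
  donor <- rep(0L, length(labs))
  pair_of <- rep(NA_integer_, length(labs))
  for (j in seq_along(pair_ids)) {
    k <- pair_ids[j]
    ids <- which(!is.na(hk) & hk == k)
    if (length(ids) != 2L)
      stop("hybrid label #H", k, " must occur exactly twice, found ",
           length(ids))
    if (any(nch[ids] != 1L))
      stop("hybrid attachment nodes for #H", k, " must have exactly one child")
    type[ids] <- "hyb"
    donor[ids[1]] <- ids[2]; donor[ids[2]] <- ids[1]
    pair_of[ids] <- j
    if (!nzchar(labs[ids[1]])) labs[ids[1]] <- paste0("h", k, "a")
    if (!nzchar(labs[ids[2]])) labs[ids[2]] <- paste0("h", k, "b")
    pairs <- rbind(pairs, data.frame(pair = j, a = ids[1], b = ids[2],
                                     label = paste0("H", k),
                                     stringsAsFactors = FALSE))
  }
  # auto-label internal divergence nodes (omitted again on write)
  auto <- which(type == "div" & !nzchar(labs))
  if (length(auto)) {
    base <- paste0("n", seq_along(auto))
    clash <- base %in% labs
    base[clash] <- paste0(".", base[clash])
    labs[auto] <- base
  }
  nodes <- data.frame(id = seq_along(labs), label = labs, type = type,
                      parent = ifelse(pars == 0L, NA_integer_, pars),
                      donor = donor, pair = pair_of, stringsAsFactors = FALSE)
  nodes$auto <- seq_along(labs) %in% auto
  net <- new_species_network(nodes, root, pairs, anns)
  err <- validate_structure(net)
  if (length(err)) stop("invalid network: ", paste(err, collapse = "; "))
  net
}

validate_structure <- function(net) {
  nd <- net$nodes
  out <- character()
  tips <- nd$label[nd$type == "tip"]
  if (!length(tips)) out <- c(out, "network has no tips")
  if (anyDuplicated(tips))
    out <- c(out, paste0("duplicate tip labels: ",
                         paste(unique(tips[duplicated(tips)]), collapse = ",")))
  if (anyDuplicated(nd$label))
    out <- c(out, "node labels are not unique")
  if (sum(is.na(nd$parent)) != 1L) out <- c(out, "exactly one root required")
  out
}

#' Write a species network as extended Newick
#'
#' Children are ordered by their smallest descendant tip label, so the output
#' is canonical for a given labelled structure and `parse_network()` of the
#' result reproduces the network.
#'
#' @param net a `species_network`.
#' @return a single extended-Newick string.
#' @export
write_network <- function(net) {
  nd <- net$nodes
  kids <- split(nd$id, factor(ifelse(is.na(nd$parent), 0L, nd$parent),
                              levels = 0:nrow(nd)))
  mintip <- character(nrow(nd))
  rec_min <- function(v) {
    if (nd$type[v] == "tip") mintip[v] <<- nd$label[v]
    else {
      ks <- kids[[v + 1L]]
      for (k in ks) rec_min(k)
      mintip[v] <<- min(mintip[ks])
    }
    invisible()
  }
  rec_min(net$root)
  auto <- if ("auto" %in% names(nd)) nd$auto else rep(FALSE, nrow(nd))
  hlab <- function(v) {
    if (nd$type[v] == "hyb") {
      plab <- net$pairs$label[net$pairs$a == v | net$pairs$b == v][1]
      paste0(nd$label[v], "#", plab)
    } else if (auto[v]) "" else nd$label[v]
  }
  rec <- function(v) {
    if (nd$type[v] == "tip") return(nd$label[v])
    ks <- kids[[v + 1L]]
    ks <- ks[order(mintip[ks])]
    paste0("(", paste(vapply(ks, rec, ""), collapse = ","), ")", hlab(v))
  }
  paste0(rec(net$root), ";")
}

#' Count free parameters of an MSC-I model
#'
#' Counting conventions: each bidirectional introgression pair contributes one
#' shared event time and two introgression probabilities; under the linked
#' population-size convention the populations on either side of a
#' hybridization node share one theta, so attachment nodes add no theta and
#' `n_theta = n_tips + n_divergence_nodes`.  Under `independent` each
#' attachment node starts a new population with its own theta.
#'
#' @param net a `species_network`.
#' @param theta_model `"linked"` (default) or `"independent"`.
#' @return a list with `n_phi`, `n_tau`, `n_theta` and `total`.
#' @examples
#' count_free_parameters(parse_network("(A,B)r;"))      # total 4
#' @export
count_free_parameters <- function(net, theta_model = c("linked", "independent")) {
  theta_model <- match.arg(theta_model)
  n_tips <- sum(net$nodes$type == "tip")
  n_div <- sum(net$nodes$type == "div")
  n_pairs <- nrow(net$pairs)
  n_phi <- 2L * n_pairs
  n_tau <- n_div + n_pairs
  n_theta <- n_tips + n_div + if (theta_model == "independent") 2L * n_pairs else 0L
  list(n_phi = n_phi, n_tau = n_tau, n_theta = n_theta,
       total = n_phi + n_tau + n_theta)
}

#' Construct a parameter set for a species network
#'
#' @param tau named numeric: event times (expected substitutions per site) for
#'   every divergence node label and every introgression pair label (`"H1"`,
#'   ...); one shared time per bidirectional pair.
#' @param theta named numeric: mutation-scaled population sizes `4*N*mu`, one
#'   per tip and divergence node label (the population on the branch above
#'   that node; the root label names the root population).  Linked
#'   convention: attachment-node populations inherit the theta of their
#'   branch.
#' @param phi named numeric: introgression probabilities in `[0,1]`, one per
#'   attachment-node label; `phi[h]` is the probability that a lineage below
#'   `h` traces back through the donor branch (gene flow *into* `h`'s branch).
#' @param M named numeric, entries `"from->to"`: expected migrants per
#'   generation between contemporaneous populations (MSC-M only).
#' @return an object of class `param_set`.
#' @export
param_set <- function(tau, theta, phi = numeric(), M = numeric()) {
  for (v in list(tau, theta, phi, M))
    if (length(v) && is.null(names(v))) stop("param_set components must be named")
  structure(list(tau = tau, theta = theta, phi = phi, M = M),
            class = "param_set")
}

# per-node event times implied by (net, params); tips are at time 0
node_times <- function(net, params) {
  nd <- net$nodes
  tm <- numeric(nrow(nd))
  div <- nd$type == "div"
  tm[div] <- params$tau[nd$label[div]]
  if (nrow(net$pairs)) {
    pt <- params$tau[net$pairs$label]
    tm[net$pairs$a] <- pt
    tm[net$pairs$b] <- pt
  }
  tm
}

# label of the theta population on the branch above node v (root: root label)
theta_keys <- function(net) {
  nd <- net$nodes
  key <- nd$label
  for (i in which(nd$type == "hyb")) {
    v <- i
    while (nd$type[v] == "hyb") v <- nd$id[which(nd$parent == v)][1]
    key[i] <- nd$label[v]
  }
  key
}

#' Validate a parameter set against a network
#'
#' Returns human-readable descriptions of every violated invariant (empty
#' character vector when the parameters are valid): missing entries,
#' non-positive theta, phi outside `[0,1]`, negative migration rates, child
#' nodes older than their parents, and introgression times not strictly
#' between the divergence times of the two branches they connect.
#'
#' @inheritParams write_network
#' @param params a [param_set()].
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_params <- function(net, params) {
  nd <- net$nodes
  out <- character()
  need_tau <- c(nd$label[nd$type == "div"], net$pairs$label)
  miss <- setdiff(need_tau, names(params$tau))
  if (length(miss)) out <- c(out, paste0("missing tau for: ",
                                         paste(miss, collapse = ",")))
  keys <- unique(theta_keys(net))
  misst <- setdiff(keys, names(params$theta))
  if (length(misst)) out <- c(out, paste0("missing theta for: ",
                                          paste(misst, collapse = ",")))
  hlab <- nd$label[nd$type == "hyb"]
  missp <- setdiff(hlab, names(params$phi))
  if (length(missp)) out <- c(out, paste0("missing phi for: ",
                                          paste(missp, collapse = ",")))
  if (length(out)) return(out) # cannot evaluate times with missing entries
  if (any(params$theta[keys] <= 0))
    out <- c(out, paste0("non-positive theta: ",
                         paste(keys[params$theta[keys] <= 0], collapse = ",")))
  bad_phi <- hlab[params$phi[hlab] < 0 | params$phi[hlab] > 1]
  if (length(bad_phi))
    out <- c(out, paste0("phi outside [0,1]: ", paste(bad_phi, collapse = ",")))
  if (length(params$M) && any(params$M < 0))
    out <- c(out, "negative migration rate")
  if (any(params$tau[need_tau] < 0)) out <- c(out, "negative tau")
  tm <- node_times(net, params)
  for (i in which(!is.na(nd$parent))) {
    p <- nd$parent[i]
    if (tm[p] < tm[i])
      out <- c(out, paste0("node '", nd$label[i], "' (", signif(tm[i], 4),
                           ") is older than its parent '", nd$label[p],
                           "' (", signif(tm[p], 4), ")"))
  }
  if (nrow(net$pairs)) for (j in seq_len(nrow(net$pairs))) {
    pr <- net$pairs[j, ]
    for (h in c(pr$a, pr$b)) {
      ch <- nd$id[which(nd$parent == h)][1]
      pa <- nd$parent[h]
      if (!(tm[h] > tm[ch] && tm[h] < tm[pa]))
        out <- c(out, paste0("introgression time of pair ", pr$label,
                             " is not strictly inside branch above '",
                             nd$label[ch], "'"))
    }
  }
  out
}

#' @export
print.species_network <- function(x, ...) {
  cat("species_network:", length(x$tips), "tips,",
      sum(x$nodes$type == "div"), "divergence nodes,",
      nrow(x$pairs), "introgression pair(s)\n")
  cat(" ", write_network(x), "\n")
  invisible(x)
}

# ---- generators used across the package and its tests ----------------------

#' Random species network generator
#'
#' Draws a random rooted binary tree over `n_tips` labelled tips and inserts
#' `n_pairs` bidirectional introgression pairs on random branch pairs with no
#' ancestor--descendant relationship (so a shared event time strictly inside
#' both branches exists for suitable parameters).
#'
#' @param n_tips number of species (>= 2).
#' @param n_pairs number of bidirectional introgression pairs.
#' @param tips optional tip labels (default `s1..sn`).
#' @return a `species_network`.
#' @export
random_network <- function(n_tips, n_pairs = 0L, tips = NULL) {
  stopifnot(n_tips >= 2)
  if (is.null(tips)) tips <- paste0("s", seq_len(n_tips))
  grp <- as.list(tips)
  while (length(grp) > 1L) {
    i <- sample.int(length(grp), 2L)
    merged <- sprintf("(%s,%s)", grp[[i[1]]], grp[[i[2]]])
    grp <- c(grp[-i], merged)
  }
  net <- parse_network(paste0(grp[[1]], ";"))
  k <- 0L; attempt <- 0L
  while (k < n_pairs) {
    attempt <- attempt + 1L
    if (attempt > 500L) stop("could not place ", n_pairs, " pairs on this tree")
    cand <- net$nodes$id[!is.na(net$nodes$parent) & net$nodes$type != "hyb"]
    uv <- sample(cand, 2L)
    if (is_ancestor(net, uv[1], uv[2]) || is_ancestor(net, uv[2], uv[1])) next
    net2 <- insert_pair(net, uv[1], uv[2])
    # keep only placements that admit a valid time assignment
    ok <- tryCatch({ draw_params(net2, tries = 40); TRUE },
                   error = function(e) FALSE)
    if (!ok) next
    net <- net2
    k <- k + 1L
  }
  net
}

is_ancestor <- function(net, a, b) { # is a an ancestor of b (edge above a)?
  v <- b
  while (!is.na(net$nodes$parent[v])) {
    v <- net$nodes$parent[v]
    if (v == a) return(TRUE)
  }
  FALSE
}

# insert a bidirectional pair on the branches above nodes u and v
insert_pair <- function(net, u, v) {
  nd <- net$nodes
  k <- nrow(net$pairs) + 1L
  while (any(nd$label %in% paste0("h", k, c("a", "b"))) ||
         paste0("H", k) %in% net$pairs$label) k <- k + 1L
  ids <- nrow(nd) + 1:2
  nd <- rbind(nd, data.frame(
    id = ids, label = paste0("h", k, c("a", "b")), type = "hyb",
    parent = c(nd$parent[u], nd$parent[v]), donor = c(ids[2], ids[1]),
    pair = nrow(net$pairs) + 1L, auto = FALSE, stringsAsFactors = FALSE))
  nd$parent[u] <- ids[1]; nd$parent[v] <- ids[2]
  pairs <- rbind(net$pairs, data.frame(pair = nrow(net$pairs) + 1L,
                                       a = ids[1], b = ids[2],
                                       label = paste0("H", k),
                                       stringsAsFactors = FALSE))
  new_species_network(nd, net$root, pairs, net$annotations)
}

#' Draw a valid random parameter set for a network
#'
#' Divergence times are assigned top-down from the root age; each pair's
#' shared introgression time is uniform on its feasible window.  Used for
#' property tests and synthetic-data defaults; magnitudes mirror typical
#' butterfly-scale estimates (tau of order 0.01, theta of order 0.01).
#'
#' @inheritParams write_network
#' @param root_age root divergence time (substitutions/site).
#' @param theta_range range for uniform theta draws.
#' @return a [param_set()] that passes [validate_params()].
#' @export
draw_params <- function(net, root_age = 0.02, theta_range = c(0.005, 0.02),
                        tries = 200) {
  nd <- net$nodes
  for (try in seq_len(tries)) {
    tau <- numeric(0)
    tm <- rep(NA_real_, nrow(nd))
    tm[nd$type == "tip"] <- 0
    assign_rec <- function(v, upper) {
      if (nd$type[v] == "tip") return()
      if (nd$type[v] == "div") {
        t <- if (is.na(nd$parent[v])) root_age else stats::runif(1, 0.3, 0.9) * upper
        tm[v] <<- t
        tau[nd$label[v]] <<- t
        for (k in nd$id[which(nd$parent == v)]) assign_rec(k, t)
      } else { # hyb: time set later; pass the upper bound through
        for (k in nd$id[which(nd$parent == v)]) assign_rec(k, upper)
      }
    }
    assign_rec(net$root, root_age)
    ok <- TRUE
    if (nrow(net$pairs)) for (j in seq_len(nrow(net$pairs))) {
      pr <- net$pairs[j, ]
      lo <- hi <- numeric(0)
      for (h in c(pr$a, pr$b)) {
        ch <- nd$id[which(nd$parent == h)][1]
        top <- nd$parent[h]
        while (nd$type[top] == "hyb") top <- nd$parent[top]
        bot <- ch
        while (nd$type[bot] == "hyb") bot <- nd$id[which(nd$parent == bot)][1]
        lo <- c(lo, tm[bot]); hi <- c(hi, tm[top])
      }
      win <- c(max(lo), min(hi))
      if (win[1] >= win[2]) { ok <- FALSE; break }
      t <- stats::runif(1, win[1] + 1e-9, win[2] - 1e-9)
      tau[pr$label] <- t
      tm[c(pr$a, pr$b)] <- t
    }
    if (!ok) next
    keys <- unique(theta_keys(net))
    theta <- stats::setNames(stats::runif(length(keys), theta_range[1],
                                          theta_range[2]), keys)
    hlab <- nd$label[nd$type == "hyb"]
    phi <- stats::setNames(stats::runif(length(hlab), 0.05, 0.95), hlab)
    p <- param_set(tau, theta, phi)
    if (!length(validate_params(net, p))) return(p)
  }
  stop("could not draw valid parameters for this network")
}

# JSON-serializable record of (network, params); inverse of record_to_model()
#' Serialize and restore a (network, parameters) model record
#'
#' @inheritParams validate_params
#' @return `model_record()`: a plain list safe for `jsonlite`;
#'   `record_to_model()`: a list with elements `net` and `params`.
#' @export
model_record <- function(net, params) {
  list(network = write_network(net),
       tau = as.list(params$tau), theta = as.list(params$theta),
       phi = as.list(params$phi), M = as.list(params$M))
}

#' @rdname model_record
#' @param rec a list produced by `model_record()` (possibly via JSON).
#' @export
record_to_model <- function(rec) {
  num <- function(x) stats::setNames(as.numeric(unlist(x)),
                                     names(unlist(x)))
  list(net = parse_network(rec$network),
       params = param_set(num(rec$tau), num(rec$theta),
                          if (length(rec$phi)) num(rec$phi) else numeric(),
                          if (length(rec$M)) num(rec$M) else numeric()))
}
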