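#' Simulate a gene tree under the MSC, MSC-I or MSC-M model
#'
#' Backward-in-time coalescent simulation within a species network.  Within a
#' population of size theta, k lineages coalesce at total rate `k(k-1)/theta`
#' (pairwise rate `2/theta`).  At an introgression (hybridization) node each
#' lineage independently follows the donor branch with probability phi.
#' Under MSC-M (any entry of `params$M` positive) a lineage in population `j`
#' additionally jumps backwards to population `i` at rate `4*M[i->j]/theta_j`
#' whenever both populations exist at the current time.
#'
#' @inheritParams validate_params
#' @param samples_per_species either a single integer (sequences sampled from
#'   every species) or a named integer vector keyed by tip label.
#' @param seed optional integer seed; identical seeds give identical trees.
#' @return a `gene_tree`: rooted binary topology with node ages in expected
#'   substitutions per site, tip-to-species assignments, and the donor /
#'   ancestral path indicator recorded for every hybrid-node crossing.
#' @export
sim_gene_tree <- function(net, params, samples_per_species = 1L, seed = NULL) {
  viol <- validate_params(net, params)
  if (length(viol)) stop("invalid parameters: ", paste(viol, collapse = "; "))
  samp <- expand_samples(net, samples_per_species)
  if (sum(samp) < 2) stop("need at least two sampled sequences")
  with_seed(seed, {
    if (length(params$M) && any(params$M > 0))
      sim_gene_tree_mig(net, params, samp)
    else {
      spm <- spm_build(net, params)
      pop0 <- rep(spm$tip_id[names(samp)], samp)
      raw <- cpp_sim_gene_tree(spm, as.integer(pop0))
      species <- rep(names(samp), samp)
      labels <- make_seq_labels(species)
      new_gene_tree(raw$parent, raw$age, raw$pop0, labels, species,
                    raw$crossings)
    }
  })
}

expand_samples <- function(net, samples_per_species) {
  tips <- net$tips
  if (is.null(names(samples_per_species))) {
    if (length(samples_per_species) != 1L)
      stop("samples_per_species must be a single count or a named vector")
    samp <- stats::setNames(rep(as.integer(samples_per_species),
                                length(tips)), tips)
  } else {
    bad <- setdiff(names(samples_per_species), tips)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ","))
    samp <- stats::setNames(rep(0L, length(tips)), tips)
    samp[names(samples_per_species)] <- as.integer(samples_per_species)
  }
  samp[samp > 0]
}

make_seq_labels <- function(species) {
  idx <- stats::ave(seq_along(species), species, FUN = seq_along)
  paste0(species, "^", idx)
}

# R reference simulator with continuous migration (used when any M > 0)
sim_gene_tree_mig <- function(net, params, samp) {
  nd <- net$nodes
  tm <- node_times(net, params)
  keys <- theta_keys(net)
  theta_above <- unname(params$theta[keys])
  lab_id <- stats::setNames(nd$id, nd$label)
  # parse M entries "from->to" into population node ids (forward direction)
  Mtab <- NULL
  if (length(params$M)) {
    pp <- strsplit(names(params$M), "->", fixed = TRUE)
    Mtab <- data.frame(from = lab_id[vapply(pp, `[`, "", 1)],
                       to = lab_id[vapply(pp, `[`, "", 2)],
                       M = unname(params$M))
    if (any(is.na(Mtab$from)) || any(is.na(Mtab$to)))
      stop("M entries must be named 'from->to' with node labels")
  }
  parent <- ifelse(is.na(nd$parent), 0L, nd$parent)
  exists_at <- function(p, t) { # does population above node p span time t?
    up <- if (parent[p] == 0L) Inf else tm[parent[p]]
    t >= tm[p] && t < up
  }
  spm <- spm_build(net, params)
  n <- sum(samp)
  m <- 2L * n - 1L
  gparent <- integer(m); gage <- numeric(m)
  pop <- integer(m); act <- seq_len(n)
  pop[act] <- rep(spm$tip_id[names(samp)], samp)
  cross <- matrix(0L, 0, 3)
  t <- 0; is <- 1L; nxt <- n + 1L
  ns <- length(spm$ev_time)
  while (length(act) > 1L || is <= ns) {
    cnt <- table(pop[act])
    pops <- as.integer(names(cnt))
    crate <- as.numeric(cnt) * (as.numeric(cnt) - 1) / theta_above[pops]
    # migration: lineage in pop j -> pop i at rate 4*M(i->j)/theta_j
    mig <- NULL
    if (!is.null(Mtab)) {
      for (r in seq_len(nrow(Mtab))) {
        j <- Mtab$to[r]; i <- Mtab$from[r]
        if (Mtab$M[r] > 0 && exists_at(i, t)) {
          here <- act[pop[act] == j]
          if (length(here))
            mig <- rbind(mig, cbind(lin = here, dest = i,
                                    rate = 4 * Mtab$M[r] / theta_above[j]))
        }
      }
    }
    R <- sum(crate) + if (is.null(mig)) 0 else sum(mig[, "rate"])
    ts <- if (is <= ns) spm$ev_time[is] else Inf
    tev <- if (R > 0) t + stats::rexp(1, R) else Inf
    if (tev < ts) {
      t <- tev
      u <- stats::runif(1) * R
      if (u <= sum(crate)) {
        p <- pops[min(findInterval(u, cumsum(crate), left.open = TRUE) + 1L,
                      length(pops))]
        pick <- sample(act[pop[act] == p], 2L)
        gparent[pick] <- nxt; gage[nxt] <- t; pop[nxt] <- p
        act <- c(setdiff(act, pick), nxt); nxt <- nxt + 1L
      } else {
        u <- u - sum(crate)
        r <- findInterval(u, cumsum(mig[, "rate"]), left.open = TRUE) + 1L
        pop[mig[r, "lin"]] <- mig[r, "dest"]
      }
    } else {
      if (!is.finite(ts)) break
      t <- ts
      if (spm$ev_kind[is] == 0L) {
        d <- spm$ev_n1[is]
        sel <- act[parent[pop[act]] == d]
        pop[sel] <- d
      } else {
        hs <- c(spm$ev_n1[is], spm$ev_n2[is])
        for (v in act) {
          h <- hs[match(parent[pop[v]], hs)]
          if (!is.na(h)) {
            flag <- stats::runif(1) < spm$phi[h]
            cross <- rbind(cross, c(v, h, as.integer(flag)))
            pop[v] <- if (flag) nd$donor[h] else h
          }
        }
      }
      is <- is + 1L
    }
  }
  species <- rep(names(samp), samp)
  new_gene_tree(gparent, gage, pop[seq_len(n)], make_seq_labels(species),
                species, cross)
}

#' Simulate a JC69 alignment along a gene tree
#'
#' Sites are i.i.d.; the root state is uniform on A,C,G,T and along a branch
#' of length `t` a site stays with probability `1/4 + (3/4) exp(-4t/3)`,
#' otherwise changes to one of the three other bases uniformly.
#'
#' @param tree a `gene_tree`.
#' @param n_sites number of sites (>= 1).
#' @param seed optional integer seed.
#' @return a `locus_alignment` with one sequence per gene-tree tip.
#' @export
sim_alignment_jc69 <- function(tree, n_sites, seed = NULL) {
  stopifnot(n_sites >= 1)
  m <- length(tree$parent)
  n <- (m + 1L) / 2L
  root <- which(tree$parent == 0L)
  bl <- ifelse(tree$parent > 0, tree$age[pmax(tree$parent, 1L)] - tree$age, 0)
  if (any(bl < 0)) stop("negative branch length")
  with_seed(seed, {
    states <- matrix(0L, m, n_sites)
    states[root, ] <- sample.int(4L, n_sites, replace = TRUE)
    kids <- split(seq_len(m), factor(tree$parent, levels = 0:m))
    evolve <- function(v) {
      for (k in kids[[v + 1L]]) {
        e <- exp(-4 * bl[k] / 3)
        chg <- stats::runif(n_sites) > 0.25 + 0.75 * e
        s <- states[v, ]
        if (any(chg)) {
          shift <- sample.int(3L, sum(chg), replace = TRUE)
          s[chg] <- ((s[chg] - 1L + shift) %% 4L) + 1L
        }
        states[k, ] <<- s
        if (k > n) evolve(k)
      }
    }
    evolve(root)
    bases <- c("A", "C", "G", "T")
    seqs <- apply(states[seq_len(n), , drop = FALSE], 1L,
                  function(s) paste(bases[s], collapse = ""))
    new_locus_alignment(stats::setNames(seqs, tree$labels),
                        stats::setNames(tree$species, tree$labels))
  })
}

#' Collapse two haplotypes into an unphased diploid IUPAC sequence
#'
#' Homozygous sites keep the base; heterozygous sites get the two-base IUPAC
#' ambiguity code (for example A/G -> R).
#'
#' @param hapA,hapB equal-length nucleotide strings.
#' @return a single IUPAC-coded string.
#' @export
sim_diploid_collapse <- function(hapA, hapB) {
  if (nchar(hapA) != nchar(hapB)) stop("haplotype length mismatch")
  a <- strsplit(toupper(hapA), "")[[1]]
  b <- strsplit(toupper(hapB), "")[[1]]
  key <- ifelse(a <= b, paste0(a, b), paste0(b, a))
  code <- iupac_pair_codes()
  out <- unname(code[key])
  if (anyNA(out)) stop("non-ACGT base in haplotypes")
  paste(out, collapse = "")
}

iupac_pair_codes <- function() {
  c(AA = "A", CC = "C", GG = "G", TT = "T",
    AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
}

#' Construct a locus alignment
#'
#' @param seqs named character vector of equal-length sequences (IUPAC
#'   codes allowed).
#' @param species named character vector mapping sequence labels to species
#'   (default: the part of each label before `^`).
#' @param spec optional locus metadata (e.g. a [plan_loci()] row).
#' @return a `locus_alignment`.
#' @export
locus_alignment <- function(seqs, species = NULL, spec = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length")
  if (is.null(species))
    species <- stats::setNames(sub("\\^.*$", "", names(seqs)), names(seqs))
  new_locus_alignment(seqs, species, spec)
}

new_locus_alignment <- function(seqs, species, spec = NULL) {
  structure(list(seqs = seqs, species = species, spec = spec,
                 n_sites = if (length(seqs)) nchar(seqs[[1]]) else 0L),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment:", length(x$seqs), "sequences x", x$n_sites, "sites\n")
  invisible(x)
}

#' Simulate a blockwise multilocus dataset with its truth record
#'
#' Emulates the structure of a blockwise multilocus study: blocks of
#' well-spaced, freely recombining loci, each a short alignment simulated
#' under the MSC / MSC-I / MSC-M model.  Locus lengths are drawn uniformly
#' from `sites_per_locus` when a range is given.  With `diploid = TRUE` two
#' haplotypes per individual are simulated and collapsed into one unphased
#' IUPAC-coded sequence.  Per-locus RNG streams are derived from
#' `(seed, locus index)` so the dataset is reproducible.
#'
#' @inheritParams sim_gene_tree
#' @param n_blocks,loci_per_block block structure (defaults mirror 200-locus
#'   blocks).
#' @param sites_per_locus single length or range `c(min, max)`.
#' @param diploid collapse haplotype pairs into unphased diploid sequences.
#' @param out_dir optional directory: per-locus FASTA files, a tab-separated
#'   locus index and a JSON truth file are written there.
#' @return invisibly, a list with `loci` (list of `locus_alignment`), `index`
#'   (data frame), and `truth` (model record plus per-locus gene trees).
#' @export
sim_block_dataset <- function(net, params, n_blocks = 1L,
                              loci_per_block = 200L,
                              sites_per_locus = c(100L, 1000L),
                              samples_per_species = 1L, diploid = FALSE,
                              seed = NULL, out_dir = NULL) {
  n_loci <- n_blocks * loci_per_block
  samp <- expand_samples(net, samples_per_species)
  sim_samp <- if (diploid) samp * 2L else samp
  master <- if (is.null(seed)) sample.int(2^30, 1L) else as.integer(seed)
  loci <- vector("list", n_loci)
  trees <- character(n_loci)
  index <- data.frame(block = rep(seq_len(n_blocks), each = loci_per_block),
                      locus = seq_len(n_loci), n_seqs = 0L, n_sites = 0L)
  for (i in seq_len(n_loci)) {
    si <- derive_seed(master, i)
    res <- with_seed(si, {
      L <- if (length(sites_per_locus) == 2L)
        sample(seq(sites_per_locus[1], sites_per_locus[2]), 1L)
      else as.integer(sites_per_locus)
      tr <- sim_gene_tree(net, params, sim_samp)
      aln <- sim_alignment_jc69(tr, L)
      if (diploid) aln <- collapse_alignment_diploid(aln)
      list(aln = aln, newick = gene_tree_newick(tr))
    })
    loci[[i]] <- res$aln
    trees[i] <- res$newick
    index$n_seqs[i] <- length(loci[[i]]$seqs)
    index$n_sites[i] <- loci[[i]]$n_sites
  }
  truth <- c(model_record(net, params),
             list(seed = master, gene_trees = trees))
  out <- list(loci = loci, index = index, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_loci)) {
      f <- file.path(out_dir, sprintf("block%03d_locus%05d.fa",
                                      index$block[i], i))
      write_locus_fasta(loci[[i]], f)
      index$file[i] <- basename(f)
    }
    utils::write.table(index, file.path(out_dir, "loci_index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$index <- index
  }
  invisible(out)
}

# pair consecutive haplotypes of each individual into IUPAC diploids
collapse_alignment_diploid <- function(aln) {
  sp <- aln$species
  seqs <- character(0); species <- character(0)
  for (s in unique(sp)) {
    idx <- which(sp == s)
    for (k in seq_len(length(idx) %/% 2)) {
      d <- sim_diploid_collapse(aln$seqs[idx[2 * k - 1]],
                                aln$seqs[idx[2 * k]])
      lab <- paste0(s, "^", k)
      seqs[lab] <- d; species[lab] <- s
    }
  }
  new_locus_alignment(seqs, species, aln$spec)
}

#' Write / read a locus alignment as FASTA
#'
#' @param aln a `locus_alignment`.
#' @param path file path.
#' @export
write_locus_fasta <- function(aln, path) {
  seqinr::write.fasta(as.list(aln$seqs), names(aln$seqs), path)
  invisible(path)
}

#' @rdname write_locus_fasta
#' @param species_of optional function mapping a sequence label to its
#'   species (default: part of the label before `^`).
#' @export
read_locus_fasta <- function(path, species_of = NULL) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  seqs <- toupper(vapply(fa, function(x) as.character(x)[1], ""))
  names(seqs) <- names(fa)
  if (is.null(species_of)) species_of <- function(l) sub("\\^.*$", "", l)
  sp <- vapply(names(seqs), species_of, "")
  new_locus_alignment(seqs, sp)
}
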