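# Brute-force pruning oracle: sum over all internal-state assignments
brute_force_loglik <- function(tree, aln) {
  m <- length(tree$parent)
  n <- (m + 1L) / 2L
  codes <- mscflow:::iupac_partials()
  chars <- do.call(rbind, strsplit(toupper(aln$seqs[tree$labels]), ""))
  P <- ncol(chars)
  bl <- ifelse(tree$parent > 0, tree$age[pmax(tree$parent, 1L)] - tree$age, 0)
  Pm <- lapply(bl, jc69_transition)
  root <- which(tree$parent == 0L)
  internals <- setdiff(seq_len(m), seq_len(n))
  ll <- 0
  for (p in seq_len(P)) {
    tot <- 0
    grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
    for (g in seq_len(nrow(grid))) {
      st <- integer(m)
      st[internals] <- grid[g, ]
      pr <- 1 / 4 # root state probability (root is an internal node)
      for (v in seq_len(m)) {
        if (v == root) next
        pa <- tree$parent[v]
        if (v <= n) {
          pr <- pr * sum(Pm[[v]][st[pa], ] * codes[, chars[v, p]])
        } else {
          pr <- pr * Pm[[v]][st[pa], st[v]]
        }
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}


# Independent matrix-route site-pattern class probabilities for a 3-taxon
# genealogy ((x,y):u, z):v (no closed forms; explicit transition matrices)
matrix_class_probs <- function(u, v, pair) {
  Pm <- function(t) {
    e <- exp(-4 * t / 3)
    m <- matrix((1 - e) / 4, 4, 4); diag(m) <- (1 + 3 * e) / 4
    m
  }
  P1 <- Pm(u); Pi <- Pm(v - u); Pz <- Pm(v)
  W <- 0.25 * t(Pi) %*% Pz          # W[m, z] = sum_r pi_r Pi[r,m] Pz[r,z]
  p5 <- numeric(5)
  for (x in 1:4) for (y in 1:4) for (z in 1:4) {
    pr <- sum(W[, z] * P1[, x] * P1[, y])
    s <- integer(3)
    s[pair] <- c(x, y); s[setdiff(1:3, pair)] <- z
    cls <- if (s[1] == s[2] && s[2] == s[3]) 1
           else if (s[1] == s[2]) 2 else if (s[1] == s[3]) 3
           else if (s[2] == s[3]) 4 else 5
    p5[cls] <- p5[cls] + pr
  }
  p5
}

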