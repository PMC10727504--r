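# Shared fixtures: small species trees / networks with valid parameters,
# quick simulated multilocus datasets, and a toy VCF generator that carries
# its own independently computed filtering truth.

three_tip_tree <- function() parse_network("((A,B)ab,C)r;")

three_tip_params <- function(tau_ab = 0.01, tau_r = 0.02, theta = 0.01) {
  param_set(c(r = tau_r, ab = tau_ab),
            stats::setNames(rep(theta, 5), c("A", "B", "C", "ab", "r")))
}

four_tip_tree <- function() parse_network("(((A,B)ab,C)abc,D)r;")

four_tip_params <- function(theta = 0.005) {
  param_set(c(r = 0.025, abc = 0.015, ab = 0.008),
            stats::setNames(rep(theta, 7),
                            c("A", "B", "C", "D", "ab", "abc", "r")))
}

# 5 taxa, one bidirectional introgression pair between the B and C branches
phi_net <- function() parse_network("(((A,(B)hb#H1)ab,((C)hc#H1,D)cd)m,E)r;")

phi_params <- function(phi_b = 0.75, phi_c = 0.05) {
  param_set(c(r = 0.025, m = 0.018, ab = 0.012, cd = 0.012, H1 = 0.006),
            stats::setNames(rep(0.01, 9),
                            c("A", "B", "C", "D", "E", "ab", "cd", "m", "r")),
            c(hb = phi_b, hc = phi_c))
}

sim_loci <- function(net, params, n_loci, n_sites, samples = 1L) {
  replicate(n_loci, {
    tr <- sim_gene_tree(net, params, samples)
    sim_alignment_jc69(tr, n_sites)
  }, simplify = FALSE)
}

triplet_net <- function() parse_network("((S1,S2)anc,S3)r;")

triplet_params <- function(tau1 = 0.005, tau0 = 0.01, theta = 0.01,
                           M12 = 0, M21 = 0) {
  M <- if (M12 > 0 || M21 > 0)
    stats::setNames(c(M12, M21), c("S1->S2", "S2->S1")) else numeric()
  param_set(stats::setNames(c(tau0, tau1), c("r", "anc")),
            stats::setNames(c(theta, theta, 1e-6, theta, theta),
                            c("S1", "S2", "S3", "anc", "r")), M = M)
}

# ---- toy VCF fixture with independent filtering truth ----------------------
#
# Builds a single-chromosome all-sites VCF for two samples.  Per locus the
# generator engineers QUAL/GQ/DP patterns and indels, and computes the
# expected per-individual-mode outcome (kept sites after column removal, or
# a rejection reason) by direct application of the filtering rules -- an
# implementation independent of the package's build_locus_alignment().
toy_vcf_fixture <- function(dir = tempfile("vcf"), n_loci = 20, locus_len = 40,
                            mean_dp = 30, d = 10, seed = 77) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(seed)
  samples <- c("s1", "s2")
  rows <- character()
  expected <- vector("list", n_loci)
  loci <- data.frame(chrom = "chr1",
                     start = (seq_len(n_loci) - 1L) * locus_len,
                     end = seq_len(n_loci) * locus_len)
  ref_chars <- sample(c("A", "C", "G", "T"), n_loci * locus_len, TRUE)
  kind_all <- character(0)
  for (l in seq_len(n_loci)) {
    pos0 <- loci$start[l]:(loci$end[l] - 1L)
    # engineered per-site state: mostly good, some bad-GQ / bad-DP / indel
    kind <- sample(c("good", "badgq", "baddp", "indel", "lowqual"),
                   locus_len, TRUE,
                   prob = c(0.62 + 0.3 * (l / n_loci), 0.12, 0.12,
                            0.04, 0.10) /
                     sum(c(0.62 + 0.3 * (l / n_loci), 0.12, 0.12, 0.04, 0.10)))
    gq <- ifelse(kind == "badgq", 5, 60)
    dp <- ifelse(kind == "baddp", 2 * mean_dp + 10, mean_dp)
    qual <- ifelse(kind == "lowqual", 10, 60)
    het <- stats::runif(locus_len) < 0.1
    for (k in seq_len(locus_len)) {
      refb <- ref_chars[pos0[k] + 1L]
      if (kind[k] == "indel") {
        rows <- c(rows, paste(c("chr1", pos0[k] + 1L, ".", paste0(refb, "A"),
                                refb, 60, ".", "DP=60", "GT:DP:GQ",
                                "0/0:30:60", "0/0:30:60"), collapse = "\t"))
      } else {
        alt <- if (het[k]) setdiff(c("A", "C", "G", "T"), refb)[1] else "."
        gt <- if (het[k]) "0/1" else "0/0"
        rows <- c(rows, paste(c("chr1", pos0[k] + 1L, ".", refb, alt,
                                qual[k], ".", "DP=60;QD=10;MQ=50", "GT:DP:GQ",
                                paste(gt, dp[k], gq[k], sep = ":"),
                                paste("0/0", dp[k], gq[k], sep = ":")),
                              collapse = "\t"))
      }
    }
    kind_all <- c(kind_all, kind)
  }
  # independent truth, second pass: indel masking is genome-wide, so
  # neighbouring loci can mask sites near a locus boundary
  indels_all <- which(kind_all == "indel") - 1L
  for (l in seq_len(n_loci)) {
    pos0 <- loci$start[l]:(loci$end[l] - 1L)
    kind <- kind_all[pos0 + 1L]
    gq <- ifelse(kind == "badgq", 5, 60)
    dp <- ifelse(kind == "baddp", 2 * mean_dp + 10, mean_dp)
    qual <- ifelse(kind == "lowqual", 10, 60)
    near <- vapply(pos0, function(p)
      length(indels_all) > 0 && min(abs(p - indels_all)) <= 5, TRUE)
    keep_call <- qual >= 20 & gq >= 20 &
      dp >= pmax(mean_dp / 2, d) & dp <= 2 * mean_dp
    col_ok <- keep_call & !near & kind != "indel"
    miss_frac <- mean(!col_ok) # both samples share the engineered pattern
    expected[[l]] <-
      if (miss_frac > 0.5) list(kept = FALSE, reason = "missing")
      else if (sum(col_ok) < 11) list(kept = FALSE, reason = "sites")
      else list(kept = TRUE, n_sites = sum(col_ok))
  }
  header <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  vcf_path <- file.path(dir, "toy.vcf")
  writeLines(c(header, rows), vcf_path)
  list(vcf = vcf_path,
       reference = c(chr1 = paste(ref_chars, collapse = "")),
       loci = loci, expected = expected, mean_dp = mean_dp, d = d)
}

# minimal two-sequence gene tree at pairwise divergence d
new_gene_tree_for_test <- function(d) {
  mscflow:::new_gene_tree(c(3L, 3L, 0L), c(0, 0, d / 2), c(1L, 1L),
                          c("x^1", "x^2"), c("x", "x"))
}
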