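test_that("two-lineage coalescent ages have the right law", {
  one <- parse_network("A;")
  p <- param_set(numeric(), c(A = 0.01))
  set.seed(1)
  ages <- replicate(4000, max(sim_gene_tree(one, p, 2L)$age))
  # mean theta/2 within 3 MC standard errors (sd of Exp(2/theta) = theta/2)
  expect_lt(abs(mean(ages) - 0.005), 3 * 0.005 / sqrt(4000))
  # KS against the closed-form exponential density
  ks <- suppressWarnings(stats::ks.test(ages, stats::pexp, rate = 2 / 0.01))
  expect_gt(ks$p.value, 0.001)
})

test_that("identical seeds reproduce identical trees and alignments", {
  net <- three_tip_tree()
  p <- three_tip_params()
  expect_identical(sim_gene_tree(net, p, 2L, seed = 5),
                   sim_gene_tree(net, p, 2L, seed = 5))
  tr <- sim_gene_tree(net, p, 1L, seed = 5)
  expect_identical(sim_alignment_jc69(tr, 50, seed = 6),
                   sim_alignment_jc69(tr, 50, seed = 6))
})

test_that("a probability-one introgression arrow reroutes every lineage", {
  net <- phi_net()
  p <- phi_params(phi_b = 1, phi_c = 0)
  set.seed(2)
  for (i in 1:20) {
    tr <- sim_gene_tree(net, p, 1L)
    cr <- tr$crossings
    hb <- net$nodes$id[net$nodes$label == "hb"]
    expect_true(all(cr[cr[, 2] == hb, 3] == 1L))
    hc <- net$nodes$id[net$nodes$label == "hc"]
    expect_true(all(cr[cr[, 2] == hc, 3] == 0L))
  }
})

test_that("a star tree gives exchangeable triplet topologies", {
  net <- three_tip_tree()
  p <- three_tip_params(tau_ab = 0.01, tau_r = 0.01) # zero internal branch
  set.seed(3)
  topo <- replicate(3000, {
    tr <- sim_gene_tree(net, p, 1L)
    first <- which.min(tr$age[4:5]) + 3L
    paste(sort(tr$species[which(tr$parent == first & seq_len(5) <= 3)]),
          collapse = "")
  })
  cnt <- table(topo)
  expect_equal(length(cnt), 3L)
  expect_gt(stats::chisq.test(cnt)$p.value, 0.001)
})

test_that("gene-tree discordance follows the coalescent prediction", {
  # asymmetric 3-species tree: discordant topologies each at exp(-2 dt/th)/3
  dt <- 0.005; th <- 0.01
  net <- three_tip_tree()
  p <- three_tip_params(tau_ab = 0.01, tau_r = 0.01 + dt, theta = th)
  set.seed(4)
  n <- 4000
  topo <- replicate(n, {
    tr <- sim_gene_tree(net, p, 1L)
    first <- which.min(tr$age[4:5]) + 3L
    paste(sort(tr$species[which(tr$parent == first & seq_len(5) <= 3)]),
          collapse = "")
  })
  p_disc <- exp(-2 * dt / th) / 3
  for (d in c("AC", "BC")) {
    ph <- mean(topo == d)
    expect_lt(abs(ph - p_disc), 3 * sqrt(p_disc * (1 - p_disc) / n))
  }
})

test_that("JC69 alignments match the expected p-distance", {
  two <- new_gene_tree_for_test(d = 0.1)
  aln <- sim_alignment_jc69(two, 50000, seed = 9)
  pd <- mean(strsplit(aln$seqs[1], "")[[1]] != strsplit(aln$seqs[2], "")[[1]])
  exp_pd <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(pd - exp_pd), 3 * sqrt(exp_pd * (1 - exp_pd) / 50000))
  # saturation
  sat <- sim_alignment_jc69(new_gene_tree_for_test(d = 10), 20000, seed = 10)
  ps <- mean(strsplit(sat$seqs[1], "")[[1]] != strsplit(sat$seqs[2], "")[[1]])
  expect_lt(abs(ps - 0.75), 0.02)
  # zero branch lengths: identical sequences
  z <- sim_alignment_jc69(new_gene_tree_for_test(d = 0), 100, seed = 11)
  expect_identical(z$seqs[[1]], z$seqs[[2]])
  expect_error(sim_alignment_jc69(new_gene_tree_for_test(d = -0.1), 10),
               "negative")
})

test_that("diploid collapse uses IUPAC codes and keeps both alleles", {
  expect_identical(sim_diploid_collapse("ACGT", "ACGT"), "ACGT")
  expect_identical(sim_diploid_collapse("A", "G"), "R")
  expect_error(sim_diploid_collapse("AC", "A"), "mismatch")
  codes <- c(A = "A", C = "C", G = "G", T = "T")
  decode <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))
  for (a in names(codes)) for (b in names(codes)) {
    out <- sim_diploid_collapse(a, b)
    expect_true(all(c(a, b) %in% decode[[out]]))
  }
})

test_that("MSC-I with phi = 0 and MSC-M with M = 0 reduce to the MSC", {
  # compare ingroup-pair concordance frequencies across the three models
  net0 <- three_tip_tree()
  p0 <- three_tip_params(tau_ab = 0.008, tau_r = 0.014)
  topo_of <- function(tr) {
    first <- which.min(tr$age[4:5]) + 3L
    paste(sort(tr$species[which(tr$parent == first & seq_len(5) <= 3)]),
          collapse = "")
  }
  n <- 2500
  set.seed(6)
  f_msc <- mean(replicate(n, topo_of(sim_gene_tree(net0, p0, 1L))) == "AB")
  pm <- p0
  pm$M <- c("A->B" = 0, "B->A" = 0)
  f_m0 <- mean(replicate(n, topo_of(sim_gene_tree(net0, pm, 1L))) == "AB")
  neti <- parse_network("(((A)ha#H1,(B)hb#H1)ab,C)r;")
  pi0 <- param_set(c(r = 0.014, ab = 0.008, H1 = 0.004),
                   stats::setNames(rep(0.01, 5), c("A", "B", "C", "ab", "r")),
                   c(ha = 0, hb = 0))
  f_i0 <- mean(replicate(n, topo_of(sim_gene_tree(neti, pi0, 1L))) == "AB")
  se <- sqrt(0.25 / n)
  expect_lt(abs(f_msc - f_m0), 4 * se)
  expect_lt(abs(f_msc - f_i0), 4 * se)
})

test_that("block datasets are reproducible and correctly indexed", {
  net <- three_tip_tree()
  p <- three_tip_params()
  out <- tempfile("blocks")
  d1 <- sim_block_dataset(net, p, n_blocks = 2, loci_per_block = 15,
                          sites_per_locus = c(100, 1000),
                          samples_per_species = 1, seed = 123,
                          out_dir = out)
  expect_equal(nrow(d1$index), 30L)
  expect_length(list.files(out, pattern = "\\.fa$"), 30L)
  expect_true(file.exists(file.path(out, "loci_index.tsv")))
  expect_true(file.exists(file.path(out, "truth.json")))
  d2 <- sim_block_dataset(net, p, n_blocks = 2, loci_per_block = 15,
                          sites_per_locus = c(100, 1000),
                          samples_per_species = 1, seed = 123)
  expect_identical(lapply(d1$loci, `[[`, "seqs"),
                   lapply(d2$loci, `[[`, "seqs"))
  lens <- d1$index$n_sites
  expect_true(stats::median(lens) >= 100 && stats::median(lens) <= 1000)
  # truth file reloads into a valid model
  rec <- jsonlite::read_json(file.path(out, "truth.json"))
  mod <- record_to_model(rec)
  expect_length(validate_params(mod$net, mod$params), 0L)
  # diploid collapse halves the sequence count
  dd <- sim_block_dataset(net, p, n_blocks = 1, loci_per_block = 3,
                          sites_per_locus = 100, samples_per_species = 1,
                          diploid = TRUE, seed = 5)
  expect_equal(unique(dd$index$n_seqs), 3L) # 2 haplotypes -> 1 per species
})

test_that("FASTA roundtrip preserves alignments", {
  net <- three_tip_tree()
  tr <- sim_gene_tree(net, three_tip_params(), 2L, seed = 1)
  aln <- sim_alignment_jc69(tr, 120, seed = 2)
  f <- tempfile(fileext = ".fa")
  write_locus_fasta(aln, f)
  back <- read_locus_fasta(f)
  expect_identical(unname(back$seqs), unname(aln$seqs))
  expect_identical(unname(back$species), unname(aln$species))
})
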