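# independent brute-force locus planner used as an oracle: scans positions
# directly instead of doing interval arithmetic
brute_force_plan <- function(cds, reps, len, cfg) {
  occ_cds <- rep(FALSE, len); occ_rep <- rep(FALSE, len)
  for (i in seq_len(nrow(cds)))
    occ_cds[(cds$start[i] + 1):cds$end[i]] <- TRUE
  if (nrow(reps)) for (i in seq_len(nrow(reps)))
    occ_rep[(reps$start[i] + 1):reps$end[i]] <- TRUE
  runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  coding <- runs(occ_cds & !occ_rep)
  coding <- coding[coding[, 2] - coding[, 1] + 1L >= cfg$min_coding, ,
                   drop = FALSE]
  nc <- runs(!occ_cds & !occ_rep)
  nc_pieces <- NULL
  for (i in seq_len(nrow(nc))) {
    s <- nc[i, 1]
    while (nc[i, 2] - s + 1L >= cfg$noncoding_range[1]) {
      e <- min(nc[i, 2], s + cfg$noncoding_range[2] - 1L)
      nc_pieces <- rbind(nc_pieces, c(s, e))
      s <- e + 1L
    }
  }
  space <- function(m) {
    if (is.null(m) || !nrow(m)) return(m)
    m <- m[order(m[, 1]), , drop = FALSE]
    keep <- logical(nrow(m)); last <- -Inf
    for (i in seq_len(nrow(m))) {
      if (m[i, 1] - 1L - last >= cfg$spacing) { keep[i] <- TRUE
        last <- m[i, 2] }
    }
    m[keep, , drop = FALSE]
  }
  list(coding = space(coding), noncoding = space(nc_pieces))
}

test_that("locus planning enforces the length and spacing rules", {
  # a 90-bp CDS yields no coding locus
  p1 <- plan_loci(data.frame(chrom = "c", start = 100L, end = 190L),
                  data.frame(chrom = character(), start = integer(),
                             end = integer()),
                  NULL, c(c = 10000L))
  expect_false(any(p1$class == "coding"))
  # two 500-bp CDS 1 kb apart: spacing keeps only the first
  p2 <- plan_loci(data.frame(chrom = "c", start = c(1000L, 2500L),
                             end = c(1500L, 3000L)),
                  data.frame(chrom = character(), start = integer(),
                             end = integer()),
                  NULL, c(c = 4000L))
  expect_equal(sum(p2$class == "coding"), 1L)
  expect_equal(p2$start[p2$class == "coding"], 1000L)
  # intervals beyond the chromosome or unsorted input are errors
  expect_error(plan_loci(data.frame(chrom = "c", start = 1L, end = 99999L),
                         p2[0, 1:3], NULL, c(c = 4000L)), "beyond")
  expect_error(plan_loci(data.frame(chrom = "c", start = c(50L, 10L),
                                    end = c(60L, 20L)),
                         p2[0, 1:3], NULL, c(c = 4000L)), "sorted")
})

test_that("locus planning agrees with a brute-force position scan", {
  set.seed(19)
  for (rep in 1:5) {
    len <- 50000L
    starts <- sort(sample.int(len - 600L, 25L))
    cds <- data.frame(chrom = "c", start = starts,
                      end = pmin(starts + sample(50:600, 25, TRUE), len))
    cds <- cds[!duplicated(cds$start), ]
    # drop overlapping CDS to keep the fixture simple and sorted
    keep <- c(TRUE, diff(cds$start) > 700)
    cds <- cds[keep, ]
    rst <- sort(sample.int(len - 2000L, 5L))
    reps <- data.frame(chrom = "c", start = rst, end = rst + 1500L)
    reps <- reps[c(TRUE, diff(rst) > 1600), ]
    cfg <- loci_config()
    plan <- plan_loci(cds, reps, NULL, c(c = len), cfg)
    bf <- brute_force_plan(cds, reps, len, cfg)
    got_cod <- plan[plan$class == "coding", ]
    expect_equal(nrow(got_cod), nrow(bf$coding))
    if (nrow(got_cod))
      expect_equal(got_cod$start, bf$coding[, 1] - 1L)
    got_nc <- plan[plan$class == "noncoding", ]
    expect_equal(nrow(got_nc), nrow(bf$noncoding))
  }
})

test_that("genotype filtering follows the depth and quality rules", {
  expect_true(genotype_keep(30, 30, 30, mean_dp = 30))
  expect_false(genotype_keep(30, 30, 61, mean_dp = 30))   # above 2*meanDP
  expect_false(genotype_keep(30, 30, 18, mean_dp = 30, d = 20)) # max(15,20)
  expect_true(genotype_keep(30, 30, 18, mean_dp = 30, d = 20, female_z = TRUE))
  expect_false(genotype_keep(10, 30, 30, mean_dp = 30))   # low site QUAL
  expect_false(genotype_keep(30, 10, 30, mean_dp = 30))   # low GQ
  expect_error(genotype_keep(30, 30, 30, mean_dp = 0), "positive")
})

test_that("indel masking matches a brute-force distance scan", {
  expect_equal(mask_near_indels(90:110, 100L), 95:105)
  expect_length(mask_near_indels(1:50, integer()), 0L)
  set.seed(4)
  sites <- sort(sample.int(5000L, 800L))
  indels <- sort(sample.int(5000L, 20L))
  bf <- sites[vapply(sites, function(s) min(abs(s - indels)) <= 5, TRUE)]
  expect_equal(mask_near_indels(sites, indels), bf)
})

test_that("toy-VCF survival matches the fixture's independent computation", {
  fx <- toy_vcf_fixture()
  g <- read_genotypes(fx$vcf)
  cfg <- loci_config(d = fx$d)
  md <- stats::setNames(rep(fx$mean_dp, 2), c("s1", "s2"))
  res <- extract_loci(g, fx$reference, fx$loci, "per_individual", cfg,
                      mean_dp = md)
  exp_kept <- vapply(fx$expected, `[[`, TRUE, "kept")
  expect_equal(length(res$loci), sum(exp_kept))
  got_sites <- res$index$n_sites
  expect_equal(got_sites,
               vapply(fx$expected[exp_kept], `[[`, 0, "n_sites"))
  expect_gt(sum(res$rejections), 0)
})

test_that("filtering is monotone in its thresholds", {
  fx <- toy_vcf_fixture(seed = 99)
  g <- read_genotypes(fx$vcf)
  md <- stats::setNames(rep(fx$mean_dp, 2), c("s1", "s2"))
  n_strict <- length(extract_loci(g, fx$reference, fx$loci, "per_individual",
                                  loci_config(d = 25), mean_dp = md)$loci)
  n_loose <- length(extract_loci(g, fx$reference, fx$loci, "per_individual",
                                 loci_config(d = 5), mean_dp = md)$loci)
  expect_gte(n_loose, n_strict)
  n_tight_miss <- length(extract_loci(g, fx$reference, fx$loci,
                                      "per_individual",
                                      loci_config(d = 10, max_missing = 0.2),
                                      mean_dp = md)$loci)
  n_loose_miss <- length(extract_loci(g, fx$reference, fx$loci,
                                      "per_individual",
                                      loci_config(d = 10, max_missing = 0.8),
                                      mean_dp = md)$loci)
  expect_gte(n_loose_miss, n_tight_miss)
})

test_that("per-individual alignments have no missing columns and use IUPAC", {
  fx <- toy_vcf_fixture(seed = 55)
  g <- read_genotypes(fx$vcf)
  md <- stats::setNames(rep(fx$mean_dp, 2), c("s1", "s2"))
  res <- extract_loci(g, fx$reference, fx$loci, "per_individual",
                      loci_config(d = fx$d), mean_dp = md)
  ok_chars <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M")
  for (a in res$loci) {
    chars <- unlist(strsplit(a$seqs, ""))
    expect_true(all(chars %in% ok_chars))
  }
})

test_that("joint mode masks low-depth and low-quality sites and drops rows", {
  ref <- c(chr1 = paste(rep("A", 60), collapse = ""))
  mk_row <- function(pos, ref_a, alt, qual, info, gts) {
    paste(c("chr1", pos, ".", ref_a, alt, qual, ".", info, "GT:DP:GQ", gts),
          collapse = "\t")
  }
  vcf <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    mk_row(10, "A", "G", 60, "DP=50;QD=10;MQ=55",
           c("0/1:25:60", "1/1:25:60")),      # good SNP -> R and G
    mk_row(15, "A", "C", 60, "DP=50;QD=9;MQ=50",
           c("0/1:25:60", "./.:25:60")),      # s2 missing at a good SNP
    mk_row(20, "A", "G", 60, "DP=50;QD=1;MQ=55",
           c("0/1:25:60", "0/0:25:60")),      # low QD -> N column
    mk_row(30, "A", ".", 60, "DP=5", c("0/0:2:60", "0/0:2:60")), # low depth
    mk_row(40, "AT", "A", 60, "DP=50", c("0/0:25:60", "0/0:25:60"))) # indel
  tf <- tempfile(fileext = ".vcf"); writeLines(vcf, tf)
  g <- read_genotypes(tf)
  a <- build_locus_alignment(g, ref, list(chrom = "chr1", start = 0L,
                                          end = 60L), "joint",
                             loci_config())
  expect_false(is_rejected(a))
  s1 <- strsplit(a$seqs[["s1"]], "")[[1]]
  s2 <- strsplit(a$seqs[["s2"]], "")[[1]]
  # SNP sites kept with per-sample genotypes
  expect_true("R" %in% s1 && "G" %in% s2)
  # a failed per-sample call at a good SNP leaves N only in that sample
  expect_true("M" %in% s1)
  expect_equal(sum(s2 == "N"), 1L)
  # site-level masks (low QD, low depth, indel +- 5 bp) become all-missing
  # columns and are removed: 60 - {pos 19} - {pos 29} - {pos 34..44} = 47
  expect_equal(length(s1), 47L)
  expect_false(any(s1 == "-"))
})
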