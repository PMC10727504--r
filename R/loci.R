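#' Locus extraction from genotype calls
#'
#' Turns per-sample genotype calls (VCF), a reference sequence and
#' annotation intervals into filtered multilocus alignments: coding loci
#' coincide with protein-coding sequence (>= 100 bp), noncoding loci are
#' carved from the CDS/repeat complement (100-1000 bp), repetitive regions
#' are excluded, loci are spaced >= 2 kb apart, genotypes are filtered on
#' site quality, genotype quality and read depth, sites near indels are
#' masked, and loci with too much missing data or too few remaining sites
#' are rejected.  All coordinates are 0-based half-open internally (BED
#' native; VCF positions are converted on read).
#'
#' @name loci_extract
NULL

#' Locus-planning / filtering configuration
#'
#' @param min_coding minimum coding locus length (bp).
#' @param noncoding_range noncoding locus length range (bp).
#' @param spacing minimum gap between loci on a chromosome (bp).
#' @param relaxed_regions region labels where spacing is not enforced
#'   (e.g. inside an inversion where recombination is suppressed).
#' @param d base depth threshold for genotype filtering (12 or 20 in
#'   typical resequencing datasets).
#' @param indel_window mask sites within this many bp of an indel.
#' @param max_missing reject a locus when its pre-removal missing-data
#'   fraction exceeds this.
#' @param min_sites reject a locus with fewer sites remaining (strictly
#'   more than 10 sites are required by default).
#' @param joint_min_depth site depth below which joint-mode constant sites
#'   are masked as '-'.
#' @param qd_min,mq_min joint-mode SNP quality gates.
#' @return a `loci_config` list.
#' @export
loci_config <- function(min_coding = 100L, noncoding_range = c(100L, 1000L),
                        spacing = 2000L, relaxed_regions = character(),
                        d = 20, indel_window = 5L, max_missing = 0.5,
                        min_sites = 11L, joint_min_depth = 20,
                        qd_min = 2.0, mq_min = 40) {
  structure(as.list(environment()), class = "loci_config")
}

iranges_of <- function(df, chrom) {
  sel <- df$chrom == chrom
  IRanges::IRanges(start = df$start[sel] + 1L, end = df$end[sel])
}

check_intervals <- function(df, chrom_lengths, what) {
  if (!nrow(df)) return(invisible())
  if (any(df$end <= df$start)) stop(what, ": empty or inverted interval")
  for (ch in unique(df$chrom)) {
    if (!ch %in% names(chrom_lengths))
      stop(what, ": unknown chromosome ", ch)
    sel <- df$chrom == ch
    if (any(df$end[sel] > chrom_lengths[[ch]]))
      stop(what, ": interval beyond the length of ", ch)
    if (is.unsorted(df$start[sel]))
      stop(what, ": intervals on ", ch, " are not sorted")
  }
  invisible()
}

#' Plan coding and noncoding loci from annotation
#'
#' @param cds_intervals,repeat_intervals,region_intervals data frames with
#'   columns `chrom`, `start`, `end` (0-based half-open);
#'   `region_intervals` additionally has `label` and may be `NULL`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param cfg a [loci_config()].
#' @return data frame of loci: `chrom`, `start`, `end`, `class`
#'   (coding/noncoding), `region`.
#' @export
plan_loci <- function(cds_intervals, repeat_intervals,
                      region_intervals = NULL, chrom_lengths,
                      cfg = loci_config()) {
  check_intervals(cds_intervals, chrom_lengths, "CDS")
  check_intervals(repeat_intervals, chrom_lengths, "repeats")
  out <- NULL
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    cds <- IRanges::reduce(iranges_of(cds_intervals, ch))
    rep_ <- IRanges::reduce(iranges_of(repeat_intervals, ch))
    coding <- IRanges::setdiff(cds, rep_)
    coding <- coding[IRanges::width(coding) >= cfg$min_coding]
    # noncoding: complement of CDS and repeats, carved into <= max pieces
    occ <- IRanges::reduce(c(cds, rep_))
    gaps <- IRanges::gaps(occ, start = 1L, end = len)
    nc_start <- integer(0); nc_end <- integer(0)
    for (i in seq_along(gaps)) {
      s <- IRanges::start(gaps)[i]; e <- IRanges::end(gaps)[i]
      while (e - s + 1L >= cfg$noncoding_range[1]) {
        piece_end <- min(e, s + cfg$noncoding_range[2] - 1L)
        nc_start <- c(nc_start, s); nc_end <- c(nc_end, piece_end)
        s <- piece_end + 1L
      }
    }
    mk <- function(ir_start, ir_end, cls) {
      if (!length(ir_start)) return(NULL)
      data.frame(chrom = ch, start = ir_start - 1L, end = ir_end,
                 class = cls, stringsAsFactors = FALSE)
    }
    cand <- rbind(mk(IRanges::start(coding), IRanges::end(coding), "coding"),
                  mk(nc_start, nc_end, "noncoding"))
    if (is.null(cand)) next
    # region labels
    cand$region <- ""
    if (!is.null(region_intervals) && nrow(region_intervals)) {
      rr <- region_intervals[region_intervals$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(rr)))
        cand$region[cand$start < rr$end[i] & cand$end > rr$start[i]] <-
          rr$label[i]
    }
    # greedy left-to-right spacing, per class
    for (cls in c("coding", "noncoding")) {
      sel <- which(cand$class == cls)
      sel <- sel[order(cand$start[sel])]
      last_end <- -Inf
      keep <- logical(length(sel))
      for (k in seq_along(sel)) {
        i <- sel[k]
        gap_needed <- if (cand$region[i] %in% cfg$relaxed_regions) 0
                      else cfg$spacing
        if (cand$start[i] - last_end >= gap_needed) {
          keep[k] <- TRUE
          last_end <- cand$end[i]
        }
      }
      cand <- cand[-sel[!keep], , drop = FALSE]
    }
    out <- rbind(out, cand)
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), class = character(),
                      region = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genotype-call quality filter
#'
#' Keep a genotype call iff `QUAL >= 20`, `GQ >= 20` and
#' `max(meanDP/2, d') <= DP <= 2 meanDP`, where `d' = d/2` for the Z
#' chromosome in (heterogametic) females and `d' = d` otherwise.
#'
#' @param qual site quality (applied at variant and invariant sites).
#' @param gq genotype quality.
#' @param dp read depth.
#' @param mean_dp sample-averaged read depth (> 0), per sample per
#'   chromosome.
#' @param d base depth threshold (12 or 20).
#' @param female_z is this a female sample on the Z chromosome?
#' @return logical: keep (TRUE) or mask (FALSE); vectorized.
#' @export
genotype_keep <- function(qual, gq, dp, mean_dp, d = 20, female_z = FALSE) {
  if (any(mean_dp <= 0)) stop("mean_dp must be positive")
  dprime <- ifelse(female_z, d / 2, d)
  qual >= 20 & gq >= 20 & dp >= pmax(mean_dp / 2, dprime) & dp <= 2 * mean_dp
}

#' Mask sites near indels
#'
#' @param site_positions 0-based site positions.
#' @param indel_positions 0-based indel positions.
#' @param window mask sites within this many bp of any indel.
#' @return the masked subset of `site_positions`.
#' @export
mask_near_indels <- function(site_positions, indel_positions, window = 5L) {
  if (!length(indel_positions) || !length(site_positions))
    return(site_positions[0])
  ind <- sort(indel_positions)
  i <- findInterval(site_positions, ind)
  d_left <- ifelse(i >= 1, site_positions - ind[pmax(i, 1L)], Inf)
  d_right <- ifelse(i < length(ind), ind[pmin(i + 1L, length(ind))] -
                      site_positions, Inf)
  site_positions[pmin(d_left, d_right) <= window]
}

#' Read genotype calls from a VCF file
#'
#' Thin wrapper around `vcfR` returning the site table and per-sample
#' genotype matrices used by [build_locus_alignment()].  Positions are
#' converted to 0-based.
#'
#' @param path path to a (possibly gzipped) VCF.
#' @return list with `site` (data frame: chrom, pos0, ref, alt, qual, qd,
#'   mq, dp_info, is_indel), matrices `GT`, `DP`, `GQ` (sites x samples)
#'   and `samples`.
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, key)))
  }
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  is_indel <- nchar(ref) > 1L |
    vapply(strsplit(ifelse(is.na(alt), "", alt), ","), function(a)
      any(nchar(a) > 1L), TRUE)
  site <- data.frame(chrom = fix[, "CHROM"],
                     pos0 = as.integer(fix[, "POS"]) - 1L,
                     ref = ref, alt = alt,
                     qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                     qd = info_num("QD"), mq = info_num("MQ"),
                     dp_info = info_num("DP"),
                     is_indel = is_indel, stringsAsFactors = FALSE)
  num_mat <- function(el) {
    m <- vcfR::extract.gt(v, element = el)
    storage.mode(m) <- "numeric"
    m
  }
  list(site = site, GT = vcfR::extract.gt(v, element = "GT"),
       DP = num_mat("DP"), GQ = num_mat("GQ"),
       samples = colnames(v@gt)[-1])
}

#' Per-sample mean read depth
#'
#' @param genotypes output of [read_genotypes()].
#' @return named numeric vector of sample-averaged depths.
#' @export
mean_depth <- function(genotypes) {
  colMeans(genotypes$DP, na.rm = TRUE)
}

gt_to_base <- function(gt, ref, alt) {
  if (is.na(gt)) return(NA_character_)
  alleles <- c(ref, strsplit(ifelse(is.na(alt), "", alt), ",")[[1]])
  idx <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]])) + 1L
  if (anyNA(idx) || any(idx > length(alleles))) return(NA_character_)
  b <- sort(unique(alleles[idx]))
  if (any(nchar(b) != 1L) || !all(b %in% c("A", "C", "G", "T")))
    return(NA_character_)
  if (length(b) == 1L) return(b)
  if (length(b) > 2L) return(NA_character_)
  unname(iupac_pair_codes()[paste0(b[1], b[2])])
}

#' Build one locus alignment from genotype calls
#'
#' `per_individual` mode applies the genotype filters
#' ([genotype_keep()]), masks sites near indels, codes heterozygotes as
#' IUPAC ambiguities, removes every column containing missing data, and
#' rejects the locus when the pre-removal missing fraction exceeds 50% or
#' 10 or fewer sites remain.  `joint` mode takes constant sites from the
#' reference, masks sites with joint depth below 20 as `-` and non-SNP or
#' low-quality variants (QD < 2 or MQ < 40) as `N`, drops sequences with
#' more than 50% missing data and all-missing columns, and rejects loci
#' with fewer than two sequences left.
#'
#' @param genotypes output of [read_genotypes()].
#' @param reference named character vector of chromosome sequences.
#' @param spec one row of [plan_loci()] output (or a list with `chrom`,
#'   `start`, `end`).
#' @param mode `"per_individual"` or `"joint"`.
#' @param cfg a [loci_config()].
#' @param mean_dp per-sample mean depths (default [mean_depth()]).
#' @param female_z_samples samples to which the halved Z-chromosome depth
#'   threshold applies for this locus.
#' @return a `locus_alignment`, or a `locus_rejection` (with a `reason`
#'   attribute; test with [is_rejected()]) when the locus is rejected.
#' @export
build_locus_alignment <- function(genotypes, reference, spec,
                                  mode = c("per_individual", "joint"),
                                  cfg = loci_config(),
                                  mean_dp = mean_depth(genotypes),
                                  female_z_samples = character()) {
  mode <- match.arg(mode)
  chrom <- as.character(spec$chrom)
  if (!chrom %in% names(reference)) stop("unknown chromosome ", chrom)
  refseq <- reference[[chrom]]
  if (spec$start < 0 || spec$end > nchar(refseq))
    stop("locus outside the reference sequence")
  L <- spec$end - spec$start
  pos <- spec$start:(spec$end - 1L)
  refbase <- strsplit(toupper(substr(refseq, spec$start + 1L, spec$end)),
                      "")[[1]]
  st <- genotypes$site
  in_locus <- which(st$chrom == chrom & st$pos0 >= spec$start &
                      st$pos0 < spec$end)
  reject <- function(reason)
    structure(NA, class = "locus_rejection", reason = reason)
  indel_pos <- st$pos0[st$chrom == chrom & st$is_indel]
  masked_near <- mask_near_indels(pos, indel_pos, cfg$indel_window)
  samples <- genotypes$samples
  if (mode == "per_individual") {
    if (!length(in_locus)) return(reject("no genotype records"))
    seqs <- matrix(rep(NA_character_, length(samples) * L),
                   nrow = length(samples),
                   dimnames = list(samples, NULL))
    rec_at <- match(pos, st$pos0[in_locus])
    for (s in seq_along(samples)) {
      sample <- samples[s]
      row <- refbase
      row[] <- NA_character_ # no record = missing
      for (k in seq_along(pos)) {
        r <- rec_at[k]
        if (is.na(r)) next
        i <- in_locus[r]
        if (st$is_indel[i]) next # indel record: masked
        keep <- genotype_keep(st$qual[i], genotypes$GQ[i, sample],
                              genotypes$DP[i, sample], mean_dp[[sample]],
                              d = cfg$d,
                              female_z = sample %in% female_z_samples)
        if (isTRUE(keep))
          row[k] <- gt_to_base(genotypes$GT[i, sample], st$ref[i],
                               st$alt[i])
      }
      seqs[s, ] <- row
    }
    seqs[, pos %in% masked_near] <- NA_character_
    miss_frac <- mean(is.na(seqs))
    if (miss_frac > cfg$max_missing)
      return(reject("more than 50% missing data"))
    keep_col <- colSums(is.na(seqs)) == 0L
    if (sum(keep_col) < cfg$min_sites)
      return(reject("10 or fewer sites remaining"))
    seqs <- seqs[, keep_col, drop = FALSE]
    strs <- apply(seqs, 1L, paste, collapse = "")
    new_locus_alignment(stats::setNames(strs, samples),
                        stats::setNames(samples, samples), spec)
  } else {
    # joint mode: reference-backed constant sites, site-level masks
    col_state <- refbase # default: reference base for everyone
    per_sample_at <- list()
    for (k in seq_along(pos)) {
      r <- match(pos[k], st$pos0[in_locus])
      if (is.na(r)) next
      i <- in_locus[r]
      dp <- st$dp_info[i]
      if (!is.na(dp) && dp < cfg$joint_min_depth) { col_state[k] <- "-"; next }
      if (st$is_indel[i]) { col_state[k] <- "N"; next }
      if (!is.na(st$alt[i]) && nzchar(st$alt[i])) {
        ok <- !is.na(st$qd[i]) && st$qd[i] >= cfg$qd_min &&
          !is.na(st$mq[i]) && st$mq[i] >= cfg$mq_min
        if (!ok) { col_state[k] <- "N"; next }
        col_state[k] <- "SNP"
        per_sample_at[[as.character(k)]] <- i
      }
    }
    col_state[pos %in% masked_near] <- "N"
    seqs <- matrix(rep(col_state, each = length(samples)),
                   nrow = length(samples), dimnames = list(samples, NULL))
    for (k in names(per_sample_at)) {
      kk <- as.integer(k)
      if (col_state[kk] != "SNP") next
      i <- per_sample_at[[k]]
      for (s in seq_along(samples)) {
        b <- gt_to_base(genotypes$GT[i, samples[s]], st$ref[i], st$alt[i])
        seqs[s, kk] <- if (is.na(b)) "N" else b
      }
    }
    seqs[seqs == "SNP"] <- "N"
    miss <- seqs %in% c("N", "-")
    dim(miss) <- dim(seqs)
    keep_seq <- rowMeans(miss) <= cfg$max_missing
    if (sum(keep_seq) < 2L)
      return(reject("fewer than two sequences remaining"))
    seqs <- seqs[keep_seq, , drop = FALSE]
    miss <- miss[keep_seq, , drop = FALSE]
    keep_col <- colSums(!miss) > 0L
    seqs <- seqs[, keep_col, drop = FALSE]
    if (!ncol(seqs)) return(reject("no sites remaining"))
    strs <- apply(seqs, 1L, paste, collapse = "")
    sm <- samples[keep_seq]
    new_locus_alignment(stats::setNames(strs, sm),
                        stats::setNames(sm, sm), spec)
  }
}

#' Extract all planned loci from a VCF-backed dataset
#'
#' Applies [build_locus_alignment()] to every locus of a plan and reports
#' per-reason rejection counts.
#'
#' @inheritParams build_locus_alignment
#' @param plan data frame from [plan_loci()].
#' @return list with `loci` (list of `locus_alignment`), `index` (data
#'   frame of surviving loci), `rejections` (named counts).
#' @export
extract_loci <- function(genotypes, reference, plan,
                         mode = c("per_individual", "joint"),
                         cfg = loci_config(),
                         mean_dp = mean_depth(genotypes),
                         female_z_samples = character()) {
  mode <- match.arg(mode)
  loci <- list(); idx <- NULL
  rej <- integer()
  for (i in seq_len(nrow(plan))) {
    a <- build_locus_alignment(genotypes, reference, plan[i, ], mode, cfg,
                               mean_dp, female_z_samples)
    if (is_rejected(a)) {
      r <- attr(a, "reason")
      rej[r] <- if (r %in% names(rej)) rej[[r]] + 1L else 1L
    } else {
      loci[[length(loci) + 1L]] <- a
      idx <- rbind(idx, data.frame(plan[i, ], n_seqs = length(a$seqs),
                                   n_sites = a$n_sites))
    }
  }
  list(loci = loci, index = idx, rejections = rej)
}

#' Was a locus rejected by the filters?
#'
#' @param x return value of [build_locus_alignment()].
#' @return TRUE for a `locus_rejection`.
#' @export
is_rejected <- function(x) inherits(x, "locus_rejection")

#' @export
print.locus_rejection <- function(x, ...) {
  cat("locus rejected:", attr(x, "reason"), "\n")
  invisible(x)
}
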