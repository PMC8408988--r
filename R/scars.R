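# Genomic scar scores from allele-specific copy-number segments.
#
# The three components of the HRD score are counted from a per-sample
# segment table (1-based inclusive coordinates, SEG convention):
#   * LOH  - loss-of-heterozygosity regions longer than 15 Mb that do not
#            span a whole chromosome,
#   * ntAI - allelic-imbalance segments reaching a telomere without crossing
#            the centromere, above an 11 Mb size floor,
#   * LST  - chromosome-arm breakpoints between adjacent >= 10 Mb segments
#            (<= 3 Mb apart) after smoothing away segments < 3 Mb.
# All thresholds are exposed through scar_thresholds().

#' Default scar-count thresholds (base pairs)
#'
#' @param loh_min Minimum LOH segment length (exclusive), default 15 Mb.
#' @param tai_min Telomeric-allelic-imbalance size floor (exclusive), 11 Mb.
#' @param lst_seg Minimum length of each segment flanking an LST breakpoint,
#'   10 Mb (inclusive).
#' @param lst_gap Maximum gap between the two flanking segments, 3 Mb.
#' @param lst_smooth Segments shorter than this are smoothed away before
#'   breakpoints are counted, 3 Mb.
#' @return Named list of thresholds in bp.
#' @export
scar_thresholds <- function(loh_min = 15 * MB, tai_min = 11 * MB,
                            lst_seg = 10 * MB, lst_gap = 3 * MB,
                            lst_smooth = 3 * MB) {
  list(loh_min = loh_min, tai_min = tai_min, lst_seg = lst_seg,
       lst_gap = lst_gap, lst_smooth = lst_smooth)
}

#' Validate a segment table
#'
#' @param segments data.frame with columns chrom, start, end, total_cn,
#'   minor_cn (one sample; a `sample` column is allowed and ignored here).
#' @return The segment table, invisibly, ordered by (chrom, start).
#' @keywords internal
validate_segments <- function(segments) {
  .check_columns(segments, c("chrom", "start", "end", "total_cn", "minor_cn"),
                 "segment table")
  if (nrow(segments) == 0L) return(invisible(segments))
  if (any(segments$end < segments$start)) {
    stop("malformed segment: end < start")
  }
  if (any(segments$total_cn < 0) || any(segments$minor_cn < 0)) {
    stop("copy numbers must be non-negative")
  }
  if (any(segments$minor_cn > segments$total_cn)) {
    stop("minor-allele copy number exceeds total copy number")
  }
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)])) {
      stop(sprintf("overlapping segments on chromosome %s", ch))
    }
  }
  invisible(segments)
}

.seg_len <- function(segments) segments$end - segments$start + 1

.genome_lookup <- function(genome, chroms) {
  .check_columns(genome, c("chrom", "length"), "genome annotation")
  miss <- setdiff(chroms, genome$chrom)
  if (length(miss)) {
    stop(sprintf("genome annotation missing chromosome(s): %s",
                 paste(miss, collapse = ", ")))
  }
  genome[match(chroms, genome$chrom), , drop = FALSE]
}

#' Count large loss-of-heterozygosity regions
#'
#' A segment counts when its minor-allele copy number is 0, its total copy
#' number is at least 1 (so homozygous deletions are excluded), it is longer
#' than the LOH threshold, and it does not span the entire chromosome.
#'
#' @param segments One sample's segment table.
#' @param genome Genome annotation: chrom, length, cen_start, cen_end.
#' @param thresholds See [scar_thresholds()].
#' @return Integer count.
#' @export
count_loh <- function(segments, genome, thresholds = scar_thresholds()) {
  segments <- validate_segments(segments)
  if (nrow(segments) == 0L) return(0L)
  g <- .genome_lookup(genome, unique(segments$chrom))
  chrom_len <- g$length[match(segments$chrom, g$chrom)]
  len <- .seg_len(segments)
  hit <- segments$minor_cn == 0 & segments$total_cn >= 1 &
    len > thresholds$loh_min &
    !(segments$start == 1 & segments$end == chrom_len)
  sum(hit)
}

#' Count telomeric allelic imbalances
#'
#' A segment counts when its alleles are imbalanced (minor != total - minor),
#' it reaches a chromosome end, it does not cross the centromere, and it is
#' longer than the size floor.
#'
#' @inheritParams count_loh
#' @return Integer count.
#' @export
count_tai <- function(segments, genome, thresholds = scar_thresholds()) {
  segments <- validate_segments(segments)
  if (nrow(segments) == 0L) return(0L)
  .check_columns(genome, c("chrom", "length", "cen_start", "cen_end"),
                 "genome annotation")
  g <- .genome_lookup(genome, unique(segments$chrom))
  if (any(is.na(g$cen_start)) || any(is.na(g$cen_end))) {
    stop("centromere interval missing for a chromosome present in the profile")
  }
  idx <- match(segments$chrom, g$chrom)
  chrom_len <- g$length[idx]
  cen_start <- g$cen_start[idx]
  cen_end <- g$cen_end[idx]
  len <- .seg_len(segments)
  imbalanced <- segments$minor_cn != (segments$total_cn - segments$minor_cn)
  telomeric <- segments$start == 1 | segments$end == chrom_len
  crosses_cen <- segments$start <= cen_end & segments$end >= cen_start
  sum(imbalanced & telomeric & !crosses_cen & len > thresholds$tai_min)
}

# Split segments into chromosome-arm pieces, trimming at the centromere.
.arm_pieces <- function(segments, genome) {
  g <- .genome_lookup(genome, unique(segments$chrom))
  out <- vector("list", 2L * nrow(g))
  k <- 0L
  for (i in seq_len(nrow(g))) {
    ch <- g$chrom[i]
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) next
    for (arm in c("p", "q")) {
      lo <- if (arm == "p") 1 else g$cen_end[i] + 1
      hi <- if (arm == "p") g$cen_start[i] - 1 else g$length[i]
      a <- s[s$start <= hi & s$end >= lo, , drop = FALSE]
      if (nrow(a) == 0L) next
      a$start <- pmax(a$start, lo)
      a$end <- pmin(a$end, hi)
      a$arm <- paste0(ch, arm)
      k <- k + 1L
      out[[k]] <- a
    }
  }
  if (k == 0L) return(NULL)
  do.call(rbind, out[seq_len(k)])
}

# Smooth one arm: segments shorter than `smooth` are dropped, unless they
# share an exact boundary with a neighbour, in which case the larger
# neighbour (left on ties) absorbs their span. Deterministic: the shortest
# (first on ties) small segment is handled each round.
.smooth_arm <- function(a, smooth) {
  a <- a[order(a$start), , drop = FALSE]
  repeat {
    len <- a$end - a$start + 1
    small <- which(len < smooth)
    if (length(small) == 0L || nrow(a) == 1L) break
    i <- small[which.min(len[small])]
    left_adj <- i > 1L && a$start[i] == a$end[i - 1L] + 1
    right_adj <- i < nrow(a) && a$end[i] == a$start[i + 1L] - 1
    if (left_adj && right_adj) {
      take_left <- len[i - 1L] >= len[i + 1L]  # left neighbour on ties
    } else if (left_adj) {
      take_left <- TRUE
    } else if (right_adj) {
      take_left <- FALSE
    } else {
      a <- a[-i, , drop = FALSE]  # isolated small segment: removed
      next
    }
    if (take_left) a$end[i - 1L] <- a$end[i] else a$start[i + 1L] <- a$start[i]
    a <- a[-i, , drop = FALSE]
  }
  a
}

#' Count large-scale transitions
#'
#' After per-arm smoothing of segments shorter than 3 Mb, counts breakpoints
#' between adjacent segments that differ in copy state, are each at least
#' 10 Mb long, and lie at most 3 Mb apart.
#'
#' @inheritParams count_tai
#' @return Integer count.
#' @export
count_lst <- function(segments, genome, thresholds = scar_thresholds()) {
  segments <- validate_segments(segments)
  if (nrow(segments) == 0L) return(0L)
  .check_columns(genome, c("chrom", "length", "cen_start", "cen_end"),
                 "genome annotation")
  pieces <- .arm_pieces(segments, genome)
  if (is.null(pieces)) return(0L)
  n <- 0L
  for (arm in unique(pieces$arm)) {
    a <- .smooth_arm(pieces[pieces$arm == arm, , drop = FALSE],
                     thresholds$lst_smooth)
    if (nrow(a) < 2L) next
    len <- a$end - a$start + 1
    for (i in seq_len(nrow(a) - 1L)) {
      gap <- a$start[i + 1L] - a$end[i] - 1
      state_change <- a$total_cn[i] != a$total_cn[i + 1L] ||
        a$minor_cn[i] != a$minor_cn[i + 1L]
      if (state_change && gap <= thresholds$lst_gap &&
          len[i] >= thresholds$lst_seg && len[i + 1L] >= thresholds$lst_seg) {
        n <- n + 1L
      }
    }
  }
  n
}

#' HRD score of one sample
#'
#' Sum of the LOH, ntAI and LST counts; the total is the quantity compared
#' against the deficiency threshold of 42.
#'
#' @inheritParams count_tai
#' @return List of class `hrd_score`: loh_count, tai_count, lst_count, total.
#' @export
hrd_score <- function(segments, genome, thresholds = scar_thresholds()) {
  loh <- count_loh(segments, genome, thresholds)
  tai <- count_tai(segments, genome, thresholds)
  lst <- count_lst(segments, genome, thresholds)
  structure(list(loh_count = loh, tai_count = tai, lst_count = lst,
                 total = loh + tai + lst),
            class = "hrd_score")
}

#' @export
print.hrd_score <- function(x, ...) {
  cat(sprintf("HRD score: %d (LOH %d + ntAI %d + LST %d)\n",
              x$total, x$loh_count, x$tai_count, x$lst_count))
  invisible(x)
}

#' HRD scores for every sample in a cohort segment table
#'
#' @param segments Segment table with a `sample` column.
#' @inheritParams count_tai
#' @return data.frame: sample, loh_count, tai_count, lst_count, total.
#' @export
hrd_score_cohort <- function(segments, genome,
                             thresholds = scar_thresholds()) {
  .check_columns(segments, "sample", "cohort segment table")
  samples <- unique(segments$sample)
  by_sample <- split(segments, factor(segments$sample, levels = samples))
  rows <- lapply(samples, function(sm) {
    sc <- hrd_score(by_sample[[sm]], genome, thresholds)
    data.frame(sample = sm, loh_count = sc$loh_count, tai_count = sc$tai_count,
               lst_count = sc$lst_count, total = sc$total)
  })
  do.call(rbind, rows)
}

#' Consequence classes treated as deleterious for BRCA1/2
#' @return Character vector.
#' @export
deleterious_consequences <- function() {
  c("frameshift", "nonsense", "splice_site", "pathogenic_missense")
}

#' Classify homologous recombination status
#'
#' A sample is HR-deficient iff it carries a deleterious tumour BRCA1/2
#' mutation or its HRD score total meets the threshold (default 42,
#' inclusive).
#'
#' @param score An `hrd_score` or a single total.
#' @param brca_mutations Mutation rows for this sample (may be empty);
#'   filtered here to deleterious BRCA1/2 calls via `gene` and `consequence`.
#' @param threshold HRD-score cutoff, default 42.
#' @param deleterious Consequence classes counted as deleterious.
#' @return List of class `hr_status_call`: tbrca_mutated, hrd_total, status.
#' @export
classify_hr_status <- function(score, brca_mutations = NULL, threshold = 42,
                               deleterious = deleterious_consequences()) {
  total <- if (inherits(score, "hrd_score")) score$total else as.integer(score)
  tbrca <- FALSE
  if (!is.null(brca_mutations) && nrow(brca_mutations) > 0L) {
    .check_columns(brca_mutations, c("gene", "consequence"), "mutation table")
    tbrca <- any(brca_mutations$gene %in% c("BRCA1", "BRCA2") &
                   brca_mutations$consequence %in% deleterious)
  }
  structure(list(tbrca_mutated = tbrca, hrd_total = total,
                 status = if (tbrca || total >= threshold)
                   "HR-deficient" else "HR-proficient"),
            class = "hr_status_call")
}

#' @export
print.hr_status_call <- function(x, ...) {
  cat(sprintf("%s (HRD total %d, tBRCA %s)\n", x$status, x$hrd_total,
              if (x$tbrca_mutated) "mutated" else "wild-type"))
  invisible(x)
}

#' Call BRCA1 promoter hypermethylation from a beta value
#'
#' Epigenetic silencing is called when the probe's beta value strictly
#' exceeds the cutoff (default probe cg13782816, cutoff 0.9). A missing
#' probe yields an explicit `NA` call rather than FALSE.
#'
#' @param betas Named numeric vector of beta values for one sample, or a
#'   probe x sample matrix (then a call per sample is returned).
#' @param probe Probe identifier, default "cg13782816".
#' @param cutoff Strict threshold, default 0.9.
#' @return For a vector: list (probe, beta, silenced). For a matrix: a
#'   data.frame (sample, beta, silenced).
#' @export
call_brca1_methylation <- function(betas, probe = "cg13782816", cutoff = 0.9) {
  if (is.matrix(betas)) {
    beta <- if (probe %in% rownames(betas)) betas[probe, ] else
      rep(NA_real_, ncol(betas))
    return(data.frame(sample = colnames(betas), beta = as.numeric(beta),
                      silenced = as.numeric(beta) > cutoff,
                      row.names = NULL))
  }
  beta <- if (probe %in% names(betas)) unname(betas[[probe]]) else NA_real_
  list(probe = probe, beta = beta,
       silenced = if (is.na(beta)) NA else beta > cutoff)
}

#' Map methylation probes to gene promoters
#'
#' A probe belongs to a gene's promoter iff it lies within 1500 bp upstream
#' to 500 bp downstream of the TSS in transcription orientation (closed
#' interval on both ends); for minus-strand genes the genomic window is
#' TSS - 500 to TSS + 1500.
#'
#' @param probe_positions data.frame: probe, chrom, pos.
#' @param tss_table data.frame: gene, chrom, tss, strand ("+"/"-").
#' @param upstream,downstream Window sizes in bp (defaults 1500/500).
#' @return data.frame: probe, gene.
#' @export
locate_promoter_probes <- function(probe_positions, tss_table,
                                   upstream = 1500, downstream = 500) {
  .check_columns(probe_positions, c("probe", "chrom", "pos"), "probe table")
  .check_columns(tss_table, c("gene", "chrom", "tss", "strand"), "TSS table")
  bad <- !tss_table$strand %in% c("+", "-")
  if (any(bad)) {
    warning(sprintf("skipping %d gene(s) with unknown strand", sum(bad)))
    tss_table <- tss_table[!bad, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(tss_table))) {
    g <- tss_table[i, ]
    if (g$strand == "+") {
      lo <- g$tss - upstream; hi <- g$tss + downstream
    } else {
      lo <- g$tss - downstream; hi <- g$tss + upstream
    }
    hit <- probe_positions$chrom == g$chrom &
      probe_positions$pos >= lo & probe_positions$pos <= hi
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(probe = probe_positions$probe[hit],
                                            gene = g$gene)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(probe = character(), gene = character()))
  }
  do.call(rbind, out)
}

#' Consequence classes counted as nonsynonymous for TMB
#' @return Character vector.
#' @export
nonsynonymous_consequences <- function() {
  c("missense", "pathogenic_missense", "nonsense", "frameshift",
    "splice_site", "inframe_indel")
}

#' Tumour mutation burden of one sample
#'
#' Counts distinct nonsynonymous variants (SNVs and indels). Duplicated
#' variant rows (same chrom, pos, ref, alt) count once.
#'
#' @param mutations One sample's mutation rows with chrom, pos, ref, alt,
#'   consequence.
#' @param nonsynonymous Consequence classes that count.
#' @return Integer count.
#' @export
compute_tmb <- function(mutations,
                        nonsynonymous = nonsynonymous_consequences()) {
  if (is.null(mutations) || nrow(mutations) == 0L) return(0L)
  .check_columns(mutations, c("chrom", "pos", "ref", "alt", "consequence"),
                 "mutation table")
  m <- mutations[mutations$consequence %in% nonsynonymous, , drop = FALSE]
  if (nrow(m) == 0L) return(0L)
  key <- paste(m$chrom, m$pos, m$ref, m$alt, sep = "\r")
  length(unique(key))
}
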