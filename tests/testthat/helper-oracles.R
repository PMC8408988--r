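# Independent brute-force oracles and fixture builders used across tests.
# The oracles are literal per-definition scans, kept separate from the
# package implementation on purpose.

toy_genome_small <- function() {
  data.frame(chrom = c("c1", "c2"),
             length = c(100e6, 80e6),
             cen_start = c(50e6 + 1, 38e6 + 1),
             cen_end = c(55e6, 42e6))
}

seg_row <- function(chrom, start, end, total, minor, sample = NULL) {
  d <- data.frame(chrom = chrom, start = start, end = end,
                  total_cn = total, minor_cn = minor)
  if (!is.null(sample)) d <- cbind(sample = sample, d)
  d
}

# literal LOH scan
oracle_loh <- function(seg, genome, loh_min = 15e6) {
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    chrom_len <- genome$length[genome$chrom == s$chrom]
    len <- s$end - s$start + 1
    whole <- s$start == 1 && s$end == chrom_len
    if (s$minor_cn == 0 && s$total_cn >= 1 && len > loh_min && !whole) {
      n <- n + 1L
    }
  }
  n
}

# literal ntAI scan
oracle_tai <- function(seg, genome, tai_min = 11e6) {
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    g <- genome[genome$chrom == s$chrom, ]
    len <- s$end - s$start + 1
    imbalanced <- s$minor_cn != (s$total_cn - s$minor_cn)
    telomeric <- s$start == 1 || s$end == g$length
    crosses <- s$start <= g$cen_end && s$end >= g$cen_start
    if (imbalanced && telomeric && !crosses && len > tai_min) n <- n + 1L
  }
  n
}

# literal LST scan: per-arm trim, smoothing (< 3 Mb dropped unless sharing a
# boundary; absorbed by the larger neighbour, left on ties), then adjacent
# pairs both >= 10 Mb, gap <= 3 Mb, different state
oracle_lst <- function(seg, genome, seg_min = 10e6, gap_max = 3e6,
                       smooth = 3e6) {
  total <- 0L
  for (ci in seq_len(nrow(genome))) {
    g <- genome[ci, ]
    for (arm in c("p", "q")) {
      lo <- if (arm == "p") 1 else g$cen_end + 1
      hi <- if (arm == "p") g$cen_start - 1 else g$length
      a <- seg[seg$chrom == g$chrom & seg$start <= hi & seg$end >= lo, ,
               drop = FALSE]
      if (nrow(a) == 0L) next
      a$start <- pmax(a$start, lo)
      a$end <- pmin(a$end, hi)
      a <- a[order(a$start), , drop = FALSE]
      repeat {
        len <- a$end - a$start + 1
        small <- which(len < smooth)
        if (length(small) == 0L || nrow(a) == 1L) break
        i <- small[which.min(len[small])]
        left <- i > 1L && a$start[i] == a$end[i - 1L] + 1
        right <- i < nrow(a) && a$end[i] == a$start[i + 1L] - 1
        if (left && right) {
          if (len[i - 1L] >= len[i + 1L]) a$end[i - 1L] <- a$end[i]
          else a$start[i + 1L] <- a$start[i]
        } else if (left) {
          a$end[i - 1L] <- a$end[i]
        } else if (right) {
          a$start[i + 1L] <- a$start[i]
        }
        a <- a[-i, , drop = FALSE]
      }
      if (nrow(a) < 2L) next
      len <- a$end - a$start + 1
      for (i in seq_len(nrow(a) - 1L)) {
        gap <- a$start[i + 1L] - a$end[i] - 1
        differs <- a$total_cn[i] != a$total_cn[i + 1L] ||
          a$minor_cn[i] != a$minor_cn[i + 1L]
        if (differs && gap <= gap_max && len[i] >= seg_min &&
            len[i + 1L] >= seg_min) total <- total + 1L
      }
    }
  }
  total
}

# random toy profile: non-overlapping segments with a mix of tiny, medium
# and large lesions in assorted copy states
random_profile <- function(genome, max_segments = 60) {
  rows <- list()
  n_left <- sample.int(max_segments, 1)
  for (ci in seq_len(nrow(genome))) {
    pos <- 1
    while (pos < genome$length[ci] - 2e6 && n_left > 0L) {
      gap <- sample(c(0, sample(1:20, 1) * 5e5), 1, prob = c(0.4, 0.6))
      start <- pos + gap
      len <- sample(c(sample(1:29, 1) * 1e5,        # tiny
                      sample(3:12, 1) * 1e6,        # medium
                      sample(10:30, 1) * 1e6), 1)   # large
      end <- min(start + len - 1, genome$length[ci])
      if (end < start) break
      total <- sample(0:5, 1)
      minor <- sample(0:total, 1)
      rows[[length(rows) + 1L]] <- seg_row(genome$chrom[ci], start, end,
                                           total, minor)
      pos <- end + 1
      n_left <- n_left - 1L
    }
  }
  if (length(rows) == 0L) return(seg_row("c1", 1, 1, 2, 1)[0, ])
  do.call(rbind, rows)
}

# Mann-Whitney AUC of scores against binary labels (independent of the
# package's ROC code)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}
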