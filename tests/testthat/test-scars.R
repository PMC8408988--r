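# Genomic scar counting: LOH, telomeric allelic imbalance, large-scale
# transitions, the HRD score, HR-status classification, BRCA1 promoter
# methylation and TMB.

genome <- toy_genome_small()

test_that("LOH counting follows the size and whole-chromosome rules", {
  expect_identical(count_loh(seg_row("c1", 1, 1, 2, 1)[0, ], genome), 0L)

  # 20 Mb copy-loss LOH inside a 100 Mb chromosome counts once
  expect_equal(count_loh(seg_row("c1", 60e6, 80e6 - 1, 2, 0), genome), 1)
  # the same state spanning the whole chromosome does not count
  expect_equal(count_loh(seg_row("c1", 1, 100e6, 2, 0), genome), 0)
  # ten 10 Mb LOH segments are all below the 15 Mb floor
  ten <- do.call(rbind, lapply(0:9, function(i)
    seg_row("c2", i * 8e6 + 1, i * 8e6 + 7e6, 1, 0)))
  expect_equal(count_loh(ten, genome), 0)
  # exactly 15 Mb does not count (strict), 15 Mb + 1 bp does
  expect_equal(count_loh(seg_row("c1", 10e6, 25e6 - 1, 2, 0), genome), 0)
  expect_equal(count_loh(seg_row("c1", 10e6, 25e6, 2, 0), genome), 1)
  # total copy number 0 (homozygous deletion) is not LOH
  expect_equal(count_loh(seg_row("c1", 10e6, 40e6, 0, 0), genome), 0)

  expect_error(count_loh(seg_row("c1", 50, 10, 2, 0), genome), "end < start")
})

test_that("ntAI requires imbalance, a telomere, and no centromere crossing", {
  expect_identical(count_tai(seg_row("c1", 1, 1, 2, 1)[0, ], genome), 0L)
  # balanced diploid genome: nothing to count
  balanced <- rbind(seg_row("c1", 1, 100e6, 2, 1), seg_row("c2", 1, 80e6, 2, 1))
  expect_equal(count_tai(balanced, genome), 0)
  # 15 Mb imbalanced segment abutting the p-telomere counts
  expect_equal(count_tai(seg_row("c1", 1, 15e6, 3, 1), genome), 1)
  # extended over the centromere (c1 cen at 50-55 Mb) it no longer counts
  expect_equal(count_tai(seg_row("c1", 1, 60e6, 3, 1), genome), 0)
  # q-telomere works symmetrically
  expect_equal(count_tai(seg_row("c1", 80e6, 100e6, 1, 0), genome), 1)
  # interior imbalance does not count
  expect_equal(count_tai(seg_row("c1", 60e6, 80e6, 3, 1), genome), 0)
  # missing centromere annotation is a configuration error
  g2 <- genome; g2$cen_start[1] <- NA
  expect_error(count_tai(seg_row("c1", 1, 15e6, 3, 1), g2), "centromere")
})

test_that("LST counts arm-wise breakpoints after smoothing", {
  # a single segment per chromosome has no breakpoints
  one <- rbind(seg_row("c1", 1, 100e6, 3, 1), seg_row("c2", 1, 80e6, 2, 1))
  expect_equal(count_lst(one, genome), 0)
  # two adjacent 12 Mb segments in different states, zero gap, same arm
  two <- rbind(seg_row("c1", 1e6, 13e6 - 1, 2, 1),
               seg_row("c1", 13e6, 25e6 - 1, 4, 2))
  expect_equal(count_lst(two, genome), 1)
  # separated by a 5 Mb third state: the 5 Mb middle survives the 3 Mb
  # filter but is itself below 10 Mb, so no pair qualifies
  three <- rbind(seg_row("c1", 1e6, 13e6 - 1, 2, 1),
                 seg_row("c1", 13e6, 18e6 - 1, 3, 1),
                 seg_row("c1", 18e6, 30e6 - 1, 4, 2))
  expect_equal(count_lst(three, genome), 0)
  # a < 3 Mb interruption is smoothed into its larger neighbour -> 1
  smoothed <- rbind(seg_row("c1", 1e6, 13e6 - 1, 2, 1),
                    seg_row("c1", 13e6, 15e6 - 1, 3, 1),
                    seg_row("c1", 15e6, 28e6 - 1, 4, 2))
  expect_equal(count_lst(smoothed, genome), 1)
  # breakpoints across the centromere are not counted (arms independent)
  span <- rbind(seg_row("c1", 30e6, 50e6, 2, 1),
                seg_row("c1", 55e6 + 1, 75e6, 4, 2))
  expect_equal(count_lst(span, genome), 0)
  # same state on both sides is not a transition
  same <- rbind(seg_row("c1", 1e6, 13e6 - 1, 2, 1),
                seg_row("c1", 13e6, 25e6 - 1, 2, 1))
  expect_equal(count_lst(same, genome), 0)
})

test_that("hrd_score sums its components and empty profiles give zero", {
  empty <- seg_row("c1", 1, 1, 2, 1)[0, ]
  sc <- hrd_score(empty, genome)
  expect_equal(unlist(sc[c("loh_count", "tai_count", "lst_count", "total")]),
               c(loh_count = 0, tai_count = 0, lst_count = 0, total = 0))
  # components (20, 12, 10) -> total 42 meets the deficiency threshold
  fake <- structure(list(loh_count = 20L, tai_count = 12L, lst_count = 10L,
                         total = 42L), class = "hrd_score")
  expect_equal(fake$total, fake$loh_count + fake$tai_count + fake$lst_count)
  expect_equal(classify_hr_status(fake)$status, "HR-deficient")
})

test_that("scar counts equal the brute-force oracle on random profiles", {
  set.seed(42)
  for (i in 1:300) {
    prof <- random_profile(genome)
    expect_equal(count_loh(prof, genome), oracle_loh(prof, genome))
    expect_equal(count_tai(prof, genome), oracle_tai(prof, genome))
    expect_equal(count_lst(prof, genome), oracle_lst(prof, genome))
  }
})

test_that("isolated balanced diploid segments never change scar counts", {
  set.seed(99)
  for (i in 1:50) {
    prof <- random_profile(genome)
    sc0 <- hrd_score(prof, genome)
    # insert a balanced diploid segment at least 4 Mb away from any other
    # segment and from both telomeres
    for (try in 1:50) {
      ci <- sample.int(nrow(genome), 1)
      start <- sample.int(genome$length[ci] - 30e6, 1) + 10e6
      end <- start + sample(c(1e6, 5e6, 12e6), 1)
      near <- prof$chrom == genome$chrom[ci] &
        prof$start <= end + 4e6 & prof$end >= start - 4e6
      if (!any(near) && end < genome$length[ci] - 4e6) break
    }
    if (any(near)) next
    aug <- rbind(prof, seg_row(genome$chrom[ci], start, end, 2, 1))
    sc1 <- hrd_score(aug, genome)
    expect_equal(sc1$total, sc0$total)
  }
})

test_that("HR-status classification matches the tBRCA-or-threshold rule", {
  no_mut <- data.frame(gene = character(), consequence = character())
  expect_equal(classify_hr_status(41, no_mut)$status, "HR-proficient")
  expect_equal(classify_hr_status(42, no_mut)$status, "HR-deficient")
  brca1_fs <- data.frame(gene = "BRCA1", consequence = "frameshift")
  call <- classify_hr_status(0, brca1_fs)
  expect_true(call$tbrca_mutated)
  expect_equal(call$status, "HR-deficient")
  # synonymous BRCA1 change is not deleterious
  expect_equal(classify_hr_status(0, data.frame(gene = "BRCA1",
                                                consequence = "synonymous"))$status,
               "HR-proficient")
  # monotone: raising the score never flips deficient -> proficient
  for (s in 0:60) {
    lo <- classify_hr_status(s, no_mut)$status
    hi <- classify_hr_status(s + 1, no_mut)$status
    expect_false(lo == "HR-deficient" && hi == "HR-proficient")
  }
})

test_that("BRCA1 promoter methylation uses a strict 0.9 cutoff", {
  expect_true(call_brca1_methylation(c(cg13782816 = 0.95))$silenced)
  expect_false(call_brca1_methylation(c(cg13782816 = 0.90))$silenced)
  miss <- call_brca1_methylation(c(cg00000001 = 0.99))
  expect_true(is.na(miss$silenced))
  m <- matrix(c(0.95, 0.2), nrow = 1,
              dimnames = list("cg13782816", c("A", "B")))
  calls <- call_brca1_methylation(m)
  expect_equal(calls$silenced, c(TRUE, FALSE))
})

test_that("promoter probe mapping respects strand and closed bounds", {
  tss <- data.frame(gene = c("PLUS", "MINUS"), chrom = "c1",
                    tss = c(10000, 50000), strand = c("+", "-"))
  probes <- data.frame(
    probe = c("at_up_edge", "past_down", "minus_up", "minus_past"),
    chrom = "c1",
    pos = c(10000 - 1500, 10000 + 501, 50000 + 1500, 50000 - 501))
  map <- locate_promoter_probes(probes, tss)
  expect_setequal(map$probe[map$gene == "PLUS"], "at_up_edge")
  expect_setequal(map$probe[map$gene == "MINUS"], "minus_up")
  expect_warning(
    locate_promoter_probes(probes,
                           data.frame(gene = "X", chrom = "c1", tss = 1,
                                      strand = "?")),
    "unknown strand")
})

test_that("TMB counts distinct nonsynonymous variants", {
  expect_identical(compute_tmb(NULL), 0L)
  mut <- data.frame(
    chrom = "c1", pos = c(1:5, 6, 6), ref = "A",
    alt = c(rep("T", 6), "T"),
    consequence = c("missense", "missense", "missense", "synonymous",
                    "synonymous", "frameshift", "frameshift"))
  # 3 missense + 1 frameshift (duplicated row counted once)
  expect_equal(compute_tmb(mut), 4)
})
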