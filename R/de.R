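# Negative-binomial differential expression between HR-deficient and
# HR-proficient groups.
#
# The stage follows the familiar count-model contract (median-of-ratios
# normalisation, per-gene dispersion shrunk toward a 1/mean trend, a Wald
# test on the log2 fold change, BH correction) without aiming for
# bit-compatibility with any specific implementation; the downstream
# pipeline only consumes the DEG set. A DESeq2 backend is available when
# that package is installed.

#' Median-of-ratios size factors
#' @param counts Genes x samples non-negative integer matrix.
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) return(rep(1, ncol(counts)))
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - log_geo[use], na.rm = TRUE))
  })
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

.de_nbwald <- function(counts, deficient, proficient, pseudocount = 1) {
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- norm[, deficient, drop = FALSE]
  b <- norm[, proficient, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  keep <- mu_a + mu_b > 0
  lfc <- log2((mu_a + pseudocount) / (mu_b + pseudocount))

  # method-of-moments dispersion, pooled within groups
  var_w <- (rowSums((a - mu_a)^2) + rowSums((b - mu_b)^2)) / (na + nb - 2)
  mu_w <- (na * mu_a + nb * mu_b) / (na + nb)
  disp_raw <- pmax((var_w - mu_w) / mu_w^2, 1e-8)
  # trend: disp ~ a0 + a1/mu, fitted on genes with real signal
  fit_genes <- keep & mu_w > 1 & disp_raw > 1e-8
  if (sum(fit_genes) >= 10L) {
    tf <- stats::lm(disp_raw[fit_genes] ~ I(1 / mu_w[fit_genes]))
    a0 <- max(stats::coef(tf)[1], 1e-4)
    a1 <- max(stats::coef(tf)[2], 0)
  } else {
    a0 <- stats::median(disp_raw[keep]); a1 <- 0
  }
  disp_trend <- a0 + a1 / pmax(mu_w, 1e-8)
  # shrink gene-wise estimates toward the trend on the log scale
  disp <- exp(0.35 * log(pmax(disp_raw, 1e-8)) + 0.65 * log(disp_trend))

  var_mu_a <- (mu_a + disp * mu_a^2) / na
  var_mu_b <- (mu_b + disp * mu_b^2) / nb
  se_lfc <- sqrt(var_mu_a / (mu_a + pseudocount)^2 +
                   var_mu_b / (mu_b + pseudocount)^2) / log(2)
  z <- lfc / se_lfc
  df <- na + nb - 2
  p <- 2 * stats::pt(-abs(z), df = df)
  data.frame(gene = rownames(counts), log2fc = lfc, p = p,
             row.names = NULL)[keep, , drop = FALSE]
}

.de_deseq2 <- function(counts, deficient, proficient) {
  if (!requireNamespace("DESeq2", quietly = TRUE)) {
    stop("method = 'deseq2' requires the DESeq2 package")
  }
  grp <- factor(ifelse(seq_len(ncol(counts)) %in% which(deficient),
                       "deficient", "proficient"),
                levels = c("proficient", "deficient"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = counts, colData = data.frame(group = grp), design = ~group)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds, contrast = c("group", "deficient", "proficient"))
  out <- data.frame(gene = rownames(res), log2fc = res$log2FoldChange,
                    p = res$pvalue, row.names = NULL)
  out[!is.na(out$p), , drop = FALSE]
}

#' Differential expression between HR status groups
#'
#' @param counts Genes x samples integer count matrix.
#' @param groups Character/factor per sample: "HR-deficient"/"HR-proficient"
#'   (or logical, TRUE = deficient).
#' @param fdr_cutoff DEG significance threshold on BH FDR, default 0.05.
#' @param fc_cutoff DEG fold-change threshold, default 2 (>= 2 or <= 1/2).
#' @param method "nbwald" (default, package-internal) or "deseq2".
#' @return data.frame: gene, log2fc (deficient vs proficient), p, fdr, deg
#'   flag. Genes with all-zero counts in both groups are excluded.
#' @export
differential_expression <- function(counts, groups, fdr_cutoff = 0.05,
                                    fc_cutoff = 2,
                                    method = c("nbwald", "deseq2")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers; this stage expects raw ",
         "counts, not log expression")
  }
  if (is.logical(groups)) {
    deficient <- groups
  } else {
    deficient <- as.character(groups) == "HR-deficient"
  }
  proficient <- !deficient
  if (sum(deficient) < 3L || sum(proficient) < 3L) {
    stop("need at least 3 samples per HR status group")
  }
  res <- switch(method,
                nbwald = .de_nbwald(counts, deficient, proficient),
                deseq2 = .de_deseq2(counts, deficient, proficient))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$deg <- res$fdr <= fdr_cutoff &
    (res$log2fc >= log2(fc_cutoff) | res$log2fc <= -log2(fc_cutoff))
  res[order(res$p), , drop = FALSE]
}
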