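# Single-sample immune activity scoring.
#
# GSVA-style kernel scoring is replaced by the simpler ssGSEA rank
# statistic: per sample, genes are ranked by expression and the activity of
# a set is the summed difference between the weighted (exponent 0.25 on
# normalised ranks) cumulative distribution of in-set genes and the
# unweighted CDF of out-set genes. Activities are normalised across the
# cohort by the global max - min range. Only the ordering and sums of these
# scores are consumed downstream, for which the two statistics are
# interchangeable.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name description gene...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (the description is dropped).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    genes <- f[-(1:2)]
    genes[nzchar(genes)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (any(lengths(sets) == 0L)) stop("GMT contains an empty gene set")
  sets
}

#' Write a GMT gene-set file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled), default "na".
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Packaged synthetic immune gene sets
#'
#' Placeholder sets named after the immune response pathways the responder
#' analysis relies on (interferon-gamma signalling, PD-L blockade, CTLA-4
#' pathway, CD28 costimulation, NK cytotoxicity, antigen processing and
#' presentation, JAK-STAT, IL2-STAT4/5 and CD8 effector T cells). The gene
#' memberships are plausible but synthetic; curated sets must be supplied
#' for real analyses.
#'
#' @return Named list of character vectors.
#' @export
default_immune_sets <- function() {
  read_gmt(system.file("extdata", "immune_sets_synthetic.gmt",
                       package = "hrdact", mustWork = TRUE))
}

#' Default prognostic immune marker genes (synthetic placeholder list)
#' @return Character vector of marker gene symbols.
#' @export
default_immune_markers <- function() {
  c("CD8A", "GZMB", "PRF1", "IFNG", "CXCL9", "CXCL10",
    "PDCD1", "CD274", "CTLA4", "LAG3")
}

# ssGSEA enrichment statistic for one pre-sorted sample. in_ord: logical
# set membership in descending-expression order (ties broken by gene name
# upstream so the score is invariant to row order); nr_alpha: normalised
# rank weights ((n:1)/n)^alpha.
.ssgsea_sorted <- function(in_ord, nr_alpha) {
  n_in <- sum(in_ord)
  n_out <- length(in_ord) - n_in
  if (n_in == 0L || n_out == 0L) return(0)
  w <- ifelse(in_ord, nr_alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / n_out
  sum(p_in - p_out)
}

#' Rank-based single-sample gene-set activity
#'
#' @param log_expression Genes x samples numeric matrix (any monotone
#'   per-sample transform of expression gives identical activities).
#' @param sets Named list of gene-identifier vectors.
#' @param alpha Rank-weight exponent, default 0.25.
#' @param normalize Divide by the global max - min range, default TRUE.
#' @param min_genes Sets matching fewer genes are skipped with a warning.
#' @return Sets x samples activity matrix.
#' @export
single_sample_activity <- function(log_expression, sets, alpha = 0.25,
                                   normalize = TRUE, min_genes = 2L) {
  if (is.null(dim(log_expression)) || nrow(log_expression) < 2L) {
    stop("expression matrix must have at least 2 genes")
  }
  if (is.null(rownames(log_expression))) stop("expression needs gene rownames")
  genes <- rownames(log_expression)
  matched <- lapply(sets, function(s) genes %in% s)
  keep <- vapply(matched, sum, integer(1)) >= min_genes
  if (!all(keep)) {
    warning(sprintf("skipping %d set(s) with fewer than %d matched genes: %s",
                    sum(!keep), min_genes,
                    paste(names(sets)[!keep], collapse = ", ")))
  }
  if (!any(keep)) stop("no gene set matches the expression matrix")
  matched <- matched[keep]
  act <- matrix(0, nrow = length(matched), ncol = ncol(log_expression),
                dimnames = list(names(matched), colnames(log_expression)))
  n <- length(genes)
  nr_alpha <- ((n:1) / n)^alpha
  for (j in seq_len(ncol(log_expression))) {
    ord <- order(-log_expression[, j], genes)
    for (i in seq_along(matched)) {
      act[i, j] <- .ssgsea_sorted(matched[[i]][ord], nr_alpha)
    }
  }
  if (normalize) {
    rng <- max(act) - min(act)
    if (rng > 0) act <- act / rng
  }
  act
}

#' Pathway-sum immune score
#'
#' The immune score of a sample is the sum of its activities over the named
#' immune pathways.
#'
#' @param activities Sets x samples matrix from [single_sample_activity()].
#' @param immune_set_names Names of the rows to sum; default all rows.
#' @param quantile Positivity quantile, default 0.75 (top quartile).
#' @return data.frame: sample, method, score, is_positive.
#' @export
immune_score_pathway <- function(activities,
                                 immune_set_names = rownames(activities),
                                 quantile = 0.75) {
  unknown <- setdiff(immune_set_names, rownames(activities))
  if (length(unknown)) {
    stop(sprintf("unknown set name(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(rownames(activities), collapse = ", ")))
  }
  score <- colSums(activities[immune_set_names, , drop = FALSE])
  data.frame(sample = colnames(activities), method = "pathway-sum",
             score = unname(score),
             is_positive = call_quantile_positive(score, quantile),
             row.names = NULL)
}

#' Marker-mean immune score
#'
#' Per-sample mean of the matched marker genes' log expression.
#'
#' @param log_expression Genes x samples matrix.
#' @param marker_genes Marker gene identifiers.
#' @param quantile Positivity quantile, default 0.75.
#' @return data.frame: sample, method, score, is_positive.
#' @export
immune_score_markers <- function(log_expression,
                                 marker_genes = default_immune_markers(),
                                 quantile = 0.75) {
  hit <- rownames(log_expression) %in% marker_genes
  if (!any(hit)) stop("no marker gene matched the expression matrix")
  score <- colMeans(log_expression[hit, , drop = FALSE])
  data.frame(sample = colnames(log_expression), method = "marker-mean",
             score = unname(score),
             is_positive = call_quantile_positive(score, quantile),
             row.names = NULL)
}

#' Top-quartile immune-score positivity
#'
#' Alias of the shared quantile rule: positive iff the score lies strictly
#' above the cohort's 75th percentile.
#'
#' @param scores Numeric scores.
#' @param quantile Default 0.75.
#' @return Logical vector.
#' @export
call_is_positive <- function(scores, quantile = 0.75) {
  call_quantile_positive(scores, quantile)
}
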