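# Trinucleotide spectra and signature-exposure fitting.
#
# Spectra use the pyrimidine-strand convention: every SNV with a purine
# reference (A/G) is reverse-complemented before binning into one of the 96
# canonical channels. Exposure fitting mirrors the iterative
# forward-selection scheme popularised for bulk tumour refitting: greedily
# add the signature that most reduces the reconstruction error of the
# normalised spectrum, refit non-negative weights at each step, stop when
# the improvement drops below a tolerance, then discard weights under the
# 6% floor.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Canonical 96 trinucleotide channel names
#'
#' Ordered by substitution class, then 5' base, then 3' base; names have the
#' form `A[C>A]A`.
#' @return Character vector of length 96.
#' @export
trinucleotide_channels <- function() {
  unlist(lapply(SUBSTITUTION_CLASSES, function(s) {
    unlist(lapply(BASES, function(b5) paste0(b5, "[", s, "]", BASES)))
  }))
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
                character(1)))
}

#' Build a 96-channel trinucleotide spectrum
#'
#' Single-nucleotide variants only; indels and multi-nucleotide variants are
#' ignored. The trinucleotide context is taken from the table (column
#' `trinucleotide_context`, the reference strand 3-mer centred on the
#' variant); contexts that are not 3 ACGT letters with the middle base equal
#' to `ref` are excluded, and the number excluded is attached as attribute
#' `n_excluded`.
#'
#' @param mutations Mutation table with ref, alt, trinucleotide_context.
#' @return Named integer vector of length 96 (class `trinucleotide_spectrum`
#'   via its names), attribute `n_excluded`.
#' @export
build_spectrum <- function(mutations) {
  channels <- trinucleotide_channels()
  counts <- stats::setNames(integer(96), channels)
  if (is.null(mutations) || nrow(mutations) == 0L) {
    attr(counts, "n_excluded") <- 0L
    return(counts)
  }
  .check_columns(mutations, c("ref", "alt", "trinucleotide_context"),
                 "mutation table")
  ref <- toupper(mutations$ref)
  alt <- toupper(mutations$alt)
  ctx <- toupper(mutations$trinucleotide_context)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES & ref != alt
  ref <- ref[is_snv]; alt <- alt[is_snv]; ctx <- ctx[is_snv]
  ok_ctx <- nchar(ctx) == 3L & grepl("^[ACGT]{3}$", ctx) &
    substr(ctx, 2L, 2L) == ref
  n_excluded <- sum(!ok_ctx)
  ref <- ref[ok_ctx]; alt <- alt[ok_ctx]; ctx <- ctx[ok_ctx]
  if (length(ref)) {
    purine <- ref %in% c("A", "G")
    if (any(purine)) {
      ctx[purine] <- .revcomp(ctx[purine])
      ref[purine] <- chartr("AG", "TC", ref[purine])
      alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
    }
    name <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                   substr(ctx, 3, 3))
    tab <- table(factor(name, levels = channels))
    counts[] <- as.integer(tab)
  }
  attr(counts, "n_excluded") <- n_excluded
  counts
}

#' Packaged synthetic signature matrix
#'
#' A deterministic, synthetic stand-in for a COSMIC v2-style mutational
#' process matrix with five columns: SBS1 (CpG deamination-like, mass on
#' `N[C>T]G`), SBS3 (broad, mildly tilted across classes, the HRD-associated
#' process), SBS6 (C>T outside CpG), SBS20 (T>C heavy) and `flat` (uniform).
#' These are stylised shapes for simulation and testing, not the published
#' COSMIC profiles; real matrices can be supplied as a 96 x k matrix whose
#' columns sum to 1 (e.g. read from TSV).
#'
#' @return 96 x 5 matrix; rows named by channel, columns by signature.
#' @export
default_signature_matrix <- function() {
  channels <- trinucleotide_channels()
  sub <- sub(".*\\[(.+)\\].*", "\\1", channels)
  b5 <- substr(channels, 1, 1)
  b3 <- substr(channels, 7, 7)

  sbs1 <- rep(0.28 / 92, 96)
  cpg <- sub == "C>T" & b3 == "G"
  sbs1[cpg] <- 0.72 / 4

  sbs6 <- numeric(96)
  ct_noncpg <- sub == "C>T" & b3 != "G"
  sbs6[ct_noncpg] <- 0.60 / sum(ct_noncpg)
  sbs6[sub == "C>A"] <- sbs6[sub == "C>A"] + 0.20 / 16
  sbs6 <- sbs6 + 0.20 / 96

  sbs20 <- numeric(96)
  sbs20[sub == "T>C"] <- 0.55 / 16
  sbs20[sub == "C>A"] <- sbs20[sub == "C>A"] + 0.25 / 16
  sbs20 <- sbs20 + 0.20 / 96

  # broad like the HRD process, but with enough class/context structure to
  # stay identifiable against the uniform column
  class_w <- c("C>A" = 0.24, "C>G" = 0.08, "C>T" = 0.12,
               "T>A" = 0.20, "T>C" = 0.10, "T>G" = 0.26)
  five_w <- c(A = 0.55, C = 1.70, G = 0.45, T = 1.30)
  three_w <- c(A = 1.35, C = 0.60, G = 0.70, T = 1.35)
  sbs3 <- class_w[sub] * five_w[b5] * three_w[b3] / 16

  flat <- rep(1 / 96, 96)
  m <- cbind(SBS1 = sbs1, SBS3 = unname(sbs3), SBS6 = sbs6,
             SBS20 = sbs20, flat = flat)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- channels
  m
}

# Lawson-Hanson non-negative least squares: min ||Ax - b||, x >= 0.
.nnls <- function(A, b, tol = 1e-10, max_iter = 10 * ncol(A)) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- logical(p)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter * 10L) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive] <- x[passive] > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Fit per-sample signature exposures
#'
#' Forward selection over the signature matrix columns: starting from the
#' empty model, the signature whose addition (with a full non-negative
#' least-squares refit) most reduces the L2 reconstruction error of the
#' normalised spectrum is added, until the improvement falls below `tol`.
#' Weights under `drop_floor` are then zeroed and the survivors rescaled to
#' preserve the pre-drop total.
#'
#' @param spectrum 96-channel counts (named as [trinucleotide_channels()]).
#' @param signature_matrix 96 x k matrix, columns summing to 1.
#' @param drop_floor Weights below this are zeroed, default 0.06.
#' @param tol Stop when the error improvement is below this, default 1e-3.
#' @return List of class `signature_exposures`: weights (named, length k),
#'   error (residual L2 norm of the final weights), n_mutations.
#' @export
fit_exposures <- function(spectrum, signature_matrix = default_signature_matrix(),
                          drop_floor = 0.06, tol = 1e-3) {
  total <- sum(spectrum)
  if (total <= 0) stop("empty spectrum: exposures are undefined")
  if (nrow(signature_matrix) != length(spectrum)) {
    stop("signature matrix rows must match the 96 spectrum channels")
  }
  if (any(abs(colSums(signature_matrix) - 1) > 1e-6)) {
    stop("signature matrix columns must sum to 1")
  }
  p <- as.numeric(spectrum) / total
  k <- ncol(signature_matrix)
  sig_names <- colnames(signature_matrix)
  active <- integer(0)
  err_prev <- sqrt(sum(p^2))
  w_active <- numeric(0)
  repeat {
    cand <- setdiff(seq_len(k), active)
    if (length(cand) == 0L) break
    best <- NULL
    for (j in cand) {
      idx <- c(active, j)
      wj <- .nnls(signature_matrix[, idx, drop = FALSE], p)
      errj <- sqrt(sum((p - signature_matrix[, idx, drop = FALSE] %*% wj)^2))
      if (is.null(best) || errj < best$err) {
        best <- list(idx = idx, w = wj, err = errj)
      }
    }
    if (err_prev - best$err < tol) break
    active <- best$idx
    w_active <- best$w
    err_prev <- best$err
  }
  weights <- stats::setNames(numeric(k), sig_names)
  if (length(active)) weights[active] <- w_active
  pre_total <- sum(weights)
  weights[weights < drop_floor] <- 0
  if (sum(weights) > 0) {
    weights <- weights * pre_total / sum(weights)
  }
  err <- sqrt(sum((p - signature_matrix %*% weights)^2))
  structure(list(weights = weights, error = err, n_mutations = total),
            class = "signature_exposures")
}

#' @export
print.signature_exposures <- function(x, ...) {
  nz <- x$weights[x$weights > 0]
  cat(sprintf("Signature exposures (%d mutations, residual %.4f):\n",
              x$n_mutations, x$error))
  if (length(nz)) {
    print(round(nz, 3))
  } else cat("  (all weights zero)\n")
  invisible(x)
}

#' Is SBS3 the dominant signature?
#'
#' @param exposures A `signature_exposures` object (or named weight vector).
#' @param threshold Inclusive dominance cutoff, default 0.3.
#' @param signature Signature name, default "SBS3".
#' @return Logical flag.
#' @export
is_sbs3_dominant <- function(exposures, threshold = 0.3, signature = "SBS3") {
  w <- if (inherits(exposures, "signature_exposures")) exposures$weights
  else exposures
  if (!signature %in% names(w)) {
    stop(sprintf("signature '%s' not present in the fitted set", signature))
  }
  unname(w[signature] >= threshold)
}

#' Insertion/deletion ratio
#'
#' Insertions are variants whose alt allele is longer than the ref allele;
#' deletions the converse. With zero deletions the insertion count is
#' returned with attribute `denominator_zero = TRUE` and a warning rather
#' than propagating infinity.
#'
#' @param mutations Mutation table with ref and alt columns.
#' @return Numeric ratio with attribute `denominator_zero`.
#' @export
indel_ratio <- function(mutations) {
  if (is.null(mutations) || nrow(mutations) == 0L) {
    out <- 0
    attr(out, "denominator_zero") <- TRUE
    return(out)
  }
  .check_columns(mutations, c("ref", "alt"), "mutation table")
  n_ins <- sum(nchar(mutations$alt) > nchar(mutations$ref))
  n_del <- sum(nchar(mutations$alt) < nchar(mutations$ref))
  if (n_del == 0L) {
    warning("no deletions: indel ratio flagged (denominator zero)")
    out <- as.numeric(n_ins)
    attr(out, "denominator_zero") <- TRUE
    return(out)
  }
  out <- n_ins / n_del
  attr(out, "denominator_zero") <- FALSE
  out
}
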