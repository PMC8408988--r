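# HRDetect-style lasso-logistic deficiency predictor.
#
# The published whole-exome weights are not recoverable, so the model is
# re-trained on cohorts with known deficiency labels. Features default to
# the HRD score total, the exposures of SBS1/SBS3/SBS6/SBS20 and the
# insertion/deletion ratio; the set is configurable.

#' Default HRDetect feature names
#' @return Character vector.
#' @export
hrdetect_features <- function() {
  c("hrd_total", "SBS1", "SBS3", "SBS6", "SBS20", "indel_ratio")
}

#' Train a lasso-logistic deficiency model
#'
#' Features are standardised (centre/scale stored in the model) and an
#' L1-penalised logistic regression is fitted; the penalty is chosen by
#' cross-validated deviance. Fold assignment is derived from `seed`, so a
#' fixed seed gives identical weights.
#'
#' @param features Numeric matrix or data.frame, samples x features.
#' @param labels Logical or 0/1 vector (TRUE = HR-deficient).
#' @param seed Integer seed for the cross-validation folds.
#' @param nfolds Number of CV folds, default 5.
#' @param lambda Penalty rule: "lambda.min" (default) or "lambda.1se".
#' @return List of class `hrdetect_model`: features, weights, intercept,
#'   centre, scale, lambda.
#' @export
train_hrdetect <- function(features, labels, seed = 1L, nfolds = 5L,
                           lambda = c("lambda.min", "lambda.1se")) {
  lambda <- match.arg(lambda)
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("degenerate labels: both classes must be present")
  }
  if (nrow(x) != length(y)) stop("features and labels disagree in length")
  centre <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), length(y)))
  cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = FALSE)
  co <- as.numeric(stats::coef(cv, s = lambda))
  structure(list(features = colnames(x), weights = stats::setNames(co[-1L], colnames(x)),
                 intercept = co[1L], centre = centre, scale = scale_,
                 lambda = unname(cv[[lambda]])),
            class = "hrdetect_model")
}

#' Score samples with an HRDetect-style model
#'
#' `logistic(intercept + sum_f w_f * standardized(f))`; a score of at least
#' 0.7 is conventionally called "HRDetect-high".
#'
#' @param features Numeric matrix/data.frame (samples x features) or a named
#'   vector for a single sample. Feature names must match the model.
#' @param model An `hrdetect_model`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
hrdetect_score <- function(features, model) {
  if (!inherits(model, "hrdetect_model")) stop("not an hrdetect_model")
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  }
  x <- as.matrix(features)
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) {
    stop(sprintf("feature/model mismatch: missing feature(s) %s",
                 paste(miss, collapse = ", ")))
  }
  x <- x[, model$features, drop = FALSE]
  xs <- sweep(sweep(x, 2, model$centre), 2, model$scale, "/")
  eta <- model$intercept + drop(xs %*% model$weights)
  stats::plogis(eta)
}

#' Serialize an HRDetect model to JSON
#' @param model An `hrdetect_model`.
#' @param path Output file path.
#' @export
write_hrdetect_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
}

#' Read an HRDetect model from JSON
#' @param path JSON file written by [write_hrdetect_model()].
#' @return An `hrdetect_model`.
#' @export
read_hrdetect_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$weights <- stats::setNames(as.numeric(m$weights), m$features)
  m$centre <- stats::setNames(as.numeric(m$centre), m$features)
  m$scale <- stats::setNames(as.numeric(m$scale), m$features)
  structure(m, class = "hrdetect_model")
}

#' Assemble the HRDetect feature table for a cohort
#'
#' Computes, per sample, the HRD score total, fitted signature exposures and
#' the insertion/deletion ratio.
#'
#' @param segments Cohort segment table (with `sample`).
#' @param mutations Cohort mutation table (with `sample`).
#' @param genome Genome annotation.
#' @param signature_matrix Signature matrix for exposure fitting.
#' @return data.frame: sample plus the [hrdetect_features()] columns.
#' @export
hrdetect_feature_table <- function(segments, mutations, genome,
                                   signature_matrix = default_signature_matrix()) {
  scores <- hrd_score_cohort(segments, genome)
  samples <- scores$sample
  sig_names <- colnames(signature_matrix)
  rows <- lapply(samples, function(sm) {
    mut <- mutations[mutations$sample == sm, , drop = FALSE]
    spec <- build_spectrum(mut)
    expo <- if (sum(spec) > 0)
      fit_exposures(spec, signature_matrix)$weights
    else stats::setNames(numeric(length(sig_names)), sig_names)
    ir <- suppressWarnings(indel_ratio(mut))
    out <- data.frame(sample = sm, hrd_total = scores$total[scores$sample == sm],
                      indel_ratio = as.numeric(ir))
    for (s in setdiff(sig_names, "flat")) out[[s]] <- unname(expo[s])
    out
  })
  do.call(rbind, rows)
}
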