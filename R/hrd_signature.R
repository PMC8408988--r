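# The transcriptional HRD signature: differential-expression screen,
# univariate Cox on the failure-free interval, lasso reduction, and the
# PS / HRDPS prognostic-score equations
#
#   PS_i     = sum_j Exp_ij / HR_j          (separately for up and down factors)
#   HRDPS_i  = PS_{i,up} - PS_{i,down}
#
# where HR_j is the univariate Cox hazard ratio of factor j on FFI and
# Exp_ij the log-transformed expression. Upregulated factors must be
# protective (HR < 1) and downregulated factors risk factors (HR > 1);
# candidates violating that consistency are excluded.

#' Univariate Cox screen of candidate genes on a survival endpoint
#'
#' Fits, per gene, a proportional-hazards model of the endpoint on that
#' gene's (continuous) log expression. Genes with no expression variance or
#' failed fits are dropped with a warning.
#'
#' @param log_expression Genes x samples matrix.
#' @param time,event Survival endpoint per sample (months, 0/1).
#' @param genes Candidate genes, default all rows.
#' @param min_events Minimum number of events required, default 10.
#' @return data.frame: gene, coef, hazard_ratio, p.
#' @export
cox_screen <- function(log_expression, time, event,
                       genes = rownames(log_expression), min_events = 10L) {
  if (sum(event) < min_events) {
    stop(sprintf("need at least %d events for the Cox screen", min_events))
  }
  genes <- intersect(genes, rownames(log_expression))
  surv <- survival::Surv(time, event)
  rows <- lapply(genes, function(g) {
    x <- log_expression[g, ]
    if (stats::sd(x) == 0) return(NULL)
    fit <- tryCatch(
      survival::coxph(surv ~ x, ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit)) ||
        abs(stats::coef(fit)) > 20) return(NULL)
    s <- summary(fit)
    data.frame(gene = g, coef = unname(stats::coef(fit)),
               hazard_ratio = unname(exp(stats::coef(fit))),
               p = s$coefficients[1, "Pr(>|z|)"])
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(sprintf("%d gene(s) dropped from the Cox screen (constant or non-converged)",
                    dropped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) data.frame(gene = character(), coef = numeric(),
                               hazard_ratio = numeric(), p = numeric())
  else out
}

#' Reduce candidate factors to an HRD expression signature by lasso
#'
#' L1-penalised logistic regression of HRD status on the candidates'
#' expression (penalty by cross-validated deviance, 1-SE rule by default);
#' the surviving genes are joined with their univariate Cox hazard ratios
#' and their DE direction (up iff log2FC > 0). Factors violating the
#' direction/HR consistency (up must have HR < 1, down HR > 1) are excluded
#' with a warning. Duplicated expression rows are reduced to their first
#' occurrence before the fit. An optional L1-Cox alternative regresses the
#' FFI endpoint instead.
#'
#' @param log_expression Genes x samples matrix (candidates as rows).
#' @param labels HRD status per sample (logical or "HR-deficient"/...);
#'   used when `target = "hrd"`.
#' @param de DE table from [differential_expression()] (gene, log2fc).
#' @param cox Cox screen table from [cox_screen()] (gene, hazard_ratio).
#' @param target "hrd" (lasso logistic on HRD status, default) or "ffi"
#'   (L1 Cox on the endpoint supplied via `time`/`event`).
#' @param time,event Endpoint, needed for `target = "ffi"`.
#' @param seed Fold seed, default 1.
#' @param nfolds CV folds, default 10.
#' @param lambda "lambda.1se" (default) or "lambda.min".
#' @return data.frame of class `hrd_signature`: gene, direction ("up"/"down"),
#'   hazard_ratio.
#' @export
lasso_reduce <- function(log_expression, labels, de, cox,
                         target = c("hrd", "ffi"), time = NULL, event = NULL,
                         seed = 1L, nfolds = 10L,
                         lambda = c("lambda.1se", "lambda.min")) {
  target <- match.arg(target)
  lambda <- match.arg(lambda)
  if (nrow(log_expression) < 2L) stop("need at least 2 candidate genes")
  # redundancy removal: identical expression rows keep the first occurrence
  dup <- duplicated(apply(log_expression, 1, paste, collapse = "\r"))
  log_expression <- log_expression[!dup, , drop = FALSE]
  x <- t(log_expression)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  n <- nrow(x)
  foldid <- sample(rep_len(seq_len(nfolds), n))
  if (target == "hrd") {
    y <- if (is.logical(labels)) as.integer(labels)
    else as.integer(as.character(labels) == "HR-deficient")
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            foldid = foldid)
    co <- stats::coef(cv, s = lambda)
    nz <- rownames(co)[-1L][as.numeric(co)[-1L] != 0]
  } else {
    if (is.null(time) || is.null(event)) {
      stop("target = 'ffi' needs time and event")
    }
    y <- survival::Surv(time, event)
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid)
    co <- stats::coef(cv, s = lambda)
    nz <- rownames(co)[as.numeric(co) != 0]
  }
  if (length(nz) == 0L) {
    stop("lasso shrank all coefficients to zero; try lambda = 'lambda.min' ",
         "or a weaker penalty")
  }
  tab <- merge(data.frame(gene = nz),
               merge(de[, c("gene", "log2fc")],
                     cox[, c("gene", "hazard_ratio")], by = "gene"),
               by = "gene")
  tab$direction <- ifelse(tab$log2fc > 0, "up", "down")
  consistent <- (tab$direction == "up" & tab$hazard_ratio < 1) |
    (tab$direction == "down" & tab$hazard_ratio > 1)
  if (any(!consistent)) {
    warning(sprintf("excluding %d factor(s) violating direction/HR consistency: %s",
                    sum(!consistent),
                    paste(tab$gene[!consistent], collapse = ", ")))
    tab <- tab[consistent, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no factor survived the consistency filter")
  out <- tab[order(tab$gene), c("gene", "direction", "hazard_ratio")]
  rownames(out) <- NULL
  class(out) <- c("hrd_signature", "data.frame")
  out
}

#' Validate an HRD expression signature table
#' @param signature data.frame: gene, direction, hazard_ratio.
#' @return The signature, invisibly.
#' @keywords internal
validate_signature <- function(signature) {
  .check_columns(signature, c("gene", "direction", "hazard_ratio"),
                 "HRD signature")
  if (any(signature$hazard_ratio <= 0)) {
    stop("invalid signature: hazard ratios must be positive")
  }
  if (!all(signature$direction %in% c("up", "down"))) {
    stop("signature directions must be 'up' or 'down'")
  }
  invisible(signature)
}

#' PS and HRDPS prognostic scores
#'
#' For each sample i, `PS_up = sum over up factors of Exp_ij / HR_j`,
#' `PS_down` likewise over down factors, and `HRDPS = PS_up - PS_down`.
#' `Exp` is log-transformed expression.
#'
#' @param log_expression Genes x samples matrix containing every signature
#'   gene (missing genes are an error listing them).
#' @param signature An `hrd_signature` (gene, direction, hazard_ratio).
#' @return data.frame: sample, ps_up, ps_down, hrdps.
#' @export
prognostic_score <- function(log_expression, signature) {
  validate_signature(signature)
  miss <- setdiff(signature$gene, rownames(log_expression))
  if (length(miss)) {
    stop(sprintf("signature gene(s) missing from the expression matrix: %s",
                 paste(miss, collapse = ", ")))
  }
  ps_part <- function(dir) {
    s <- signature[signature$direction == dir, , drop = FALSE]
    if (nrow(s) == 0L) return(rep(0, ncol(log_expression)))
    e <- log_expression[s$gene, , drop = FALSE]
    colSums(e / s$hazard_ratio)
  }
  ps_up <- ps_part("up")
  ps_down <- ps_part("down")
  data.frame(sample = colnames(log_expression), ps_up = unname(ps_up),
             ps_down = unname(ps_down), hrdps = unname(ps_up - ps_down),
             row.names = NULL)
}

#' HRDPS positivity call
#'
#' Default rule: strictly above the cohort median; a quantile rule shares
#' the immune score's positivity code.
#'
#' @param hrdps Numeric HRDPS scores.
#' @param rule "median" (default) or "quantile".
#' @param quantile Quantile when `rule = "quantile"`.
#' @return Logical vector.
#' @export
call_hrdps_positive <- function(hrdps, rule = c("median", "quantile"),
                                quantile = 0.75) {
  rule <- match.arg(rule)
  if (length(hrdps) < 4L) stop("need at least 4 samples")
  if (rule == "median") hrdps > stats::median(hrdps)
  else call_quantile_positive(hrdps, quantile)
}

#' Empirical ROC curve by threshold sweep
#'
#' @param scores Numeric risk scores (higher = predicted positive).
#' @param labels Logical/0-1 true labels.
#' @return data.frame (threshold, tpr, fpr) sorted for plotting, with the
#'   trapezoid AUC as attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present for a ROC curve")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
  attr(out, "auc") <- auc
  out
}

#' Evaluate the expression signature as an HRD predictor
#'
#' Fits a lasso-logistic model of HRD status on the signature genes'
#' expression and reports the ROC curve and AUC of its predicted
#' probabilities (in-cohort). Alternatively pass precomputed `scores` to
#' evaluate any risk score.
#'
#' @param log_expression Genes x samples matrix.
#' @param labels True HRD status per sample.
#' @param signature An `hrd_signature`; ignored when `scores` given.
#' @param scores Optional precomputed risk scores.
#' @param seed Fold seed for the internal lasso fit.
#' @return List: roc (data.frame), auc, scores.
#' @export
evaluate_signature_as_hrd_predictor <- function(log_expression, labels,
                                                signature = NULL,
                                                scores = NULL, seed = 1L) {
  y <- if (is.logical(labels)) labels
  else as.character(labels) == "HR-deficient"
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(scores)) {
    validate_signature(signature)
    x <- t(log_expression[signature$gene, , drop = FALSE])
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(5L), length(y)))
    cv <- glmnet::cv.glmnet(x, as.integer(y), family = "binomial", alpha = 1,
                            foldid = foldid)
    scores <- as.numeric(stats::predict(cv, newx = x, s = "lambda.min",
                                        type = "response"))
  }
  roc <- roc_curve(scores, y)
  list(roc = roc, auc = attr(roc, "auc"), scores = scores)
}

#' Write an HRD signature as TSV and/or JSON
#' @param signature An `hrd_signature`.
#' @param path Output path; format chosen by extension (.tsv or .json).
#' @export
write_signature <- function(signature, path) {
  validate_signature(signature)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(signature), path, auto_unbox = FALSE,
                         digits = NA)
  } else {
    utils::write.table(as.data.frame(signature), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an HRD signature written by [write_signature()]
#' @param path TSV or JSON path.
#' @return An `hrd_signature`.
#' @export
read_signature <- function(path) {
  sig <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  validate_signature(sig)
  class(sig) <- c("hrd_signature", "data.frame")
  sig
}
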