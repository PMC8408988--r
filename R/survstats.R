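# Survival and association statistics for the cohort analyses:
# Kaplan-Meier / log-rank, adjusted Cox models (Efron ties), nested-model
# likelihood-ratio comparison, time-fixed ROC at a survival horizon,
# Fisher's exact test, and Wilcoxon / Kruskal-Wallis with BH correction and
# a permutation variant. Tests are two-sided by default.

#' Kaplan-Meier curves and log-rank comparison
#'
#' @param time,event Survival endpoint (months, 0/1).
#' @param group Group label per sample (>= 2 groups).
#' @param at Optional times (months) at which to report per-group survival
#'   probabilities, e.g. 60 for the 5-year rate.
#' @return List: fit (survfit), p (log-rank), chisq, and `survival_at`
#'   (groups x times matrix) when `at` is given.
#' @export
km_logrank <- function(time, event, group, at = NULL) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank comparison needs at least 2 groups")
  }
  if (sum(event) < 1L) stop("no events observed")
  df <- data.frame(time = time, event = event, group = droplevels(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  out <- list(fit = fit, chisq = unname(sd$chisq), p = p)
  if (!is.null(at)) {
    sm <- summary(fit, times = at, extend = TRUE)
    mat <- matrix(sm$surv, nrow = nlevels(df$group), byrow = TRUE,
                  dimnames = list(levels(df$group), paste0("t", at)))
    out$survival_at <- mat
  }
  out
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' @param time,event Endpoint.
#' @param covariates data.frame of covariates (model uses every column).
#' @return List of class `cox_fit`: table (term, coef, hazard_ratio,
#'   ci_lower, ci_upper, p), loglik, n, events, model.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (sum(event) < ncol(covariates) + 5L) {
    stop("too few events for the requested covariates")
  }
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w))
      }
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    })
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hazard_ratio = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab, loglik = fit$loglik[2L], df = length(stats::coef(fit)),
                 n = s$n, events = s$nevent, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model: n = %d, events = %d, loglik = %.2f\n",
              x$n, x$events, x$loglik))
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], signif, 3)
  print(tab)
  invisible(x)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' @param nested,full `cox_fit` objects on the same data; the nested model's
#'   terms must be a subset of the full model's.
#' @return List: statistic (2 * delta log-likelihood), df, p.
#' @export
lr_test <- function(nested, full) {
  if (!inherits(nested, "cox_fit") || !inherits(full, "cox_fit")) {
    stop("lr_test expects two cox_fit objects")
  }
  if (nested$n != full$n || nested$events != full$events) {
    stop("models must be fitted on the same data")
  }
  nested_terms <- nested$table$term
  if (!all(nested_terms %in% full$table$term)) {
    stop("models are not nested: nested terms must be a subset of the full model")
  }
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  df <- full$df - nested$df
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Time-fixed ROC AUC for a survival horizon
#'
#' Cases are samples with an event at or before the horizon; controls are
#' samples followed event-free beyond it. Samples censored before the
#' horizon are excluded. The AUC is the Mann-Whitney statistic of the risk
#' scores (ties count 1/2).
#'
#' @param scores Risk scores (higher = higher predicted event risk).
#' @param time,event Endpoint.
#' @param horizon Months, default 60 (5 years).
#' @return List: auc, n_cases, n_controls, n_excluded.
#' @export
roc_at_time <- function(scores, time, event, horizon = 60) {
  case <- time <= horizon & event == 1
  control <- time > horizon
  excluded <- !(case | control)
  if (!any(case) || !any(control)) {
    stop("need at least one case and one control at the horizon")
  }
  sc <- scores[case]; sn <- scores[control]
  r <- rank(c(sc, sn))
  auc <- (sum(r[seq_along(sc)]) - length(sc) * (length(sc) + 1) / 2) /
    (length(sc) * length(sn))
  list(auc = unname(auc), n_cases = sum(case), n_controls = sum(control),
       n_excluded = sum(excluded))
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Conditional hypergeometric test; the two-sided p sums outcomes with
#' probability at most that observed. Both one-sided variants are reported
#' alongside, since published tables do not always state sidedness.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return List: odds_ratio (conditional MLE), p_two_sided, p_greater,
#'   p_less.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("expected a 2 x 2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  two <- stats::fisher.test(table, alternative = "two.sided")
  list(odds_ratio = unname(two$estimate),
       p_two_sided = two$p.value,
       p_greater = stats::fisher.test(table, alternative = "greater")$p.value,
       p_less = stats::fisher.test(table, alternative = "less")$p.value)
}

# two-sided rank-sum statistic used by the permutation variant
.ranksum_stat <- function(r1, n1, n2) {
  w <- sum(r1) - n1 * (n1 + 1) / 2
  abs(w - n1 * n2 / 2)
}

#' Two-group or multi-group nonparametric comparison
#'
#' Wilcoxon rank-sum (normal approximation with continuity correction) or
#' Kruskal-Wallis. With `permutations > 0` the p-value is the add-one
#' permutation estimate `(1 + #permuted >= observed) / (1 + permutations)`
#' of the two-sided statistic. `values` may be a feature x sample matrix;
#' BH correction across features is applied when `fdr = TRUE`.
#'
#' @param values Numeric vector, or matrix with samples as columns.
#' @param groups Group label per sample.
#' @param method "wilcoxon" (2 groups) or "kruskal".
#' @param fdr Add a BH-adjusted column across features, default FALSE.
#' @param permutations Number of label permutations (0 = analytic p).
#' @param seed Seed for the permutation draw.
#' @return data.frame with p (and fdr), one row per feature.
#' @export
group_compare <- function(values, groups, method = c("wilcoxon", "kruskal"),
                          fdr = FALSE, permutations = 0L, seed = 1L) {
  method <- match.arg(method)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) stop("need at least 2 samples per group")
  if (method == "wilcoxon" && nlevels(groups) != 2L) {
    stop("wilcoxon requires exactly 2 groups")
  }
  one_feature <- function(x) {
    if (stats::sd(x) == 0) {
      warning("constant values: p set to 1")
      return(1)
    }
    if (permutations > 0L) {
      if (method != "wilcoxon") {
        stop("permutation p implemented for the wilcoxon method")
      }
      g1 <- groups == levels(groups)[1L]
      n1 <- sum(g1); n2 <- sum(!g1)
      r <- rank(x)
      obs <- .ranksum_stat(r[g1], n1, n2)
      perm <- vapply(seq_len(permutations), function(i) {
        idx <- sample.int(length(x), n1)
        .ranksum_stat(r[idx], n1, n2)
      }, numeric(1))
      return((1 + sum(perm >= obs)) / (1 + permutations))
    }
    if (method == "wilcoxon") {
      stats::wilcox.test(x ~ groups, exact = FALSE, correct = TRUE)$p.value
    } else {
      stats::kruskal.test(x, groups)$p.value
    }
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  p <- apply(values, 1, one_feature)
  out <- data.frame(feature = if (is.null(rownames(values)))
    seq_len(nrow(values)) else rownames(values), p = p, row.names = NULL)
  if (fdr) out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}
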