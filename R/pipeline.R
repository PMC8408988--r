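# Cohort assembly and end-to-end runs: failure-free-interval derivation
# from treatment records, ACT-response labelling, the combined
# HRD-or-immune responder classifier, and the discovery/validation drivers.

#' Derive the failure-free interval from a treatment record
#'
#' Time runs from the end of ACT treatment to the earliest of tumour
#' progression/recurrence or death (event = 1), otherwise to the last
#' follow-up (event = 0). Months are days / 30.44.
#'
#' @param therapy_end,progression_date,death_date,last_followup Date
#'   vectors (progression/death may be `NA`).
#' @param sample Sample IDs for error messages.
#' @return data.frame: sample, time (months), event.
#' @export
derive_ffi <- function(therapy_end, progression_date = NULL,
                       death_date = NULL, last_followup = NULL,
                       sample = seq_along(therapy_end)) {
  n <- length(therapy_end)
  if (any(is.na(therapy_end))) stop("therapy end date is required")
  to_date <- function(x) if (is.null(x)) rep(as.Date(NA), n) else as.Date(x)
  prog <- to_date(progression_date)
  death <- to_date(death_date)
  fup <- to_date(last_followup)
  event_date <- pmin(prog, death, na.rm = TRUE)
  event <- as.integer(!is.na(event_date))
  end_date <- ifelse(event == 1L, event_date, fup)
  class(end_date) <- "Date"
  if (any(event == 0L & is.na(fup))) {
    stop("last follow-up date required for samples without an event")
  }
  days <- as.numeric(end_date - as.Date(therapy_end))
  if (any(days < 0)) {
    bad <- sample[days < 0]
    stop(sprintf("event precedes therapy end for sample(s): %s",
                 paste(bad, collapse = ", ")))
  }
  data.frame(sample = sample, time = days / DAYS_PER_MONTH, event = event)
}

#' Label ACT response
#'
#' A recorded best response takes precedence: complete response is
#' sensitive; progressive or stable disease is resistant. Otherwise the
#' FFI-median rule applies: strictly above the cohort median is sensitive,
#' at or below is resistant. Samples with neither a usable response
#' category nor an FFI are "unassignable".
#'
#' @param response Best response per sample: CR/PR/SD/PD/unknown (NA
#'   allowed).
#' @param ffi_months FFI per sample (NA allowed).
#' @return Character vector: "sensitive"/"resistant"/"unassignable".
#' @export
label_act_response <- function(response, ffi_months) {
  stopifnot(length(response) == length(ffi_months))
  response <- ifelse(is.na(response), "unknown", as.character(response))
  med <- stats::median(ffi_months, na.rm = TRUE)
  out <- rep("unassignable", length(response))
  out[response == "CR"] <- "sensitive"
  out[response %in% c("PD", "SD")] <- "resistant"
  undecided <- !(response %in% c("CR", "PD", "SD"))
  has_ffi <- undecided & !is.na(ffi_months)
  out[has_ffi & ffi_months > med] <- "sensitive"
  out[has_ffi & ffi_months <= med] <- "resistant"
  out
}

#' Combined HRD / immune-activation status
#'
#' Binary rule: positive iff HRD-positive (genome mode: HR-deficient;
#' transcriptome mode: HRDPS-positive) OR immune-score-positive. Also
#' returns the four-group cross-classification used for reporting.
#'
#' @param hrd_positive Logical per sample (HR status or HRDPS call).
#' @param is_positive Logical per sample (immune-score call).
#' @return data.frame: combined_binary ("positive"/"negative"/
#'   "unassignable"), combined_four ("both+", "HRD-only+", "IS-only+",
#'   "both-").
#' @export
combined_status <- function(hrd_positive, is_positive) {
  stopifnot(length(hrd_positive) == length(is_positive))
  four <- ifelse(hrd_positive & is_positive, "both+",
                 ifelse(hrd_positive, "HRD-only+",
                        ifelse(is_positive, "IS-only+", "both-")))
  binary <- ifelse(hrd_positive | is_positive, "positive", "negative")
  four[is.na(four)] <- "unassignable"
  binary[is.na(binary)] <- "unassignable"
  data.frame(combined_binary = binary, combined_four = four)
}

#' Run the discovery analysis end-to-end on a cohort bundle
#'
#' Scars -> HR status -> mutational signatures -> immune score -> response
#' labels -> survival statistics. Deterministic given the bundle.
#'
#' @param bundle An `omics_bundle` (from [generate_cohort()] or assembled
#'   from files with the same element names).
#' @param hrd_threshold HRD-score deficiency cutoff, default 42.
#' @param sbs3_threshold SBS3 dominance cutoff, default 0.3.
#' @param is_quantile Immune-score positivity quantile, default 0.75.
#' @param horizon ROC horizon in months, default 60.
#' @return List of class `discovery_report`: labels (per-sample calls),
#'   scars, exposures, stats (km, cox, lr_test, roc, fisher).
#' @export
run_discovery <- function(bundle, hrd_threshold = 42, sbs3_threshold = 0.3,
                          is_quantile = 0.75, horizon = 60) {
  cl <- bundle$clinical
  samples <- cl$sample

  scars <- hrd_score_cohort(bundle$segments, bundle$genome)
  scars <- scars[match(samples, scars$sample), ]
  mut_by <- split(bundle$mutations,
                  factor(bundle$mutations$sample, levels = samples))
  hr_status <- vapply(samples, function(sm) {
    classify_hr_status(scars$total[scars$sample == sm], mut_by[[sm]],
                       threshold = hrd_threshold)$status
  }, character(1), USE.NAMES = FALSE)

  sigs <- default_signature_matrix()
  expo <- t(vapply(samples, function(sm) {
    spec <- build_spectrum(mut_by[[sm]])
    if (sum(spec) == 0) return(stats::setNames(numeric(ncol(sigs)),
                                               colnames(sigs)))
    fit_exposures(spec, sigs)$weights
  }, numeric(ncol(sigs))))
  sbs3_dominant <- expo[, "SBS3"] >= sbs3_threshold

  tmb <- vapply(samples, function(sm) compute_tmb(mut_by[[sm]]),
                integer(1), USE.NAMES = FALSE)

  brca1_meth <- call_brca1_methylation(bundle$methylation)
  brca1_meth <- brca1_meth[match(samples, brca1_meth$sample), ]

  activities <- single_sample_activity(bundle$expr_log, bundle$gene_sets)
  is_score <- immune_score_pathway(activities, quantile = is_quantile)
  is_score <- is_score[match(samples, is_score$sample), ]

  act_response <- label_act_response(cl$response, cl$ffi_months)
  subtype <- emulate_subtype_structure(hr_status, act_response)
  comb <- combined_status(hr_status == "HR-deficient", is_score$is_positive)

  labels <- data.frame(sample = samples, hr_status = hr_status,
                       hrd_total = scars$total,
                       sbs3_dominant = sbs3_dominant, tmb = tmb,
                       brca1_meth_silenced = brca1_meth$silenced,
                       is_score = is_score$score,
                       is_positive = is_score$is_positive,
                       act_response = act_response, subtype = subtype,
                       combined_binary = comb$combined_binary,
                       combined_four = comb$combined_four,
                       row.names = NULL)

  hrd_flag <- hr_status == "HR-deficient"
  km <- km_logrank(cl$ffi_months, cl$ffi_event, hr_status, at = horizon)
  covars <- data.frame(hrd = as.integer(hrd_flag), age = cl$age,
                       stage = factor(cl$stage))
  cox <- cox_fit(cl$ffi_months, cl$ffi_event, covars)
  cox_clin <- cox_fit(cl$ffi_months, cl$ffi_event,
                      covars[, c("age", "stage"), drop = FALSE])
  cox_comb <- cox_fit(cl$ffi_months, cl$ffi_event,
                      cbind(covars[, c("age", "stage"), drop = FALSE],
                            combined = as.integer(comb$combined_binary == "positive")))
  lrt <- lr_test(cox_clin, cox_comb)
  roc_hrd <- roc_at_time(as.numeric(!hrd_flag), cl$ffi_months, cl$ffi_event,
                         horizon)
  roc_comb <- roc_at_time(as.numeric(comb$combined_binary != "positive"),
                          cl$ffi_months, cl$ffi_event, horizon)
  assigned <- act_response != "unassignable"
  fisher_tab <- matrix(c(
    sum(hrd_flag & act_response == "sensitive"),
    sum(hrd_flag & act_response == "resistant"),
    sum(!hrd_flag & act_response == "sensitive"),
    sum(!hrd_flag & act_response == "resistant")), nrow = 2, byrow = TRUE,
    dimnames = list(c("HR-deficient", "HR-proficient"),
                    c("sensitive", "resistant")))
  fisher <- fisher_exact(fisher_tab)

  structure(list(labels = labels, scars = scars, exposures = expo,
                 stats = list(
                   km_ffi_by_hrd = list(p = km$p, chisq = km$chisq,
                                        survival_at = km$survival_at),
                   cox_ffi = cox$table,
                   lr_test_combined = lrt,
                   roc_hrd = roc_hrd, roc_combined = roc_comb,
                   fisher_hrd_response = c(list(table = fisher_tab), fisher),
                   n_unassigned_response = sum(!assigned))),
            class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  tab <- table(x$labels$hr_status)
  cat("Discovery run:", sum(tab), "samples\n")
  print(tab)
  hr_row <- x$stats$cox_ffi[x$stats$cox_ffi$term == "hrd", ]
  cat(sprintf("FFI Cox HR(HRD) = %.3f [%.3f, %.3f], p = %.3g\n",
              hr_row$hazard_ratio, hr_row$ci_lower, hr_row$ci_upper, hr_row$p))
  cat(sprintf("Log-rank p (FFI by HR status) = %.3g\n", x$stats$km_ffi_by_hrd$p))
  cat(sprintf("5-y ROC AUC: combined %.3f vs HRD alone %.3f\n",
              x$stats$roc_combined$auc, x$stats$roc_hrd$auc))
  invisible(x)
}

#' Run the validation analysis on an expression cohort
#'
#' Scores samples with an HRD expression signature (HRDPS), computes the
#' immune score, forms the transcriptome-mode combined status, and compares
#' survival across the four combined groups. When a response column with
#' pCR labels is present, the pCR-rate table by combined status with a
#' Fisher test is added.
#'
#' @param expr_log Genes x samples log-expression matrix.
#' @param clinical data.frame: sample, time, event (and optionally `pcr`,
#'   logical).
#' @param signature An `hrd_signature`.
#' @param gene_sets Immune gene sets, default the packaged synthetic sets.
#' @param is_quantile Immune positivity quantile, default 0.75.
#' @param hrdps_rule HRDPS positivity rule, default "median".
#' @return List of class `validation_report`: scores, labels, stats.
#' @export
run_validation <- function(expr_log, clinical, signature,
                           gene_sets = default_immune_sets(),
                           is_quantile = 0.75, hrdps_rule = "median") {
  stopifnot(all(c("sample", "time", "event") %in% names(clinical)))
  expr_log <- expr_log[, clinical$sample, drop = FALSE]
  ps <- prognostic_score(expr_log, signature)
  hrdps_pos <- call_hrdps_positive(ps$hrdps, rule = hrdps_rule)
  activities <- single_sample_activity(expr_log, gene_sets)
  is_score <- immune_score_pathway(activities, quantile = is_quantile)
  is_score <- is_score[match(clinical$sample, is_score$sample), ]
  comb <- combined_status(hrdps_pos, is_score$is_positive)
  km <- km_logrank(clinical$time, clinical$event, comb$combined_four, at = 60)
  out <- list(
    scores = data.frame(sample = clinical$sample, hrdps = ps$hrdps,
                        hrdps_positive = hrdps_pos,
                        is_score = is_score$score,
                        is_positive = is_score$is_positive,
                        combined_binary = comb$combined_binary,
                        combined_four = comb$combined_four),
    stats = list(km_four_group = list(p = km$p, chisq = km$chisq,
                                      survival_at = km$survival_at),
                 group_sizes = table(comb$combined_four)))
  if ("pcr" %in% names(clinical)) {
    tab <- table(combined = comb$combined_binary,
                 pcr = factor(clinical$pcr, levels = c(TRUE, FALSE),
                              labels = c("pCR", "RD")))
    out$stats$pcr_table <- tab
    if (all(dim(tab) == c(2L, 2L))) {
      out$stats$pcr_fisher <- fisher_exact(unclass(tab))
    }
  }
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation run:", nrow(x$scores), "samples\n")
  print(x$stats$group_sizes)
  cat(sprintf("Four-group log-rank p = %.3g\n", x$stats$km_four_group$p))
  invisible(x)
}

#' Write a discovery or validation report as JSON
#'
#' Keys keep their construction order, so reports from the same inputs are
#' byte-identical and diffable.
#'
#' @param report A `discovery_report` or `validation_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "table")) return(as.list(stats::setNames(as.numeric(x),
                                                             names(x))))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = 10, dataframe = "columns", force = TRUE)
  invisible(path)
}
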