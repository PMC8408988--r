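# Derivation of the HRD expression signature and the PS/HRDPS equations.

test_that("the univariate Cox screen recovers planted gene effects", {
  set.seed(71)
  n <- 500
  x_null <- stats::rnorm(n)
  x_eff <- stats::rnorm(n)
  h <- 0.02 * exp(-0.7 * x_eff)
  time <- stats::rexp(n, h)
  event <- rep(1L, n)
  expr <- rbind(null_gene = x_null, eff_gene = x_eff, const_gene = rep(1, n))
  colnames(expr) <- sprintf("s%03d", 1:n)
  expect_warning(res <- cox_screen(expr, time, event), "dropped")
  expect_false("const_gene" %in% res$gene)
  # null gene: HR near 1
  expect_gt(res$hazard_ratio[res$gene == "null_gene"], 0.85)
  expect_lt(res$hazard_ratio[res$gene == "null_gene"], 1.18)
  # planted log-HR -0.7 -> HR ~0.5
  expect_gt(res$hazard_ratio[res$gene == "eff_gene"], 0.4)
  expect_lt(res$hazard_ratio[res$gene == "eff_gene"], 0.62)
  expect_error(cox_screen(expr, time, rep(0L, n)), "events")
})

test_that("null-gene Cox HRs stay in [0.85, 1.18] in most replicates", {
  set.seed(72)
  inside <- replicate(40, {
    n <- 500
    x <- stats::rnorm(n)
    time <- stats::rexp(n, 0.02)
    expr <- rbind(g1 = x, g2 = stats::rnorm(n))
    colnames(expr) <- paste0("s", 1:n)
    hr <- cox_screen(expr, time, rep(1L, n))$hazard_ratio[1]
    hr > 0.85 && hr < 1.18
  })
  expect_gte(mean(inside), 0.9)
})

test_that("lasso reduction recovers informative genes and drops duplicates", {
  set.seed(73)
  n <- 300
  hrd <- stats::runif(n) < 0.5
  n_info <- 15; n_noise <- 200
  info <- matrix(stats::rnorm(n_info * n, 0, 1), nrow = n_info)
  info <- info + outer(rep(c(1.2, -1.2), length.out = n_info),
                       as.numeric(hrd))
  noise <- matrix(stats::rnorm(n_noise * n), nrow = n_noise)
  expr <- rbind(info, noise)
  rownames(expr) <- c(sprintf("INFO%02d", 1:n_info),
                      sprintf("NOISE%03d", 1:n_noise))
  colnames(expr) <- sprintf("s%03d", 1:n)
  # matching DE and Cox tables: direction from the planted shift, and HRs
  # consistent with it (up genes protective)
  dirs <- rep(c(1, -1), length.out = n_info)
  de <- data.frame(gene = rownames(expr),
                   log2fc = c(dirs * 2, stats::rnorm(n_noise, 0, 0.1)))
  cox <- data.frame(gene = rownames(expr),
                    hazard_ratio = c(ifelse(dirs > 0, 0.5, 2.0),
                                     stats::runif(n_noise, 0.9, 1.1)))
  # noise inclusions may trip the consistency filter, which warns by design
  sig <- suppressWarnings(lasso_reduce(expr, hrd, de, cox, seed = 7))
  got <- sum(grepl("^INFO", sig$gene))
  expect_gte(got, 12)
  expect_lte(sum(grepl("^NOISE", sig$gene)), 5)
  expect_true(all(sig$hazard_ratio[sig$direction == "up"] < 1))
  expect_true(all(sig$hazard_ratio[sig$direction == "down"] > 1))

  # determinism
  sig2 <- suppressWarnings(lasso_reduce(expr, hrd, de, cox, seed = 7))
  expect_identical(sig$gene, sig2$gene)

  # duplicated expression rows: at most one retained
  expr_dup <- rbind(expr, INFODUP = expr["INFO01", ])
  de2 <- rbind(de, data.frame(gene = "INFODUP", log2fc = de$log2fc[1]))
  cox2 <- rbind(cox, data.frame(gene = "INFODUP",
                                hazard_ratio = cox$hazard_ratio[1]))
  sig3 <- suppressWarnings(lasso_reduce(expr_dup, hrd, de2, cox2, seed = 7))
  expect_lte(sum(sig3$gene %in% c("INFO01", "INFODUP")), 1)

  # inconsistent direction/HR pairs are excluded with a warning
  cox_bad <- cox
  cox_bad$hazard_ratio[cox_bad$gene == "INFO01"] <- 2.0  # up gene, HR > 1
  expect_warning(sig4 <- lasso_reduce(expr, hrd, de, cox_bad, seed = 7),
                 "consistency")
  expect_false("INFO01" %in% sig4$gene)
})

test_that("PS and HRDPS follow the printed equations exactly", {
  sig <- data.frame(gene = c("up1", "down1"), direction = c("up", "down"),
                    hazard_ratio = c(0.5, 2))
  class(sig) <- c("hrd_signature", "data.frame")
  expr <- matrix(c(2, 1), nrow = 2, dimnames = list(c("up1", "down1"), "s1"))
  ps <- prognostic_score(expr, sig)
  expect_identical(ps$ps_up, 4)     # 2 / 0.5
  expect_identical(ps$ps_down, 0.5) # 1 / 2
  expect_identical(ps$hrdps, 3.5)

  # empty down list: HRDPS equals PS_up
  up_only <- sig[1, ]
  class(up_only) <- c("hrd_signature", "data.frame")
  ps_up <- prognostic_score(expr, up_only)
  expect_identical(ps_up$hrdps, ps_up$ps_up)

  # homogeneity: doubling expression doubles HRDPS
  set.seed(74)
  expr_many <- matrix(stats::rnorm(20, 5), nrow = 2,
                      dimnames = list(c("up1", "down1"), paste0("s", 1:10)))
  p1 <- prognostic_score(expr_many, sig)
  p2 <- prognostic_score(expr_many * 2, sig)
  expect_equal(p2$hrdps, 2 * p1$hrdps)
  # identity to machine precision
  expect_identical(p1$hrdps, p1$ps_up - p1$ps_down)

  expect_error(prognostic_score(expr[1, , drop = FALSE], sig), "missing")
  bad <- sig; bad$hazard_ratio[1] <- -1
  expect_error(prognostic_score(expr, bad), "positive")
})

test_that("HRDPS positivity uses a strict median split by default", {
  expect_equal(which(call_hrdps_positive(c(1, 2, 3, 4))), c(3L, 4L))
  expect_equal(sum(call_hrdps_positive(rep(5, 6))), 0)
  x <- c(10, 20, 30, 40, 50, 60, 70, 80)
  expect_equal(call_hrdps_positive(x, rule = "quantile", quantile = 0.75),
               call_is_positive(x))
})

test_that("signature round-trips through TSV and JSON", {
  sig <- data.frame(gene = c("a", "b"), direction = c("up", "down"),
                    hazard_ratio = c(0.4, 2.5))
  class(sig) <- c("hrd_signature", "data.frame")
  for (ext in c(".tsv", ".json")) {
    f <- tempfile(fileext = ext)
    write_signature(sig, f)
    rt <- read_signature(f)
    expect_equal(rt$gene, sig$gene)
    expect_equal(rt$hazard_ratio, sig$hazard_ratio)
  }
})

test_that("ROC evaluation behaves at the extremes and matches theory", {
  # perfect separation
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(attr(r, "auc"), 1.0)
  # permutation null
  set.seed(75)
  auc_null <- replicate(30, {
    attr(roc_curve(stats::rnorm(200), sample(rep(c(T, F), 100))), "auc")
  })
  expect_true(all(auc_null > 0.35 & auc_null < 0.65))
  expect_lt(abs(mean(auc_null) - 0.5), 0.03)
  # binormal closed form: score = label + N(0, sigma) has
  # AUC = Phi(1 / (sigma * sqrt(2)))
  sigma <- 0.8
  set.seed(76)
  auc_bn <- mean(replicate(20, {
    y <- sample(rep(c(TRUE, FALSE), 150))
    s <- as.numeric(y) + stats::rnorm(300, 0, sigma)
    attr(roc_curve(s, y), "auc")
  }))
  expect_lt(abs(auc_bn - stats::pnorm(1 / (sigma * sqrt(2)))), 0.05)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("end-to-end: derived signatures predict HRD status well", {
  set.seed(77)
  aucs <- replicate(3, {
    b <- generate_cohort(cohort_config(n_samples = 120, n_genes = 300,
                                       signature_effect = 1.5,
                                       seed = sample.int(1e6, 1)))
    de <- differential_expression(b$expr_counts, b$truth$hrd)
    cand <- de$gene[de$deg]
    cand <- cand[cand %in% rownames(b$expr_log)]
    if (length(cand) < 2) return(NA_real_)
    cox <- suppressWarnings(
      cox_screen(b$expr_log, b$clinical$ffi_months, b$clinical$ffi_event,
                 genes = cand))
    sig <- suppressWarnings(
      lasso_reduce(b$expr_log[cand, , drop = FALSE], b$truth$hrd, de, cox,
                   seed = 3, lambda = "lambda.min"))
    ev <- evaluate_signature_as_hrd_predictor(b$expr_log, b$truth$hrd,
                                              signature = sig)
    ev$auc
  })
  expect_gte(stats::median(aucs, na.rm = TRUE), 0.85)
})
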