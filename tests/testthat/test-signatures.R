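# Trinucleotide spectra, exposure fitting, SBS3 dominance, indel ratio.

test_that("spectrum building applies the pyrimidine-strand convention", {
  empty <- build_spectrum(data.frame(ref = character(), alt = character(),
                                     trinucleotide_context = character()))
  expect_equal(sum(empty), 0)
  expect_equal(length(empty), 96)

  # one G>T mutation in context A[G]C maps to G[C>A]T after revcomp
  one <- build_spectrum(data.frame(ref = "G", alt = "T",
                                   trinucleotide_context = "AGC"))
  expect_equal(sum(one), 1)
  expect_equal(unname(one["G[C>A]T"]), 1L)

  # pyrimidine reference passes through unchanged
  py <- build_spectrum(data.frame(ref = "C", alt = "T",
                                  trinucleotide_context = "ACG"))
  expect_equal(unname(py["A[C>T]G"]), 1L)

  # unresolvable contexts are excluded and counted
  mix <- data.frame(ref = c(rep("C", 47), rep("C", 3)),
                    alt = "A",
                    trinucleotide_context = c(rep("ACA", 47), rep("NNN", 3)))
  sp <- build_spectrum(mix)
  expect_equal(sum(sp), 47)
  expect_equal(attr(sp, "n_excluded"), 3L)

  # indels and MNVs are ignored silently
  ind <- build_spectrum(data.frame(ref = c("A", "AT"), alt = c("AT", "A"),
                                   trinucleotide_context = "-"))
  expect_equal(sum(ind), 0)
})

test_that("spectrum is invariant to mutation row order", {
  set.seed(1)
  sigs <- default_signature_matrix()
  ch <- sample(rownames(sigs), 200, replace = TRUE)
  mut <- data.frame(ref = substr(ch, 3, 3), alt = substr(ch, 5, 5),
                    trinucleotide_context = paste0(substr(ch, 1, 1),
                                                   substr(ch, 3, 3),
                                                   substr(ch, 7, 7)))
  expect_identical(build_spectrum(mut),
                   build_spectrum(mut[sample(nrow(mut)), ]))
})

test_that("every default signature column is a distribution over channels", {
  sigs <- default_signature_matrix()
  expect_equal(dim(sigs), c(96L, 5L))
  expect_equal(unname(colSums(sigs)), rep(1, 5))
  expect_true(all(sigs >= 0))
  expect_identical(rownames(sigs), trinucleotide_channels())
})

test_that("pure and mixed spectra are recovered by the exposure fit", {
  sigs <- default_signature_matrix()
  set.seed(11)
  # pure SBS3: weight >= 0.9, everything else zero after the drop floor
  spec <- table(factor(sample(rownames(sigs), 1000, replace = TRUE,
                              prob = sigs[, "SBS3"]),
                       levels = rownames(sigs)))
  fit <- fit_exposures(as.numeric(spec), sigs)
  expect_gte(fit$weights["SBS3"], 0.9)
  expect_equal(sum(fit$weights > 0 &
                     names(fit$weights) != "SBS3"), 0)

  # exact noiseless 50/50 mixture of SBS1 and SBS20
  mix <- 0.5 * sigs[, "SBS1"] + 0.5 * sigs[, "SBS20"]
  fit2 <- fit_exposures(round(mix * 1e6), sigs)
  expect_lt(abs(fit2$weights["SBS1"] - 0.5), 0.05)
  expect_lt(abs(fit2$weights["SBS20"] - 0.5), 0.05)

  # constraints hold for arbitrary spectra
  for (i in 1:20) {
    sp <- stats::rpois(96, 3)
    if (sum(sp) == 0) next
    f <- fit_exposures(sp, sigs)
    expect_true(all(f$weights >= 0))
    expect_lte(sum(f$weights), 1.0001)
    w <- f$weights
    expect_true(all(w[w > 0] >= 0.06 - 1e-9))
  }
  expect_error(fit_exposures(rep(0, 96), sigs), "empty spectrum")
})

test_that("fit error never exceeds the best single-signature error", {
  sigs <- default_signature_matrix()
  set.seed(5)
  for (i in 1:30) {
    sp <- stats::rmultinom(1, 500, prob = as.numeric(
      sigs %*% as.numeric(stats::rmultinom(1, 10, rep(0.2, 5))) / 10))[, 1]
    p <- sp / sum(sp)
    single_best <- min(apply(sigs, 2, function(s) {
      w <- sum(s * p) / sum(s * s)
      sqrt(sum((p - w * s)^2))
    }))
    f <- fit_exposures(sp, sigs)
    expect_lte(f$error, single_best + 1e-8)
  }
})

test_that("planted two-signature mixtures are recovered within 0.05 MAE", {
  sigs <- default_signature_matrix()
  set.seed(2024)
  err <- replicate(100, {
    w <- stats::runif(1, 0.25, 0.75)
    pair <- sample(c("SBS1", "SBS3", "SBS6", "SBS20"), 2)
    mix <- w * sigs[, pair[1]] + (1 - w) * sigs[, pair[2]]
    sp <- stats::rmultinom(1, 1000, mix)[, 1]
    f <- fit_exposures(sp, sigs)
    truth <- stats::setNames(numeric(5), colnames(sigs))
    truth[pair] <- c(w, 1 - w)
    mean(abs(f$weights - truth))
  })
  expect_lt(mean(err), 0.05)
})

test_that("SBS3 dominance is an inclusive 0.3 threshold", {
  w <- c(SBS1 = 0.1, SBS3 = 0.30, SBS6 = 0, SBS20 = 0, flat = 0.6)
  expect_true(is_sbs3_dominant(w))
  w["SBS3"] <- 0.299
  expect_false(is_sbs3_dominant(w))
  w["SBS3"] <- 0
  expect_false(is_sbs3_dominant(w))
  expect_error(is_sbs3_dominant(c(SBS1 = 1)), "not present")
})

test_that("indel ratio guards the zero-deletion case", {
  mk <- function(n_ins, n_del) {
    data.frame(ref = c(rep("A", n_ins), rep("AT", n_del)),
               alt = c(rep("AT", n_ins), rep("A", n_del)))
  }
  expect_equal(as.numeric(indel_ratio(mk(4, 2))), 2.0)
  expect_equal(as.numeric(indel_ratio(mk(0, 5))), 0.0)
  expect_warning(r <- indel_ratio(mk(3, 0)), "denominator")
  expect_equal(as.numeric(r), 3)
  expect_true(attr(r, "denominator_zero"))
})

test_that("the HRDetect-style model scores and trains sensibly", {
  # logistic identities
  m0 <- structure(list(features = c("a", "b"),
                       weights = c(a = 0, b = 0), intercept = 0,
                       centre = c(a = 0, b = 0), scale = c(a = 1, b = 1)),
                  class = "hrdetect_model")
  expect_equal(hrdetect_score(c(a = 3, b = -2), m0), 0.5)
  m0$intercept <- -50
  expect_lt(hrdetect_score(c(a = 0, b = 0), m0), 1e-10)
  expect_error(hrdetect_score(c(zz = 1), m0), "mismatch")

  # separable features train to high held-out accuracy
  set.seed(3)
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- cbind(f1 = stats::rnorm(n, ifelse(y, 3, 0)),
             f2 = stats::rnorm(n, ifelse(y, -2, 0)),
             noise = stats::rnorm(n))
  train <- sample(n, n / 2)
  model <- train_hrdetect(x[train, ], y[train], seed = 10)
  acc <- mean((hrdetect_score(x[-train, ], model) >= 0.5) == y[-train])
  expect_gte(acc, 0.95)

  # determinism under a fixed seed
  model2 <- train_hrdetect(x[train, ], y[train], seed = 10)
  expect_identical(model$weights, model2$weights)

  # monotone in positively weighted features
  f <- c(f1 = 1, f2 = 0, noise = 0)
  s1 <- hrdetect_score(f, model)
  f["f1"] <- 2
  expect_gt(hrdetect_score(f, model), s1)

  # permuted labels give chance-level AUC
  set.seed(4)
  yp <- sample(y[train])
  mp <- train_hrdetect(x[train, ], yp, seed = 10)
  auc <- oracle_auc(hrdetect_score(x[-train, ], mp), y[-train])
  expect_lt(abs(auc - 0.5), 0.12)

  expect_error(train_hrdetect(x, rep(TRUE, n)), "degenerate")

  # JSON round trip
  tmp <- tempfile(fileext = ".json")
  write_hrdetect_model(model, tmp)
  model_rt <- read_hrdetect_model(tmp)
  expect_equal(model_rt$weights, model$weights)
  expect_equal(hrdetect_score(x[1:5, ], model_rt),
               hrdetect_score(x[1:5, ], model))
})
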