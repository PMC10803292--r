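test_that("confusion matrices count (true, predicted) pairs", {
  cls <- ecg_classes()
  cm <- confusion(cls, cls)
  expect_equal(unname(diag(cm)), rep(1L, 6))
  expect_equal(sum(cm), 6)

  cm1 <- confusion("afib", "normal")
  expect_equal(cm1["afib", "normal"], 1L)
  expect_equal(sum(cm1), 1)

  set.seed(41)
  true <- sample(cls, 200, replace = TRUE)
  pred <- sample(cls, 200, replace = TRUE)
  cm <- confusion(true, pred)
  expect_equal(unname(rowSums(cm)),
               unname(as.integer(table(factor(true, levels = cls)))))
  expect_error(confusion("normal", "pvc"), "unknown")
  expect_error(confusion(cls, cls[1:3]), "length")
})

test_that("precision/recall/F1 match the brute-force oracle", {
  cm <- matrix(0L, 6, 6, dimnames = list(ecg_classes(), ecg_classes()))
  cm[1, 1] <- 8L; cm[2, 1] <- 2L; cm[1, 2] <- 2L
  m <- metrics_from_confusion(cm)
  expect_equal(m$per_class$precision[1], 0.8)
  expect_equal(m$per_class$recall[1], 0.8)
  expect_equal(m$per_class$f1[1], 0.8)

  perfect <- diag(5L, 6)
  mp <- metrics_from_confusion(perfect)
  expect_equal(mp$per_class$f1, rep(1, 6))
  expect_equal(mp$macro_f1, 1)

  set.seed(42)
  for (i in 1:10) {
    cm <- matrix(rpois(36, 4), 6, 6)
    m <- metrics_from_confusion(cm)
    ref <- metrics_oracle(cm)
    expect_lt(max(abs(cbind(m$per_class$precision, m$per_class$recall,
                            m$per_class$f1) - ref)), 1e-9)
    expect_equal(m$macro_f1, mean(ref[, 3]), tolerance = 1e-9)
  }

  # empty class: 0/0 ratios are defined as 0 and flagged
  cm0 <- diag(3L, 6); cm0[6, 6] <- 0L
  m0 <- metrics_from_confusion(cm0)
  expect_equal(m0$per_class$f1[6], 0)
  expect_true(m0$per_class$undefined[6])
})

test_that("Frechet distance matches the DP oracle and metric axioms", {
  set.seed(43)
  for (i in 1:10) {
    p <- cbind(seq_len(5) - 1, rnorm(5))
    q <- cbind(seq_len(5) - 1, rnorm(5))
    expect_equal(frechet_distance(p, q), frechet_oracle(p, q),
                 tolerance = 1e-12)
    expect_equal(frechet_distance(p, q), frechet_distance(q, p))
    expect_gte(frechet_distance(p, q), 0)
    expect_equal(frechet_distance(p, p), 0)
  }
  # polylines of different lengths
  p <- cbind(0:3, c(0, 1, 0, -1)); q <- cbind(0:5, rep(0, 6))
  expect_equal(frechet_distance(p, q), frechet_oracle(p, q))
})

test_that("generation quality has the stated closed forms", {
  x <- sin(seq(0, 2 * pi, length.out = 100))
  gq <- generation_quality(x, x)
  expect_equal(gq$mse, 0)
  expect_equal(gq$fd, 0)
  gq2 <- generation_quality(x, x + 0.25)
  expect_equal(gq2$mse, 0.0625, tolerance = 1e-12)
  expect_equal(gq2$fd, 0.25, tolerance = 1e-12)
  expect_error(generation_quality(x, x[1:50]), "length")
})

test_that("the protocol runs per group with fresh classifiers and full reports", {
  cohort <- synth_cohort(synth_config(n_records = 60, seed = 51,
                                      minor_frac = 0, unconfirmed_frac = 0))
  gcfg <- test_gan_config(epochs = 0L, seed = 100L,
                          enc = c(4L, 8L, 8L, 8L, 8L, 8L, 8L),
                          disc = c(4L, 4L, 4L, 4L, 4L))
  models <- train_all_leads(gcfg, cohort)
  ccfg <- test_clf_config(epochs = 1L, seed = 5L)
  res <- run_protocol(c("realI", "einthoven_II"), ccfg, cohort,
                      gan_models = models)
  expect_equal(nrow(res$report), 12)        # 6 classes x 2 groups
  expect_setequal(unique(res$report$group), c("realI", "einthoven_II"))
  expect_equal(dim(res$confusions$realI), c(6L, 6L))
  expect_s3_class(res$metrics$einthoven_II, "class_metrics")
  expect_true(all(c("rule", "n") %in% names(res$exclusions)))
  # identical seeds give an identical report
  res2 <- run_protocol(c("realI"), ccfg, cohort)
  expect_equal(res2$metrics$realI$per_class,
               res$metrics$realI$per_class)
  expect_error(run_protocol("gen12", ccfg, cohort), "gan_models")
})
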