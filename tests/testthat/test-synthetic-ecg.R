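test_that("dipole trajectory has the expected shape and degenerate limits", {
  p <- dipole_params("normal")
  set.seed(1)
  d <- synth_dipole(p, fs = 500, duration = 10)
  expect_equal(dim(d), c(3L, 5000L))

  p0 <- p
  p0$waves$amp[] <- 0
  set.seed(1)
  d0 <- synth_dipole(p0, fs = 500, duration = 10)
  expect_equal(dim(d0), c(3L, 5000L))
  expect_true(all(d0 == 0))

  set.seed(42); d1 <- synth_dipole(p, 500, 10)
  set.seed(42); d2 <- synth_dipole(p, 500, 10)
  expect_identical(d1, d2)
})

test_that("invalid dipole parameters are rejected", {
  expect_error(dipole_params("normal", hr_mean = -10), "heart-rate")
  expect_error(dipole_params("normal", hr_mean = NaN), "finite")
  p <- dipole_params("normal")
  p$waves$width[2] <- -0.1
  expect_error(synth_dipole(p, 500, 10), "width")
  p <- dipole_params("normal")
  p$waves$theta <- rev(p$waves$theta)
  expect_error(synth_dipole(p, 500, 10), "increasing")
  expect_error(synth_dipole(dipole_params(), fs = 0, duration = 10), "fs")
})

test_that("noise-free projection satisfies the Einthoven identities exactly", {
  cfg <- synth_config(n_records = 1, seed = 3, noise_sd = 0)
  set.seed(2)
  d <- synth_dipole(dipole_params(), 500, 10)
  sig <- project_to_leads(d, cfg)
  expect_lt(max(abs(sig["III", ] - (sig["II", ] - sig["I", ]))), 1e-10)
  expect_lt(max(abs(sig["aVR", ] + (sig["I", ] + sig["II", ]) / 2)), 1e-10)
  expect_lt(max(abs(sig["aVL", ] - (sig["I", ] - sig["II", ] / 2))), 1e-10)
  expect_lt(max(abs(sig["aVF", ] - (sig["II", ] - sig["I", ] / 2))), 1e-10)

  sig0 <- project_to_leads(matrix(0, 3, 100), cfg)
  expect_true(all(sig0 == 0))
  expect_error(project_to_leads(matrix(0, 4, 10), cfg), "3 x N")
})

test_that("cohort respects size, proportions and per-class morphology", {
  cfg <- synth_config(n_records = 60, seed = 11, minor_frac = 0,
                      unconfirmed_frac = 0)
  cohort <- synth_cohort(cfg)
  expect_length(cohort, 60)
  counts <- table(factor(vapply(cohort, `[[`, "", "label"),
                         levels = ecg_classes()))
  # multinomial draw with expectation 10 per class: all counts in a wide
  # central range (binomial(60, 1/6) has SD ~2.9)
  expect_true(all(counts >= 2 & counts <= 22))
  expect_equal(sum(counts), 60)

  # afib RR intervals are more variable than sinus RR under the same seed
  rr_sd <- function(class, seed) {
    props <- stats::setNames(as.numeric(ecg_classes() == class), ecg_classes())
    co <- synth_cohort(synth_config(n_records = 12, seed = seed,
                                    class_proportions = props))
    mean(vapply(co, function(r) stats::sd(attr(r, "rr")), 0))
  }
  expect_gt(rr_sd("afib", 5), rr_sd("normal", 5))
})

test_that("invalid cohort configuration is rejected", {
  props <- stats::setNames(rep(0.15, 6), ecg_classes())
  expect_error(synth_config(10, class_proportions = props), "sum to 1")
  props <- stats::setNames(c(-0.2, 0.4, 0.2, 0.2, 0.2, 0.2), ecg_classes())
  expect_error(synth_config(10, class_proportions = props), "nonnegative")
  P <- default_projection()
  P["III", ] <- c(1, 1, 1)
  expect_error(synth_config(10, projection = P), "Einthoven")
})

test_that("cohort generation is deterministic given the config seed", {
  cfg <- synth_config(n_records = 5, seed = 17)
  c1 <- synth_cohort(cfg)
  c2 <- synth_cohort(cfg)
  expect_identical(lapply(c1, `[[`, "signals"), lapply(c2, `[[`, "signals"))
  expect_identical(vapply(c1, `[[`, "", "label"),
                   vapply(c2, `[[`, "", "label"))
})

test_that("age and confirmed flags exercise the exclusion rules", {
  cfg <- synth_config(n_records = 200, seed = 23, minor_frac = 0.3,
                      unconfirmed_frac = 0.2)
  cohort <- synth_cohort(cfg)
  ages <- vapply(cohort, function(r) r$age, 0)
  conf <- vapply(cohort, function(r) r$confirmed, TRUE)
  expect_gt(mean(ages < 18), 0.15)
  expect_lt(mean(ages < 18), 0.45)
  expect_gt(mean(!conf), 0.1)
})
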