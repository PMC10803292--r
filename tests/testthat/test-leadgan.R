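test_that("configuration defaults encode the architecture constants", {
  cfg <- gan_config()
  expect_equal(cfg$kernel_size, 4L)
  expect_equal(cfg$stride, 2L)
  expect_equal(cfg$leaky_slope, 0.2)
  expect_equal(cfg$lr_generator, 5e-4)
  expect_equal(cfg$lr_discriminator, 1e-4)
  expect_equal(cfg$batch_size, 32L)
  expect_length(cfg$enc_widths, 7)
  expect_length(cfg$disc_widths, 5)
  expect_error(gan_config(lambda_l1 = -1), "nonnegative")
})

test_that("encoder lengths follow the stride-2 length recurrence", {
  cfg <- test_gan_config()
  expect_equal(encoder_lengths(cfg), c(625L, 312L, 156L, 78L, 39L, 19L, 9L))
})

test_that("generator maps (B,1,1250) to (B,1,1250) and rejects bad shapes", {
  set.seed(11)
  gen <- gan_generator(test_gan_config(), "II")
  for (B in c(1L, 3L)) {
    x <- array(rnorm(B * 1250), c(B, 1L, 1250L))
    y <- generator_forward(gen, x)
    expect_equal(dim(y), c(B, 1L, 1250L))
    expect_true(all(is.finite(y)))
  }
  expect_error(generator_forward(gen, array(0, c(2, 1, 1000))), "shape")
  expect_error(generator_forward(gen, array(NaN, c(1, 1, 1250))),
               "non-finite")
})

test_that("generation is deterministic when dropout is disabled", {
  set.seed(12)
  gen <- gan_generator(test_gan_config(), "II")
  x <- array(0, c(1, 1, 1250))
  y1 <- generator_forward(gen, x, use_dropout = FALSE)
  y2 <- generator_forward(gen, x, use_dropout = FALSE)
  expect_identical(y1, y2)
  x <- array(rnorm(1250), c(1, 1, 1250))
  # dropout injects stochasticity (the z of the conditional objective)
  set.seed(1); z1 <- generator_forward(gen, x, use_dropout = TRUE)
  set.seed(2); z2 <- generator_forward(gen, x, use_dropout = TRUE)
  expect_false(identical(z1, z2))
})

test_that("discriminator scores lie strictly in (0,1) with shape (B,1)", {
  set.seed(13)
  cfg <- test_gan_config()
  disc <- gan_discriminator(cfg)
  x <- array(rnorm(4 * 1250), c(4, 1, 1250))
  y <- array(rnorm(4 * 1250), c(4, 1, 1250))
  s <- discriminator_forward(disc, x, y)
  expect_equal(dim(s), c(4L, 1L))
  expect_true(all(s > 0 & s < 1))
  s2 <- discriminator_forward(disc, x, y)
  expect_identical(s, s2)
  expect_error(discriminator_forward(disc, x, y[1:2, , , drop = FALSE]),
               "batch")
})

test_that("adversarial and L1 losses match scalar-loop oracles", {
  expect_equal(as.numeric(loss_cgan(rep(0.5, 3), rep(0.5, 3))), -2 * log(2),
               tolerance = 1e-12)
  # supremum: perfect discrimination drives the objective to 0
  v <- loss_cgan(rep(1 - 1e-9, 4), rep(1e-9, 4))
  expect_gt(as.numeric(v), -1e-5)
  expect_gt(attr(v, "n_clamped"), 0)

  set.seed(14)
  for (i in 1:5) {
    dr <- runif(3, 0.05, 0.95); df <- runif(3, 0.05, 0.95)
    expect_equal(as.numeric(loss_cgan(dr, df)), cgan_oracle(dr, df),
                 tolerance = 1e-6)
  }

  y <- rnorm(5); g <- rnorm(5)
  expect_equal(loss_l1(y, g), l1_oracle(y, g), tolerance = 1e-9)
  expect_equal(loss_l1(y, y), 0)
  expect_equal(loss_l1(y, y - 0.3), 0.3, tolerance = 1e-12)
  expect_error(loss_l1(rnorm(4), rnorm(5)), "shape")

  expect_equal(combined_objective(0.7, 0.01, 100), 1.7)
  expect_equal(combined_objective(0.7, 0.01, 0), 0.7)
  a <- combined_objective(0.3, 0.02, 50)
  b <- combined_objective(0.3, 0.02, 100)
  expect_equal(b - a, 50 * 0.02)
})

test_that("zero-epoch training returns the seeded initialization unchanged", {
  cohort <- make_clean_cohort(4, seed = 15)
  pairs <- lead_pairs(cohort, "II")
  cfg <- test_gan_config(epochs = 0L, seed = 33L)
  out <- train_gan(cfg, pairs)
  expect_equal(nrow(out$log), 0)
  set.seed(cfg$seed)
  fresh <- gan_generator(cfg, "II")
  expect_equal(ecglead:::nn_param_digest(out$model$layers),
               ecglead:::nn_param_digest(fresh$layers))
})

test_that("the copy task is learned well below the untrained baseline", {
  cohort <- make_clean_cohort(60, seed = 7)
  pairs <- lead_pairs(cohort, "I")          # target == input lead
  tr <- 1:200; ho <- 201:240
  cfg <- test_gan_config(epochs = 0L, seed = 9L)
  untrained <- train_gan(cfg, list(x = pairs$x[tr, ], y = pairs$y[tr, ]))$model
  g0 <- generator_forward(untrained, pairs$x[ho, ], use_dropout = FALSE)
  base_l1 <- mean(abs(pairs$y[ho, ] - g0[, 1, ]))

  cfg$epochs <- 30L
  fit <- train_gan(cfg, list(x = pairs$x[tr, ], y = pairs$y[tr, ]))
  g1 <- generator_forward(fit$model, pairs$x[ho, ], use_dropout = FALSE)
  l1 <- mean(abs(pairs$y[ho, ] - g1[, 1, ]))
  expect_lt(l1, 0.2 * base_l1)

  # reconstruction error descends across the early 5-epoch blocks of the log
  em <- stats::aggregate(g_l1 ~ epoch, fit$log, mean)
  blocks <- vapply(split(em$g_l1, (em$epoch - 1) %/% 5), mean, 0)
  expect_true(all(diff(blocks[1:4]) < 0))
  expect_true(all(is.finite(fit$log$g_total)))
  expect_true(all(is.finite(fit$log$d_loss)))
})

test_that("one model per non-input lead is trained with distinct seeds", {
  cohort <- make_clean_cohort(2, seed = 16)
  cfg <- test_gan_config(epochs = 0L, seed = 100L,
                         enc = c(4L, 8L, 8L, 8L, 8L, 8L, 8L),
                         disc = c(4L, 4L, 4L, 4L, 4L))
  models <- train_all_leads(cfg, cohort)
  expect_length(models, 11)
  expect_setequal(names(models), setdiff(ecg_leads(), "I"))
  expect_false("I" %in% names(models))
  seeds <- vapply(models, function(m) m$config$seed, 0L)
  expect_equal(anyDuplicated(seeds), 0L)
  expect_false(any(seeds == cfg$seed))
})

test_that("12-lead assembly passes lead I through and keys leads correctly", {
  cohort <- make_clean_cohort(2, seed = 16)
  cfg <- test_gan_config(epochs = 0L, seed = 100L,
                         enc = c(4L, 8L, 8L, 8L, 8L, 8L, 8L),
                         disc = c(4L, 4L, 4L, 4L, 4L))
  models <- train_all_leads(cfg, cohort)
  xs <- t(vapply(segment_cohort(cohort)$segments,
                 function(s) s$signals["I", ], numeric(1250)))
  out <- generate_12lead(models, xs[1:3, ], use_dropout = FALSE)
  expect_equal(dim(out), c(3L, 12L, 1250L))
  expect_identical(out[2, 1, ], unname(xs[2, ]))
  expect_error(generate_12lead(models[-3], xs[1:2, ]), names(models)[3])
})
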