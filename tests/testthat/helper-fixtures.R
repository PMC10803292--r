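# Shared fixtures, built in code at test time.

# Noise-free single-class cohort (sinus morphology) for signal-level checks.
make_clean_cohort <- function(n = 10, seed = 7, class = "normal") {
  props <- stats::setNames(as.numeric(ecg_classes() == class), ecg_classes())
  synth_cohort(synth_config(n_records = n, seed = seed, noise_sd = 0,
                            minor_frac = 0, unconfirmed_frac = 0,
                            class_proportions = props))
}

# Lead I / target-lead segment pair matrices from a cohort.
lead_pairs <- function(cohort, target = "II") {
  sc <- segment_cohort(cohort)
  list(x = t(vapply(sc$segments, function(s) s$signals["I", ], numeric(1250))),
       y = t(vapply(sc$segments, function(s) s$signals[target, ],
                    numeric(1250))))
}

# Small GAN config used throughout the suite (architecture constants per the
# study; widths scaled to desk size).
test_gan_config <- function(epochs = 0L, seed = 9L,
                            enc = c(12L, 24L, 48L, 48L, 48L, 48L, 48L),
                            disc = c(12L, 24L, 48L, 48L, 48L)) {
  gan_config(enc_widths = enc, disc_widths = disc, epochs = epochs,
             seed = seed)
}

# Small classifier config (same architecture family for every group).
test_clf_config <- function(channels = 12L, epochs = 6L, seed = 61L,
                            input_len = 1250L, lr = 2e-3) {
  classifier_config(channels = channels, stem_width = 8L,
                    stage_widths = c(16L, 32L), blocks_per_stage = 1L,
                    epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
                    input_len = as.integer(input_len))
}

# Pure-R reference DP for the discrete Frechet distance (oracle).
frechet_oracle <- function(p, q) {
  n <- nrow(p); m <- nrow(q)
  ca <- matrix(NA_real_, n, m)
  d <- function(i, j) sqrt(sum((p[i, ] - q[j, ])^2))
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (i == 1 && j == 1) ca[i, j] <- d(1, 1)
    else if (i == 1) ca[i, j] <- max(ca[1, j - 1], d(i, j))
    else if (j == 1) ca[i, j] <- max(ca[i - 1, 1], d(i, j))
    else ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                         d(i, j))
  }
  ca[n, m]
}

# Scalar-loop oracles for the loss formulas.
cgan_oracle <- function(d_real, d_fake) {
  s <- 0
  for (v in d_real) s <- s + log(v) / length(d_real)
  for (v in d_fake) s <- s + log(1 - v) / length(d_fake)
  s
}

l1_oracle <- function(y, g) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - g[i])
  s / length(y)
}

metrics_oracle <- function(cm) {
  out <- matrix(0, 6, 3)
  for (c in 1:6) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 / (1 / p + 1 / r)
    out[c, ] <- c(p, r, f)
  }
  out
}
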