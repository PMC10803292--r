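# Conditional GAN for single-lead to single-lead translation.
#
# One generator per target lead maps a (B, 1, 1250) batch of lead I segments
# to the same shape in the target lead. The generator is a 7-level 1D U-Net:
# encoder convolutions (kernel 4, stride 2, padding 1; batch norm and
# LeakyReLU 0.2 everywhere except the first layer), decoder up-convolutions
# with skip connections pairing encoder level k with decoder level depth-k,
# dropout in the first three decoder blocks acting as the noise source z,
# and a linear (unbounded) output since raw mV amplitudes are not
# normalized. The discriminator sees condition and candidate concatenated as
# two channels, applies five conv+BN+LeakyReLU blocks, a final 1-channel
# mapping convolution, a sigmoid, and averages over the remaining temporal
# positions to one score per sample.
#
# Objective: L_cGAN(G,D) = E[log D(x,y)] + E[log(1 - D(x,G(x,z)))], plus a
# weighted L1 reconstruction term; G* = arg min_G max_D L_cGAN + lambda*L1.

#' Hyperparameters of the lead-translation conditional GAN
#'
#' Defaults: kernel 4, stride 2, LeakyReLU
#' slope 0.2, 7 encoder and 7 decoder layers, 5 discriminator conv blocks,
#' generator/discriminator learning rates 5e-4 / 1e-4, Adam, batch size 32.
#' The L1 weight, channel widths, Adam moments and dropout rate are not
#' fixed by the architecture description and default to the standard paired
#' image-translation settings (lambda = 100, encoder widths
#' 64,128,256,512,512,512,512, moments 0.5/0.999, dropout 0.5).
#'
#' @param kernel_size,stride,leaky_slope,batch_size,lr_generator,lr_discriminator
#'   Architecture and optimization constants (see above).
#' @param lambda_l1 Nonnegative weight of the L1 term in the generator
#'   objective.
#' @param epochs Training epochs.
#' @param enc_widths Encoder channel widths, length = encoder depth (7).
#' @param disc_widths Discriminator conv block widths (5 blocks).
#' @param adam_beta1,adam_beta2 Adam moment coefficients.
#' @param dropout Dropout rate of the first three decoder blocks (the noise
#'   source z).
#' @param seed Integer RNG seed.
#' @param input_len Segment length in samples (1250 for 2.5 s at 500 Hz).
#' @param non_saturating If `TRUE` (default) the generator minimizes
#'   `-log D(x, G(x,z))`; if `FALSE`, the literal `log(1 - D)` form.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(kernel_size = 4L, stride = 2L, leaky_slope = 0.2,
                       lr_generator = 5e-4, lr_discriminator = 1e-4,
                       batch_size = 32L, lambda_l1 = 100, epochs = 50L,
                       enc_widths = c(64L, 128L, 256L, 512L, 512L, 512L, 512L),
                       disc_widths = c(64L, 128L, 256L, 512L, 512L),
                       adam_beta1 = 0.5, adam_beta2 = 0.999,
                       dropout = 0.5, seed = 1L, input_len = 1250L,
                       non_saturating = TRUE) {
  if (lambda_l1 < 0) stop("lambda_l1 must be nonnegative")
  if (length(enc_widths) < 1L) stop("encoder depth must be >= 1")
  obj <- list(kernel_size = as.integer(kernel_size), stride = as.integer(stride),
              leaky_slope = leaky_slope, lr_generator = lr_generator,
              lr_discriminator = lr_discriminator,
              batch_size = as.integer(batch_size), lambda_l1 = lambda_l1,
              epochs = as.integer(epochs), enc_widths = as.integer(enc_widths),
              disc_widths = as.integer(disc_widths),
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              dropout = dropout, seed = as.integer(seed),
              input_len = as.integer(input_len),
              non_saturating = isTRUE(non_saturating))
  class(obj) <- "gan_config"
  obj
}

#' Encoder output lengths of the U-Net generator
#'
#' Applies `floor((L + 2p - k)/s) + 1` once per encoder level with
#' padding 1. For the default 1250-sample input and 7 levels this gives
#' 625, 312, 156, 78, 39, 19, 9.
#'
#' @param config A [gan_config()].
#' @return Integer vector, one entry per encoder level.
#' @export
encoder_lengths <- function(config) {
  L <- config$input_len
  out <- integer(length(config$enc_widths))
  for (i in seq_along(out)) {
    L <- nn_out_len(L, config$kernel_size, config$stride, 1L)
    out[i] <- L
  }
  out
}

# ---- generator -------------------------------------------------------------

#' Build an untrained U-Net generator for one target lead
#'
#' @param config A [gan_config()].
#' @param target_lead Name of the lead the generator synthesizes.
#' @return An object of class `gan_generator`.
#' @export
gan_generator <- function(config, target_lead = "II") {
  k <- config$kernel_size; s <- config$stride
  w <- config$enc_widths
  depth <- length(w)
  enc_len <- encoder_lengths(config)
  enc <- vector("list", depth)
  enc_bn <- vector("list", depth)
  c_in <- 1L
  for (i in seq_len(depth)) {
    enc[[i]] <- nn_conv1d(c_in, w[i], k, s, 1L)
    if (i > 1L) enc_bn[[i]] <- nn_bn1d(w[i])
    c_in <- w[i]
  }
  # decoder widths mirror the encoder; skip concat doubles the input width
  dec_out <- c(rev(w[-depth]), 1L)
  dec_in <- integer(depth)
  dec_in[1] <- w[depth]
  if (depth > 1)
    for (i in 2:depth) dec_in[i] <- dec_out[i - 1] + w[depth + 1L - i]
  dec <- vector("list", depth)
  dec_bn <- vector("list", depth)
  for (i in seq_len(depth)) {
    dec[[i]] <- nn_convt1d(dec_in[i], dec_out[i], k, s, 1L)
    if (i < depth) dec_bn[[i]] <- nn_bn1d(dec_out[i])
  }
  layers <- c(enc, Filter(Negate(is.null), enc_bn),
              dec, Filter(Negate(is.null), dec_bn))
  nn_zero_grad(layers)
  model <- list(config = config, target_lead = target_lead, depth = depth,
                enc = enc, enc_bn = enc_bn, dec = dec, dec_bn = dec_bn,
                enc_len = enc_len, layers = layers,
                adam = nn_adam_state(layers))
  class(model) <- "gan_generator"
  model
}

# internal forward on (1, L, B) arrays; returns y and caches
gen_fwd_internal <- function(model, x, training = TRUE, use_dropout = TRUE,
                             keep = TRUE) {
  cfg <- model$config
  depth <- model$depth
  e_out <- vector("list", depth)
  cc <- list(enc = vector("list", depth), dec = vector("list", depth))
  h <- x
  for (i in seq_len(depth)) {
    cv <- conv1d_fwd(model$enc[[i]], h, keep)
    h <- cv$y
    bn <- NULL
    if (i > 1L) {
      bn <- bn1d_fwd(model$enc_bn[[i]], h, training, keep)
      h <- bn$y
    }
    ac <- lrelu_fwd(h, cfg$leaky_slope)
    h <- ac$y
    e_out[[i]] <- h
    cc$enc[[i]] <- list(conv = cv$cache, bn = if (is.null(bn)) NULL else bn$cache,
                        act = ac$cache)
  }
  for (i in seq_len(depth)) {
    target <- if (i < depth) model$enc_len[depth - i] else cfg$input_len
    ct <- convt1d_fwd(model$dec[[i]], h, keep)
    ft <- fit_len(ct$y, target)
    h <- ft$y
    st <- list(convt = ct$cache, fit = ft$cache)
    if (i < depth) {
      bn <- bn1d_fwd(model$dec_bn[[i]], h, training, keep)
      h <- bn$y
      st$bn <- bn$cache
      if (i <= 3L) {
        dp <- dropout_fwd(h, cfg$dropout, active = use_dropout)
        h <- dp$y
        st$drop <- dp$cache
      }
      ac <- relu_fwd(h)
      h <- ac$y
      st$act <- ac$cache
      st$skip_ch <- dim(h)[1]
      h <- concat_ch(h, e_out[[depth - i]])
    }
    cc$dec[[i]] <- st
  }
  list(y = h, cache = if (keep) cc else NULL)
}

gen_bwd_internal <- function(model, cache, dy) {
  depth <- model$depth
  d_eout <- vector("list", depth)   # gradient wrt encoder block outputs (skips)
  h <- dy
  for (i in rev(seq_len(depth))) {
    st <- cache$dec[[i]]
    if (i < depth) {
      sp <- split_ch(h, st$skip_ch)
      h <- sp[[1]]
      d_eout[[depth - i]] <- sp[[2]]
      h <- relu_bwd(st$act, h)
      if (i <= 3L) h <- dropout_bwd(st$drop, h)
      h <- bn1d_bwd(model$dec_bn[[i]], st$bn, h)
    }
    h <- fit_len_bwd(st$fit, h)
    h <- convt1d_bwd(model$dec[[i]], st$convt, h)
  }
  for (i in rev(seq_len(depth))) {
    st <- cache$enc[[i]]
    if (!is.null(d_eout[[i]])) h <- h + d_eout[[i]]
    h <- lrelu_bwd(st$act, h)
    if (i > 1L) h <- bn1d_bwd(model$enc_bn[[i]], st$bn, h)
    h <- conv1d_bwd(model$enc[[i]], st$conv, h)
  }
  h
}

# coerce public (B, 1, L) arrays / (B, L) matrices to internal (1, L, B)
as_internal <- function(x, input_len) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), 1L, ncol(x)))
  d <- dim(x)
  if (length(d) != 3L || d[2] != 1L || d[3] != input_len)
    stop(sprintf("expected input of shape (B, 1, %d), got (%s)",
                 input_len, paste(d, collapse = ", ")))
  if (!all(is.finite(x))) stop("input contains non-finite values")
  aperm(x, c(2, 3, 1))
}

as_public <- function(y) aperm(y, c(3, 1, 2))

#' Generator forward pass
#'
#' Maps a batch of lead I segments to synthesized target-lead segments,
#' `(B, 1, 1250) -> (B, 1, 1250)`. The stochastic component z is realized as
#' decoder dropout, active by default in both training and generation;
#' disable it for deterministic output.
#'
#' @param model A `gan_generator`.
#' @param x Array of shape `(B, 1, input_len)` or matrix `(B, input_len)`.
#' @param use_dropout Keep the decoder dropout active.
#' @param training Use batch statistics (TRUE) or running statistics (FALSE)
#'   in batch normalization.
#' @return Array of shape `(B, 1, input_len)`.
#' @export
generator_forward <- function(model, x, use_dropout = TRUE, training = FALSE) {
  xi <- as_internal(x, model$config$input_len)
  out <- gen_fwd_internal(model, xi, training = training,
                          use_dropout = use_dropout, keep = FALSE)
  as_public(out$y)
}

# ---- discriminator ---------------------------------------------------------

#' Build an untrained conditional discriminator
#'
#' @param config A [gan_config()].
#' @return An object of class `gan_discriminator`.
#' @export
gan_discriminator <- function(config) {
  k <- config$kernel_size; s <- config$stride
  w <- config$disc_widths
  nb <- length(w)
  conv <- vector("list", nb + 1L)
  bn <- vector("list", nb)
  c_in <- 2L
  for (i in seq_len(nb)) {
    conv[[i]] <- nn_conv1d(c_in, w[i], k, s, 1L)
    bn[[i]] <- nn_bn1d(w[i])
    c_in <- w[i]
  }
  conv[[nb + 1L]] <- nn_conv1d(c_in, 1L, k, s, 1L)  # mapping conv to 1 channel
  layers <- c(conv, bn)
  nn_zero_grad(layers)
  model <- list(config = config, n_blocks = nb, conv = conv, bn = bn,
                layers = layers, adam = nn_adam_state(layers))
  class(model) <- "gan_discriminator"
  model
}

disc_fwd_internal <- function(model, x, y, training = TRUE, keep = TRUE) {
  cfg <- model$config
  if (!identical(dim(x)[3], dim(y)[3]))
    stop("discriminator: condition and candidate batch sizes differ")
  h <- concat_ch(x, y)
  nb <- model$n_blocks
  cc <- vector("list", nb + 1L)
  for (i in seq_len(nb)) {
    cv <- conv1d_fwd(model$conv[[i]], h, keep)
    bn <- bn1d_fwd(model$bn[[i]], cv$y, training, keep)
    ac <- lrelu_fwd(bn$y, cfg$leaky_slope)
    h <- ac$y
    cc[[i]] <- list(conv = cv$cache, bn = bn$cache, act = ac$cache)
  }
  cv <- conv1d_fwd(model$conv[[nb + 1L]], h, keep)
  z <- cv$y                                  # (1, T, B)
  sg <- sigmoid(z)
  score <- colMeans(matrix(sg, dim(sg)[2], dim(sg)[3]))  # mean over positions
  cc[[nb + 1L]] <- list(conv = cv$cache, sg = sg)
  list(score = score, cache = if (keep) cc else NULL)
}

# ds: gradient of the loss wrt the per-sample score (length B)
disc_bwd_internal <- function(model, cache, ds) {
  nb <- model$n_blocks
  st <- cache[[nb + 1L]]
  sg <- st$sg
  Tpos <- dim(sg)[2]; B <- dim(sg)[3]
  dsg <- array(rep(ds / Tpos, each = Tpos), c(1, Tpos, B))
  dz <- dsg * sg * (1 - sg)
  h <- conv1d_bwd(model$conv[[nb + 1L]], st$conv, dz)
  for (i in rev(seq_len(nb))) {
    h <- lrelu_bwd(cache[[i]]$act, h)
    h <- bn1d_bwd(model$bn[[i]], cache[[i]]$bn, h)
    h <- conv1d_bwd(model$conv[[i]], cache[[i]]$conv, h)
  }
  split_ch(h, 1L)   # list(d_condition, d_candidate)
}

#' Discriminator forward pass
#'
#' Scores condition/candidate pairs; conditioning is channel concatenation.
#' Scores lie strictly in (0, 1) (per-position sigmoid averaged over the
#' temporal positions left by the mapping convolution).
#'
#' @param model A `gan_discriminator`.
#' @param x,y Arrays of shape `(B, 1, input_len)` (condition and candidate).
#' @param training Batch-norm mode.
#' @return Matrix of shape `(B, 1)` of scores in (0, 1).
#' @export
discriminator_forward <- function(model, x, y, training = FALSE) {
  xi <- as_internal(x, model$config$input_len)
  yi <- as_internal(y, model$config$input_len)
  out <- disc_fwd_internal(model, xi, yi, training = training, keep = FALSE)
  matrix(out$score, ncol = 1)
}

# ---- losses ----------------------------------------------------------------

clamp01 <- function(s, eps = 1e-7) {
  n_clamped <- sum(s <= eps | s >= 1 - eps)
  s[s < eps] <- eps
  s[s > 1 - eps] <- 1 - eps
  list(s = s, n = n_clamped)
}

#' Conditional GAN adversarial objective
#'
#' `mean(log d_real) + mean(log(1 - d_fake))`: the quantity the
#' discriminator maximizes. Scores exactly 0 or 1 are clamped at 1e-7
#' before the log; the number of clamped values is attached as attribute
#' `n_clamped`.
#'
#' @param d_real,d_fake Numeric vectors of discriminator scores in (0, 1).
#' @param eps Clamping bound.
#' @return Scalar loss with attribute `n_clamped`.
#' @export
loss_cgan <- function(d_real, d_fake, eps = 1e-7) {
  cr <- clamp01(as.numeric(d_real), eps)
  cf <- clamp01(as.numeric(d_fake), eps)
  v <- mean(log(cr$s)) + mean(log(1 - cf$s))
  attr(v, "n_clamped") <- cr$n + cf$n
  v
}

#' L1 reconstruction loss
#'
#' Mean absolute deviation between target and generated segments over all
#' samples and batch entries.
#'
#' @param y,g Numeric arrays of identical shape.
#' @return Scalar.
#' @export
loss_l1 <- function(y, g) {
  if (!identical(dim(y), dim(g)) || length(y) != length(g))
    stop("loss_l1: shape mismatch")
  mean(abs(y - g))
}

#' Combined generator objective
#'
#' Adversarial term plus `lambda_l1` times the L1 term.
#'
#' @param adv,l1 Scalars.
#' @param lambda_l1 Nonnegative weight.
#' @return Scalar.
#' @export
combined_objective <- function(adv, l1, lambda_l1) {
  adv + lambda_l1 * l1
}

# ---- training --------------------------------------------------------------

#' Train the conditional GAN for one target lead
#'
#' Alternates discriminator ascent on the adversarial objective with
#' generator descent on the combined objective, using Adam at the configured
#' learning rates (discriminator 1e-4, generator 5e-4 by default). Fully
#' seeded and deterministic for a given config.
#'
#' @param config A [gan_config()].
#' @param pairs List with matrices `x` (inputs) and `y` (targets), each
#'   `N x input_len` (one segment per row).
#' @param target_lead Lead name stored in the model.
#' @param verbose Print per-epoch means.
#' @return List with `model` (the trained `gan_generator`), `disc`, and
#'   `log` (data.frame: step, epoch, d_loss, g_adv, g_l1, g_total).
#' @export
train_gan <- function(config, pairs, target_lead = "II", verbose = FALSE) {
  if (!is.matrix(pairs$x) || !is.matrix(pairs$y) ||
      nrow(pairs$x) != nrow(pairs$y))
    stop("pairs must hold matrices x and y with equal row counts")
  set.seed(config$seed)
  gen <- gan_generator(config, target_lead)
  disc <- gan_discriminator(config)
  N <- nrow(pairs$x)
  bs <- min(config$batch_size, N)
  log_rows <- list()
  step <- 0L
  if (config$epochs >= 1L) for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    for (start in seq(1L, N, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, N)]
      B <- length(idx)
      xb <- array(t(pairs$x[idx, , drop = FALSE]), c(1L, config$input_len, B))
      yb <- array(t(pairs$y[idx, , drop = FALSE]), c(1L, config$input_len, B))
      step <- step + 1L

      # --- discriminator step (ascend Eq 1) ---
      fake <- gen_fwd_internal(gen, xb, training = TRUE, use_dropout = TRUE,
                               keep = FALSE)$y
      nn_zero_grad(disc$layers)
      fr <- disc_fwd_internal(disc, xb, yb, training = TRUE)
      sf <- disc_fwd_internal(disc, xb, fake, training = TRUE)
      s_r <- clamp01(fr$score)$s
      s_f <- clamp01(sf$score)$s
      d_loss <- -(mean(log(s_r)) + mean(log(1 - s_f)))
      if (!is.finite(d_loss))
        stop("NaN/Inf discriminator loss at step ", step)
      disc_bwd_internal(disc, fr$cache, -1 / s_r / B)
      disc_bwd_internal(disc, sf$cache, 1 / (1 - s_f) / B)
      nn_adam_step(disc$layers, disc$adam, config$lr_discriminator,
                   config$adam_beta1, config$adam_beta2)

      # --- generator step (descend Eq 3) ---
      gf <- gen_fwd_internal(gen, xb, training = TRUE, use_dropout = TRUE)
      fake <- gf$y
      df <- disc_fwd_internal(disc, xb, fake, training = TRUE)
      s_g <- clamp01(df$score)$s
      if (config$non_saturating) {
        g_adv <- -mean(log(s_g))
        ds <- -1 / s_g / B
      } else {
        g_adv <- mean(log(1 - s_g))
        ds <- -1 / (1 - s_g) / B
      }
      l1 <- mean(abs(yb - fake))
      g_total <- g_adv + config$lambda_l1 * l1
      if (!is.finite(g_total))
        stop("NaN/Inf generator loss at step ", step)
      nn_zero_grad(disc$layers)
      nn_zero_grad(gen$layers)
      dfake <- disc_bwd_internal(disc, df$cache, ds)[[2]]
      dfake <- dfake + config$lambda_l1 * sign(fake - yb) / length(yb)
      gen_bwd_internal(gen, gf$cache, dfake)
      nn_adam_step(gen$layers, gen$adam, config$lr_generator,
                   config$adam_beta1, config$adam_beta2)

      log_rows[[step]] <- data.frame(step = step, epoch = ep, d_loss = d_loss,
                                     g_adv = g_adv, g_l1 = l1,
                                     g_total = g_total)
    }
    if (verbose) {
      lg <- do.call(rbind, log_rows)
      lg <- lg[lg$epoch == ep, ]
      message(sprintf("epoch %d: d %.4f  g_adv %.4f  l1 %.4f", ep,
                      mean(lg$d_loss), mean(lg$g_adv), mean(lg$g_l1)))
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows)
         else data.frame(step = integer(), epoch = integer(),
                         d_loss = numeric(), g_adv = numeric(),
                         g_l1 = numeric(), g_total = numeric())
  list(model = gen, disc = disc, log = log)
}

#' Train one generator per non-input lead
#'
#' Trains 11 fully independent models (leads II, III, aVR, aVL, aVF, V1-V6),
#' each with a distinct seed derived from the master seed.
#'
#' @param config A [gan_config()] (its seed is the master seed).
#' @param cohort List of `ecg_record` objects with all 12 leads.
#' @param window_s Segmentation window in seconds.
#' @param verbose Print progress.
#' @return Named list of 11 `gan_generator` models keyed by target lead.
#' @export
train_all_leads <- function(config, cohort, window_s = 2.5, verbose = FALSE) {
  sc <- segment_cohort(cohort, window_s)
  xs <- t(vapply(sc$segments, function(s) s$signals["I", ],
                 numeric(config$input_len)))
  targets <- setdiff(ecg_leads(), "I")
  models <- vector("list", length(targets))
  names(models) <- targets
  for (j in seq_along(targets)) {
    lead <- targets[j]
    cfg <- config
    cfg$seed <- config$seed + j * 1009L   # distinct per-lead seeds
    ys <- t(vapply(sc$segments, function(s) s$signals[lead, ],
                   numeric(config$input_len)))
    if (verbose) message("training generator for lead ", lead)
    models[[lead]] <- train_gan(cfg, list(x = xs, y = ys),
                                target_lead = lead)$model
  }
  models
}

#' Assemble full 12-lead segments from lead I via the trained generators
#'
#' Channel 1 is the measured lead I passed through bit-exactly; channels
#' 2-12 are the per-lead generator outputs, in canonical lead order.
#'
#' @param models Named list of 11 `gan_generator` models (from
#'   [train_all_leads()]).
#' @param lead_i_segments Array `(B, 1, input_len)` or matrix
#'   `(B, input_len)` of measured lead I segments.
#' @param use_dropout Keep decoder dropout active during generation.
#' @return Array of shape `(B, 12, input_len)` with lead order
#'   `ecg_leads()`.
#' @export
generate_12lead <- function(models, lead_i_segments, use_dropout = TRUE) {
  targets <- setdiff(ecg_leads(), "I")
  missing <- setdiff(targets, names(models))
  if (length(missing))
    stop("missing generator model(s) for lead(s): ",
         paste(missing, collapse = ", "))
  if (is.matrix(lead_i_segments))
    lead_i_segments <- array(lead_i_segments,
                             c(nrow(lead_i_segments), 1L,
                               ncol(lead_i_segments)))
  d <- dim(lead_i_segments)
  B <- d[1]; L <- d[3]
  out <- array(0, c(B, 12L, L))
  out[, 1L, ] <- lead_i_segments[, 1L, ]
  for (j in seq_along(targets)) {
    g <- generator_forward(models[[targets[j]]], lead_i_segments,
                           use_dropout = use_dropout)
    out[, j + 1L, ] <- g[, 1L, ]
  }
  out
}
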