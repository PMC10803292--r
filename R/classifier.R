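# 1D residual-network six-class ECG classifier.
#
# The feasibility probe: the same architecture, hyperparameters and seed are
# used for every lead group, differing only in the number of input channels
# (1 or 12). Default plan is a ResNet-18 analogue: stem convolution (kernel
# 7, stride 2), four stages of two residual blocks with widths
# 64/128/256/512 (stride-2 downsampling at the start of stages 2-4, with a
# 1x1 projection on the skip path), global average pooling over time and a
# 6-way linear softmax head.

#' Classifier configuration
#'
#' @param channels Input channel count (1 or 12).
#' @param classes Number of classes (fixed at 6).
#' @param stem_width Width of the stem convolution.
#' @param stage_widths Widths of the residual stages.
#' @param blocks_per_stage Residual blocks per stage.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @param val_frac Patient fraction held out for validation (best-validation
#'   checkpoint selection).
#' @param input_len Segment length in samples.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(channels = 12L, classes = 6L, stem_width = 64L,
                              stage_widths = c(64L, 128L, 256L, 512L),
                              blocks_per_stage = 2L, lr = 1e-3,
                              batch_size = 32L, epochs = 20L, seed = 1L,
                              val_frac = 0.2, input_len = 1250L) {
  if (!channels %in% c(1L, 12L))
    stop("channels must be 1 or 12")
  if (classes != 6L) stop("class count is fixed at 6")
  obj <- list(channels = as.integer(channels), classes = 6L,
              stem_width = as.integer(stem_width),
              stage_widths = as.integer(stage_widths),
              blocks_per_stage = as.integer(blocks_per_stage),
              lr = lr, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed),
              val_frac = val_frac, input_len = as.integer(input_len))
  class(obj) <- "classifier_config"
  obj
}

res_block_new <- function(c_in, c_out, stride) {
  bl <- list(
    conv1 = nn_conv1d(c_in, c_out, k = 3L, stride = stride, pad = 1L,
                      init_sd = sqrt(2 / (c_in * 3))),
    bn1 = nn_bn1d(c_out),
    conv2 = nn_conv1d(c_out, c_out, k = 3L, stride = 1L, pad = 1L,
                      init_sd = sqrt(2 / (c_out * 3))),
    bn2 = nn_bn1d(c_out),
    proj = NULL, proj_bn = NULL
  )
  if (stride != 1L || c_in != c_out) {
    bl$proj <- nn_conv1d(c_in, c_out, k = 1L, stride = stride, pad = 0L,
                         init_sd = sqrt(2 / c_in))
    bl$proj_bn <- nn_bn1d(c_out)
  }
  bl
}

res_block_layers <- function(bl) {
  Filter(Negate(is.null),
         list(bl$conv1, bl$bn1, bl$conv2, bl$bn2, bl$proj, bl$proj_bn))
}

res_block_fwd <- function(bl, x, training, keep = TRUE) {
  c1 <- conv1d_fwd(bl$conv1, x, keep)
  b1 <- bn1d_fwd(bl$bn1, c1$y, training, keep)
  a1 <- relu_fwd(b1$y)
  c2 <- conv1d_fwd(bl$conv2, a1$y, keep)
  b2 <- bn1d_fwd(bl$bn2, c2$y, training, keep)
  if (is.null(bl$proj)) {
    skip <- x
    pc <- NULL; pb <- NULL
  } else {
    pc <- conv1d_fwd(bl$proj, x, keep)
    pb <- bn1d_fwd(bl$proj_bn, pc$y, training, keep)
    skip <- pb$y
  }
  a2 <- relu_fwd(b2$y + skip)
  cache <- if (keep) list(c1 = c1$cache, b1 = b1$cache, a1 = a1$cache,
                          c2 = c2$cache, b2 = b2$cache,
                          pc = if (is.null(pc)) NULL else pc$cache,
                          pb = if (is.null(pb)) NULL else pb$cache,
                          a2 = a2$cache) else NULL
  list(y = a2$y, cache = cache)
}

res_block_bwd <- function(bl, cache, dy) {
  dy <- relu_bwd(cache$a2, dy)
  # main branch
  h <- bn1d_bwd(bl$bn2, cache$b2, dy)
  h <- conv1d_bwd(bl$conv2, cache$c2, h)
  h <- relu_bwd(cache$a1, h)
  h <- bn1d_bwd(bl$bn1, cache$b1, h)
  dx <- conv1d_bwd(bl$conv1, cache$c1, h)
  # skip branch
  if (is.null(bl$proj)) {
    dx <- dx + dy
  } else {
    hs <- bn1d_bwd(bl$proj_bn, cache$pb, dy)
    dx <- dx + conv1d_bwd(bl$proj, cache$pc, hs)
  }
  dx
}

#' Build an untrained 1D ResNet classifier
#'
#' @param config A [classifier_config()].
#' @return An object of class `ecg_classifier`.
#' @export
classifier_new <- function(config) {
  stem <- nn_conv1d(config$channels, config$stem_width, k = 7L, stride = 2L,
                    pad = 3L, init_sd = sqrt(2 / (config$channels * 7)))
  stem_bn <- nn_bn1d(config$stem_width)
  stages <- list()
  c_in <- config$stem_width
  for (s in seq_along(config$stage_widths)) {
    w <- config$stage_widths[s]
    blocks <- list()
    for (b in seq_len(config$blocks_per_stage)) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blocks[[b]] <- res_block_new(c_in, w, stride)
      c_in <- w
    }
    stages[[s]] <- blocks
  }
  head <- nn_dense(c_in, config$classes)
  layers <- c(list(stem, stem_bn),
              unlist(lapply(stages, function(st)
                unlist(lapply(st, res_block_layers), recursive = FALSE)),
                recursive = FALSE),
              list(head))
  nn_zero_grad(layers)
  model <- list(config = config, stem = stem, stem_bn = stem_bn,
                stages = stages, head = head, layers = layers,
                adam = nn_adam_state(layers))
  class(model) <- "ecg_classifier"
  model
}

clf_fwd_internal <- function(model, x, training, keep = TRUE) {
  cv <- conv1d_fwd(model$stem, x, keep)
  bn <- bn1d_fwd(model$stem_bn, cv$y, training, keep)
  ac <- relu_fwd(bn$y)
  h <- ac$y
  stage_caches <- list()
  for (s in seq_along(model$stages)) {
    blk_caches <- list()
    for (b in seq_along(model$stages[[s]])) {
      r <- res_block_fwd(model$stages[[s]][[b]], h, training, keep)
      h <- r$y
      blk_caches[[b]] <- r$cache
    }
    stage_caches[[s]] <- blk_caches
  }
  d <- dim(h)                       # (C, L, B)
  g <- matrix(0, d[1], d[3])
  for (b in seq_len(d[3])) g[, b] <- rowMeans(h[, , b, drop = FALSE][, , 1])
  hd <- dense_fwd(model$head, g, keep)
  z <- hd$y                         # (classes, B)
  zs <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(zs)
  p <- sweep(ez, 2, colSums(ez), "/")
  cache <- if (keep) list(stem = cv$cache, stem_bn = bn$cache,
                          stem_act = ac$cache, stages = stage_caches,
                          gap_dims = d, head = hd$cache, p = p) else NULL
  list(p = p, cache = cache)
}

clf_bwd_internal <- function(model, cache, dz) {
  # dz: gradient wrt logits (classes, B)
  dg <- dense_bwd(model$head, cache$head, dz)
  d <- cache$gap_dims
  dh <- array(0, d)
  for (b in seq_len(d[3])) dh[, , b] <- dg[, b] / d[2]
  for (s in rev(seq_along(model$stages))) {
    for (b in rev(seq_along(model$stages[[s]]))) {
      dh <- res_block_bwd(model$stages[[s]][[b]], cache$stages[[s]][[b]], dh)
    }
  }
  dh <- relu_bwd(cache$stem_act, dh)
  dh <- bn1d_bwd(model$stem_bn, cache$stem_bn, dh)
  conv1d_bwd(model$stem, cache$stem, dh)
}

# coerce (B, C, L) public arrays to internal (C, L, B)
clf_internal_input <- function(model, segments) {
  d <- dim(segments)
  if (length(d) != 3L)
    stop("segments must be an array of shape (B, channels, input_len)")
  if (d[2] != model$config$channels)
    stop(sprintf("classifier expects %d channels, got %d",
                 model$config$channels, d[2]))
  if (d[3] != model$config$input_len)
    stop(sprintf("classifier expects length %d, got %d",
                 model$config$input_len, d[3]))
  aperm(segments, c(2, 3, 1))
}

#' Classifier forward pass
#'
#' @param model An `ecg_classifier`.
#' @param segments Array of shape `(B, channels, input_len)`.
#' @param training Batch-norm mode (evaluation mode by default, so outputs
#'   are batch-size invariant).
#' @return Matrix `(B, 6)` of class probabilities; rows sum to 1.
#' @export
classifier_forward <- function(model, segments, training = FALSE) {
  xi <- clf_internal_input(model, segments)
  out <- clf_fwd_internal(model, xi, training = training, keep = FALSE)
  p <- t(out$p)
  colnames(p) <- ecg_classes()
  p
}

#' Hard label prediction
#'
#' Argmax of the class probabilities; ties break to the lowest class index.
#'
#' @param model An `ecg_classifier`.
#' @param segments Array `(B, channels, input_len)`.
#' @return Character vector of class labels.
#' @export
predict_labels <- function(model, segments) {
  p <- classifier_forward(model, segments)
  ecg_classes()[max.col(p, ties.method = "first")]
}

#' Train the six-class classifier
#'
#' Cross-entropy minimization with Adam on a patient-disjoint
#' train/validation split; the parameters with the best validation loss are
#' returned. Aborts if any of the six classes is absent from the training
#' split.
#'
#' @param config A [classifier_config()].
#' @param segments Array `(N, channels, input_len)`.
#' @param labels Character vector of length N over `ecg_classes()`.
#' @param patient_ids Character vector of length N (validation split is by
#'   patient).
#' @param verbose Print per-epoch losses.
#' @return List with `model` (best checkpoint) and `history` (data.frame:
#'   epoch, train_loss, val_loss, val_acc).
#' @export
train_classifier <- function(config, segments, labels, patient_ids = NULL,
                             verbose = FALSE) {
  N <- dim(segments)[1]
  if (length(labels) != N) stop("labels must match segment count")
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(N))
  set.seed(config$seed)
  model <- classifier_new(config)
  if (config$epochs == 0L)
    return(list(model = model,
                history = data.frame(epoch = integer(), train_loss = numeric(),
                                     val_loss = numeric(), val_acc = numeric())))
  split <- split_by_patient(patient_ids, config$val_frac)
  tr <- which(split == "train"); va <- which(split == "test")
  if (length(va) == 0L) { va <- tr[1]; tr <- tr[-1] }
  classes <- ecg_classes()
  absent <- setdiff(classes, unique(labels[tr]))
  if (length(absent))
    stop("class absent from training data: ", paste(absent, collapse = ", "))
  y_idx <- match(labels, classes)
  best <- list(val = Inf, params = nn_get_params(model$layers))
  hist <- list()
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    tl <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      B <- length(idx)
      xb <- clf_internal_input(model, segments[idx, , , drop = FALSE])
      out <- clf_fwd_internal(model, xb, training = TRUE)
      p <- out$p
      onehot <- matrix(0, config$classes, B)
      onehot[cbind(y_idx[idx], seq_len(B))] <- 1
      loss <- -mean(log(pmax(p[cbind(y_idx[idx], seq_len(B))], 1e-12)))
      if (!is.finite(loss)) stop("NaN/Inf classifier loss at epoch ", ep)
      dz <- (p - onehot) / B
      nn_zero_grad(model$layers)
      clf_bwd_internal(model, out$cache, dz)
      nn_adam_step(model$layers, model$adam, config$lr, 0.9, 0.999)
      tl <- tl + loss; nb <- nb + 1L
    }
    # validation (eval mode, batched)
    vp <- predict_proba_internal(model, segments, va, config$batch_size)
    vl <- -mean(log(pmax(vp[cbind(y_idx[va], seq_along(va))], 1e-12)))
    vacc <- mean(max.col(t(vp), ties.method = "first") == y_idx[va])
    hist[[ep]] <- data.frame(epoch = ep, train_loss = tl / nb,
                             val_loss = vl, val_acc = vacc)
    if (vl < best$val) {
      best$val <- vl
      best$params <- nn_get_params(model$layers)
    }
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f acc %.3f",
                      ep, tl / nb, vl, vacc))
  }
  nn_set_params(model$layers, best$params)
  list(model = model, history = do.call(rbind, hist))
}

# probabilities (classes, n) for a subset of segment indices, eval mode
predict_proba_internal <- function(model, segments, idx, batch_size) {
  p <- matrix(0, model$config$classes, length(idx))
  for (start in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[start:min(start + batch_size - 1L, length(idx))]
    xb <- clf_internal_input(model, segments[sel, , , drop = FALSE])
    p[, start:(start + length(sel) - 1L)] <-
      clf_fwd_internal(model, xb, training = FALSE, keep = FALSE)$p
  }
  p
}
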