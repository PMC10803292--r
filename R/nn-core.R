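# Minimal 1D neural-network engine.
#
# Tensors use the internal layout (channels, length, batch) so that a batch
# flattens to a (C, L*B) matrix and convolutions become GEMMs on im2col
# matrices. Layers are environments holding parameters, Adam state and
# accumulated gradients (grad_* fields); backward passes accumulate so a
# parameter touched twice in one step (e.g. the discriminator seen on real
# and fake pairs) sums its gradients until nn_zero_grad() is called.

nn_out_len <- function(L, k, stride, pad) (L + 2L * pad - k) %/% stride + 1L

# ---- convolution -----------------------------------------------------------

nn_conv1d <- function(c_in, c_out, k = 4L, stride = 2L, pad = 1L, init_sd = 0.02) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv1d"
  ly$c_in <- as.integer(c_in); ly$c_out <- as.integer(c_out)
  ly$k <- as.integer(k); ly$stride <- as.integer(stride); ly$pad <- as.integer(pad)
  ly$W <- matrix(rnorm(c_out * c_in * k, 0, init_sd), c_out, c_in * k)
  ly$b <- numeric(c_out)
  ly$pnames <- c("W", "b")
  ly$idx_cache <- list()
  ly
}

# im2col gather index for one batch slice, cached per input length
conv_im2col_idx <- function(ly, L) {
  key <- as.character(L)
  idx <- ly$idx_cache[[key]]
  if (!is.null(idx)) return(idx)
  C <- ly$c_in; k <- ly$k
  Lp <- L + 2L * ly$pad
  L_out <- nn_out_len(L, k, ly$stride, ly$pad)
  idx <- matrix(0L, C * k, L_out)
  for (j in seq_len(k)) {
    spos <- (seq_len(L_out) - 1L) * ly$stride + j  # position in padded coords
    idx[((j - 1L) * C + 1L):(j * C), ] <- rep((spos - 1L) * C, each = C) + seq_len(C)
  }
  ly$idx_cache[[key]] <- idx
  idx
}

conv1d_fwd <- function(ly, x, keep = TRUE) {
  d <- dim(x)
  if (d[1] != ly$c_in)
    stop(sprintf("conv1d: expected %d input channels, got %d", ly$c_in, d[1]))
  C <- d[1]; L <- d[2]; B <- d[3]; p <- ly$pad
  Lp <- L + 2L * p
  if (p > 0L) {
    xp <- array(0, c(C, Lp, B))
    xp[, (p + 1L):(p + L), ] <- x
  } else xp <- x
  L_out <- nn_out_len(L, ly$k, ly$stride, p)
  idx <- conv_im2col_idx(ly, L)
  gather <- as.vector(idx) + rep((0:(B - 1L)) * (C * Lp), each = length(idx))
  M <- matrix(xp[gather], C * ly$k, L_out * B)
  y <- array(ly$W %*% M + ly$b, c(ly$c_out, L_out, B))
  cache <- if (keep) list(M = M, L = L, Lp = Lp, L_out = L_out, B = B) else NULL
  list(y = y, cache = cache)
}

conv1d_bwd <- function(ly, cache, dy) {
  C <- ly$c_in; k <- ly$k
  L_out <- cache$L_out; B <- cache$B; Lp <- cache$Lp
  dY <- matrix(dy, ly$c_out, L_out * B)
  ly$grad_W <- ly$grad_W + dY %*% t(cache$M)
  ly$grad_b <- ly$grad_b + rowSums(dY)
  dM <- crossprod(ly$W, dY)
  dxp <- array(0, c(C, Lp, B))
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * C + 1L):(j * C)
    spos <- (seq_len(L_out) - 1L) * ly$stride + j
    dxp[, spos, ] <- dxp[, spos, , drop = FALSE] +
      array(dM[rows, , drop = FALSE], c(C, L_out, B))
  }
  p <- ly$pad
  if (p > 0L) dxp[, (p + 1L):(p + cache$L), , drop = FALSE] else dxp
}

# ---- transposed convolution ------------------------------------------------

nn_convt1d <- function(c_in, c_out, k = 4L, stride = 2L, pad = 1L, init_sd = 0.02) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "convt1d"
  ly$c_in <- as.integer(c_in); ly$c_out <- as.integer(c_out)
  ly$k <- as.integer(k); ly$stride <- as.integer(stride); ly$pad <- as.integer(pad)
  ly$W <- matrix(rnorm(c_out * k * c_in, 0, init_sd), c_out * k, c_in)
  ly$b <- numeric(c_out)
  ly$pnames <- c("W", "b")
  ly
}

convt1d_fwd <- function(ly, x, keep = TRUE) {
  d <- dim(x)
  if (d[1] != ly$c_in)
    stop(sprintf("convt1d: expected %d input channels, got %d", ly$c_in, d[1]))
  C_in <- d[1]; L_in <- d[2]; B <- d[3]
  k <- ly$k; s <- ly$stride; p <- ly$pad; C_out <- ly$c_out
  x_mat <- matrix(x, C_in, L_in * B)
  U <- ly$W %*% x_mat                       # (C_out*k, L_in*B)
  L_full <- (L_in - 1L) * s + k
  yp <- array(0, c(C_out, L_full, B))
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * C_out + 1L):(j * C_out)
    spos <- (seq_len(L_in) - 1L) * s + j
    yp[, spos, ] <- yp[, spos, , drop = FALSE] +
      array(U[rows, , drop = FALSE], c(C_out, L_in, B))
  }
  L_out <- L_full - 2L * p
  y <- yp[, (p + 1L):(p + L_out), , drop = FALSE] + ly$b
  cache <- if (keep) list(x_mat = x_mat, L_in = L_in, L_full = L_full,
                          L_out = L_out, B = B) else NULL
  list(y = y, cache = cache)
}

convt1d_bwd <- function(ly, cache, dy) {
  k <- ly$k; s <- ly$stride; p <- ly$pad; C_out <- ly$c_out
  L_in <- cache$L_in; L_full <- cache$L_full; B <- cache$B
  dyp <- array(0, c(C_out, L_full, B))
  dyp[, (p + 1L):(p + cache$L_out), ] <- dy
  dU <- matrix(0, C_out * k, L_in * B)
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * C_out + 1L):(j * C_out)
    spos <- (seq_len(L_in) - 1L) * s + j
    dU[rows, ] <- matrix(dyp[, spos, , drop = FALSE], C_out, L_in * B)
  }
  ly$grad_W <- ly$grad_W + dU %*% t(cache$x_mat)
  ly$grad_b <- ly$grad_b + rowSums(matrix(dy, C_out, cache$L_out * B))
  array(crossprod(ly$W, dU), c(ly$c_in, L_in, B))
}

# ---- batch normalization ---------------------------------------------------

nn_bn1d <- function(C, eps = 1e-5, momentum = 0.1) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bn1d"
  ly$C <- as.integer(C); ly$eps <- eps; ly$momentum <- momentum
  ly$gamma <- rep(1, C); ly$beta <- numeric(C)
  ly$run_mean <- numeric(C); ly$run_var <- rep(1, C)
  ly$pnames <- c("gamma", "beta")
  ly
}

bn1d_fwd <- function(ly, x, training = TRUE, keep = TRUE) {
  d <- dim(x); C <- d[1]; N <- d[2] * d[3]
  xm <- matrix(x, C, N)
  if (training && N > 1L) {
    mu <- rowMeans(xm)
    cx <- xm - mu
    v <- rowMeans(cx * cx)
    invstd <- 1 / sqrt(v + ly$eps)
    xhat <- cx * invstd
    ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
    ly$run_var  <- (1 - ly$momentum) * ly$run_var  + ly$momentum * v
  } else {
    invstd <- 1 / sqrt(ly$run_var + ly$eps)
    xhat <- (xm - ly$run_mean) * invstd
  }
  y <- array(ly$gamma * xhat + ly$beta, d)
  cache <- if (keep) list(xhat = xhat, invstd = invstd, dims = d,
                          batch_stats = training && N > 1L) else NULL
  list(y = y, cache = cache)
}

bn1d_bwd <- function(ly, cache, dy) {
  d <- cache$dims; C <- d[1]; N <- d[2] * d[3]
  dym <- matrix(dy, C, N)
  xhat <- cache$xhat
  ly$grad_gamma <- ly$grad_gamma + rowSums(dym * xhat)
  ly$grad_beta  <- ly$grad_beta + rowSums(dym)
  dxhat <- dym * ly$gamma
  if (cache$batch_stats) {
    dx <- cache$invstd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    dx <- cache$invstd * dxhat
  }
  array(dx, d)
}

# ---- dense head ------------------------------------------------------------

nn_dense <- function(n_in, n_out, init_sd = NULL) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "dense"
  if (is.null(init_sd)) init_sd <- sqrt(2 / n_in)
  ly$W <- matrix(rnorm(n_out * n_in, 0, init_sd), n_out, n_in)
  ly$b <- numeric(n_out)
  ly$pnames <- c("W", "b")
  ly
}

dense_fwd <- function(ly, x, keep = TRUE) {
  y <- ly$W %*% x + ly$b
  list(y = y, cache = if (keep) list(x = x) else NULL)
}

dense_bwd <- function(ly, cache, dy) {
  ly$grad_W <- ly$grad_W + dy %*% t(cache$x)
  ly$grad_b <- ly$grad_b + rowSums(dy)
  crossprod(ly$W, dy)
}

# ---- activations / dropout -------------------------------------------------

lrelu_fwd <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, cache = list(neg = neg, slope = slope))
}

lrelu_bwd <- function(cache, dy) {
  dy[cache$neg] <- dy[cache$neg] * cache$slope
  dy
}

relu_fwd <- function(x) {
  neg <- x < 0
  x[neg] <- 0
  list(y = x, cache = list(neg = neg))
}

relu_bwd <- function(cache, dy) {
  dy[cache$neg] <- 0
  dy
}

dropout_fwd <- function(x, rate = 0.5, active = TRUE) {
  if (!active || rate <= 0) return(list(y = x, cache = list(mask = NULL)))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, cache = list(mask = mask))
}

dropout_bwd <- function(cache, dy) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- channel concat / length fitting ---------------------------------------

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

split_ch <- function(dy, c1) {
  list(dy[seq_len(c1), , , drop = FALSE],
       dy[-seq_len(c1), , , drop = FALSE])
}

# Crop (right) or zero-pad (right) the time axis to an exact target length;
# needed because stride-2 down/up sampling of odd lengths does not invert.
fit_len <- function(x, target) {
  L <- dim(x)[2]
  if (L == target) return(list(y = x, cache = list(L = L, target = target)))
  if (L > target) {
    y <- x[, seq_len(target), , drop = FALSE]
  } else {
    y <- array(0, c(dim(x)[1], target, dim(x)[3]))
    y[, seq_len(L), ] <- x
  }
  list(y = y, cache = list(L = L, target = target))
}

fit_len_bwd <- function(cache, dy) {
  L <- cache$L; target <- cache$target
  if (L == target) return(dy)
  if (L > target) {
    dx <- array(0, c(dim(dy)[1], L, dim(dy)[3]))
    dx[, seq_len(target), ] <- dy
    dx
  } else {
    dy[, seq_len(L), , drop = FALSE]
  }
}

# ---- optimizer -------------------------------------------------------------

nn_zero_grad <- function(layers) {
  for (ly in layers) {
    for (nm in ly$pnames) {
      g <- paste0("grad_", nm)
      ly[[g]] <- ly[[nm]] * 0
    }
  }
  invisible(NULL)
}

nn_adam_state <- function(layers) {
  for (ly in layers) {
    for (nm in ly$pnames) {
      ly[[paste0("m_", nm)]] <- ly[[nm]] * 0
      ly[[paste0("v_", nm)]] <- ly[[nm]] * 0
    }
  }
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st
}

nn_adam_step <- function(layers, state, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (ly in layers) {
    for (nm in ly$pnames) {
      g <- ly[[paste0("grad_", nm)]]
      m <- beta1 * ly[[paste0("m_", nm)]] + (1 - beta1) * g
      v <- beta2 * ly[[paste0("v_", nm)]] + (1 - beta2) * g * g
      ly[[paste0("m_", nm)]] <- m
      ly[[paste0("v_", nm)]] <- v
      ly[[nm]] <- ly[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  invisible(NULL)
}

# Snapshot / restore parameter values (used for best-checkpoint logic)
nn_get_params <- function(layers) {
  lapply(layers, function(ly) lapply(setNames(ly$pnames, ly$pnames), function(nm) ly[[nm]]))
}

nn_set_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    for (nm in names(snap[[i]])) layers[[i]][[nm]] <- snap[[i]][[nm]]
  }
  invisible(NULL)
}

# Stable digest of all parameters (determinism checks)
nn_param_digest <- function(layers) {
  v <- unlist(lapply(layers, function(ly)
    lapply(ly$pnames, function(nm) as.vector(ly[[nm]]))))
  sum(v * seq_along(v) %% 7919) + sum(abs(v))
}
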