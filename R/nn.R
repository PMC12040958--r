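# Minimal neural-network primitives for the conditional VAE: temporal and
# lead-collapsing 2D convolutions, batch normalization, ELU, average pooling,
# nearest-neighbour upsampling, a strided transposed temporal convolution,
# dense layers and Adam. All tensors are base-R arrays laid out
# [channel, lead, time, batch] (channel fastest), and every layer implements
# an explicit backward pass; gradients are validated against finite
# differences in the test suite. Hot paths reshape with `dim<-` (no copy)
# rather than matrix()/array().

# elu(x) = x for x > 0, exp(x) - 1 otherwise, computed branch-free
elu_fwd_r <- function(x) {
  y <- pmax(x, 0) + expm1(pmin(x, 0))
  dim(y) <- dim(x)
  y
}

# dy/dx through the forward output: 1 for y >= 0, y + 1 otherwise
elu_bwd_r <- function(dy, y) {
  g <- dy * (1 + pmin(y, 0))
  dim(g) <- dim(dy)
  g
}

as_mat <- function(x, nrow) {
  dim(x) <- c(nrow, length(x) / nrow)
  x
}

#' Temporal convolution over [C, L, T, N] tensors
#'
#' Kernel of odd width K applied along time with same padding, shared across
#' leads; weights `W` are [C_out, C_in, K], bias per output channel.
#' @noRd
conv_time_fwd_r <- function(x, W, b) {
  d <- dim(x); C_in <- d[1]; L <- d[2]; Tn <- d[3]; N <- d[4]
  K <- dim(W)[3]; C_out <- dim(W)[1]; pad <- (K - 1) / 2
  xp <- array(0, c(C_in, L, Tn + K - 1, N))
  xp[, , pad + seq_len(Tn), ] <- x
  M <- L * Tn * N
  out <- matrix(0, C_out, M)
  Wm <- W; dim(Wm) <- c(C_out, C_in * K)
  for (k in seq_len(K)) {
    sm <- as_mat(xp[, , k:(k + Tn - 1), , drop = FALSE], C_in)
    out <- out + Wm[, ((k - 1) * C_in + 1):(k * C_in), drop = FALSE] %*% sm
  }
  out <- out + b
  dim(out) <- c(C_out, L, Tn, N)
  list(out = out, xp = xp)
}

conv_time_bwd_r <- function(dout, xp, W) {
  dW <- array(0, dim(W)); K <- dim(W)[3]
  dp <- dim(xp); C_in <- dp[1]; L <- dp[2]; N <- dp[4]
  C_out <- dim(W)[1]
  Tn <- dp[3] - K + 1
  pad <- (K - 1) / 2
  dout_m <- as_mat(dout, C_out)
  db <- rowSums(dout_m)
  dxp <- array(0, dp)
  for (k in seq_len(K)) {
    sm <- as_mat(xp[, , k:(k + Tn - 1), , drop = FALSE], C_in)
    dW[, , k] <- tcrossprod(dout_m, sm)
    Wk <- W[, , k]; dim(Wk) <- c(C_out, C_in)
    contrib <- crossprod(Wk, dout_m)
    dim(contrib) <- c(C_in, L, Tn, N)
    rng <- k:(k + Tn - 1)
    dxp[, , rng, ] <- dxp[, , rng, , drop = FALSE] + contrib
  }
  list(dx = dxp[, , pad + seq_len(Tn), , drop = FALSE], dW = dW, db = db)
}

#' Batch normalization over the channel dimension
#'
#' Normalizes each channel across leads, time and batch. In training mode the
#' batch statistics are used and running statistics updated (momentum 0.1); in
#' eval mode the running statistics are used.
#' @noRd
bn_fwd_r <- function(x, gamma, beta, run_mean, run_var, training, momentum = 0.1,
                   eps = 1e-5) {
  C <- dim(x)[1]
  xm <- as_mat(x, C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd
  y <- gamma * xhat + beta
  dim(y) <- dim(x)
  list(out = y, xhat = xhat, istd = istd,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd_r <- function(dout, cache, gamma) {
  C <- dim(dout)[1]
  dy <- as_mat(dout, C)
  xhat <- cache$xhat; istd <- cache$istd
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- gamma * dy
  dx <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  dim(dx) <- dim(dout)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Average pooling along time by factor f
#' @noRd
pool_time_fwd_r <- function(x, f) {
  d <- dim(x); CL <- d[1] * d[2]; Tn <- d[3]; N <- d[4]
  stopifnot(Tn %% f == 0)
  dim(x) <- c(CL, f, (Tn / f) * N)
  acc <- x[, 1, ]
  for (p in 2:f) acc <- acc + x[, p, ]
  dim(acc) <- c(d[1], d[2], Tn / f, N)
  acc / f
}

pool_time_bwd_r <- function(dout, f) {
  d <- dim(dout); CL <- d[1] * d[2]; Tf <- d[3]; N <- d[4]
  dm <- as_mat(dout, CL) / f
  dxr <- array(0, c(CL, f, Tf * N))
  for (p in seq_len(f)) dxr[, p, ] <- dm
  dim(dxr) <- c(d[1], d[2], Tf * f, N)
  dxr
}

#' Nearest-neighbour upsampling along time by factor f
#' @noRd
upsample_time_fwd_r <- function(x, f) {
  d <- dim(x); CL <- d[1] * d[2]; Tn <- d[3]; N <- d[4]
  xm <- as_mat(x, CL)
  out <- array(0, c(CL, f, Tn * N))
  for (p in seq_len(f)) out[, p, ] <- xm
  dim(out) <- c(d[1], d[2], Tn * f, N)
  out
}

upsample_time_bwd_r <- function(dout, f) {
  d <- dim(dout); CL <- d[1] * d[2]; Tn <- d[3] / f; N <- d[4]
  dim(dout) <- c(CL, f, Tn * N)
  acc <- dout[, 1, ]
  for (p in 2:f) acc <- acc + dout[, p, ]
  dim(acc) <- c(d[1], d[2], Tn, N)
  acc
}

#' Strided transposed temporal convolution to the output beat
#'
#' Maps [C, 12, T', N] to [12, f*T', N]: each output phase p in 1..f is a
#' J-tap linear combination of the channels at neighbouring coarse time
#' steps, out[l, (t'-1)f+p, n] = sum_{c,j} W[c,p,j] h[c,l,t'+j-1,n] + b[l].
#' @noRd
deconv_out_fwd_r <- function(h, W, b_lead) {
  d <- dim(h); C <- d[1]; L <- d[2]; Tc <- d[3]; N <- d[4]
  f <- dim(W)[2]; J <- dim(W)[3]
  hp <- array(0, c(C, L, Tc + J - 1, N))
  hp[, , seq_len(Tc), ] <- h
  O <- array(0, c(L, f, Tc, N))
  hm <- vector("list", J)
  for (j in seq_len(J)) hm[[j]] <- as_mat(hp[, , j:(j + Tc - 1), , drop = FALSE], C)
  for (p in seq_len(f)) {
    acc <- crossprod(W[, p, 1, drop = TRUE], hm[[1]])
    for (j in seq.int(2, J)) acc <- acc + crossprod(W[, p, j, drop = TRUE], hm[[j]])
    dim(acc) <- c(L, Tc, N)
    O[, p, , ] <- acc
  }
  dim(O) <- c(L, f * Tc, N)
  list(out = O + as.numeric(b_lead), hp = hp)  # bias recycles down leads
}

deconv_out_bwd_r <- function(dout, hp, W) {
  dW <- array(0, dim(W))
  C <- dim(hp)[1]; L <- dim(dout)[1]; N <- dim(dout)[3]
  f <- dim(W)[2]; J <- dim(W)[3]
  Tc <- dim(hp)[3] - J + 1
  dO <- dout
  dim(dO) <- c(L, f, Tc, N)
  db_lead <- rowSums(as_mat(dout, L))
  dhp <- array(0, dim(hp))
  hm <- vector("list", J)
  for (j in seq_len(J)) hm[[j]] <- as_mat(hp[, , j:(j + Tc - 1), , drop = FALSE], C)
  for (p in seq_len(f)) {
    dv <- dO[, p, , , drop = FALSE]
    dim(dv) <- NULL
    for (j in seq_len(J)) {
      dW[, p, j] <- hm[[j]] %*% dv
      contrib <- tcrossprod(W[, p, j, drop = TRUE], dv)
      dim(contrib) <- c(C, L, Tc, N)
      rng <- j:(j + Tc - 1)
      dhp[, , rng, ] <- dhp[, , rng, , drop = FALSE] + contrib
    }
  }
  list(dh = dhp[, , seq_len(Tc), , drop = FALSE], dW = dW, db_lead = db_lead)
}

dense_fwd <- function(x, W, b) W %*% x + b

dense_bwd <- function(dout, x, W) {
  list(dx = crossprod(W, dout), dW = tcrossprod(dout, x), db = rowSums(dout))
}

#' One Adam update step over a named list of parameter arrays
#' @noRd
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, lr_mult = NULL) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    lr_nm <- if (!is.null(lr_mult) && nm %in% names(lr_mult)) lr * lr_mult[[nm]] else lr
    params[[nm]] <- params[[nm]] -
      lr_nm * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(t = 0, m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# Compiled fast paths (src/layers.cpp); the _r suffixed functions above are
# the pure-R reference implementations the compiled kernels are tested
# against (note bn_fwd/bn_bwd use a leaner cache contract than bn_fwd_r).
conv_time_fwd <- function(x, W, b) conv_time_fwd_cpp(x, W, b)
conv_time_bwd <- function(dout, xp, W) conv_time_bwd_cpp(dout, xp, W)
deconv_out_fwd <- function(h, W, b_lead) deconv_out_fwd_cpp(h, W, b_lead)
deconv_out_bwd <- function(dout, hp, W) deconv_out_bwd_cpp(dout, hp, W)
elu_fwd <- function(x) elu_fwd_cpp(x)
elu_bwd <- function(dy, y) elu_bwd_cpp(dy, y)
pool_time_fwd <- function(x, f) pool_time_fwd_cpp(x, f)
pool_time_bwd <- function(dout, f) pool_time_bwd_cpp(dout, f)
upsample_time_fwd <- function(x, f) upsample_time_fwd_cpp(x, f)
upsample_time_bwd <- function(dout, f) upsample_time_bwd_cpp(dout, f)
bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  bn_fwd_cpp(x, gamma, beta, run_mean, run_var, training, momentum, eps)
}
bn_bwd <- function(dout, x, mu, istd, gamma) bn_bwd_cpp(dout, x, mu, istd, gamma)
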