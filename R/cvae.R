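# Conditional variational autoencoder for 12x400 median beats.
#
# Encoder: two convolutional blocks (2D convolution, batch normalization,
# ELU), average pooling, flatten; the condition vector is concatenated to the
# flattened features before the two fully connected layers producing the
# 64-dimensional posterior mean and log-variance. Decoder mirrors it: the
# condition is concatenated to z before the first fully connected layer,
# followed by upsampling, a lead-expanding deconvolution and a strided
# transposed temporal convolution back to 12x400. An optional risk head
# (single dense layer + sigmoid on the latent) turns the model into a joint
# generative/survival network.

#' Model configuration
#'
#' Hyperparameters of the conditional VAE. The convolutional sizes are design
#' defaults chosen for 12x400 inputs on a single CPU core; all are
#' configurable.
#'
#' @param latent_dim latent dimensionality (default 64)
#' @param conv_channels channels of the two encoder conv blocks (default
#'   c(8, 16), sized for single-CPU training on 12x400 beats)
#' @param kernel temporal kernel widths of the two blocks (default c(7, 5);
#'   the first block convolves each lead separately, the second spans all 12
#'   leads)
#' @param pool average-pooling factor after each block (default 4)
#' @param learning_rate Adam learning rate (default 0.001)
#' @param batch_size minibatch size (default 64)
#' @param epochs training epochs (default 80)
#' @param beta weight on the KL term (default 1: the equally weighted
#'   objective)
#' @param loss_weights weights of (reconstruction, KL, survival) in the joint
#'   objective (default c(1, 1, 1))
#' @param signal_scale beats are divided by this raw-unit scale before
#'   entering the loss (default 4, i.e. the model works in 0.04 mV units; see
#'   the methods vignette for how this balances reconstruction against the
#'   KL regularizer at the fixed equal loss weights)
#' @param risk_lr_mult learning-rate multiplier for the risk head (default
#'   10; the sigmoid bounds its gradients well below those of the
#'   reconstruction path)
#' @param seed seed governing initialization, shuffling and sampling
#' @return object of class `cvae_config`
#' @export
cvae_config <- function(latent_dim = 64, conv_channels = c(8, 16),
                        kernel = c(7, 5), pool = 4, learning_rate = 0.001,
                        batch_size = 64, epochs = 80, beta = 1,
                        loss_weights = c(1, 1, 1), signal_scale = 4,
                        risk_lr_mult = 10, seed = 1) {
  stopifnot(latent_dim >= 1, epochs >= 1, length(conv_channels) == 2,
            all(kernel %% 2 == 1), pool >= 1, signal_scale > 0)
  structure(list(latent_dim = latent_dim, conv_channels = conv_channels,
                 kernel = kernel, pool = pool, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs, beta = beta,
                 loss_weights = loss_weights, signal_scale = signal_scale,
                 risk_lr_mult = risk_lr_mult, seed = seed),
            class = "cvae_config")
}

glorot <- function(dims, fan_in, fan_out) {
  array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (fan_in + fan_out)), dims)
}

#' Initialize a conditional VAE
#'
#' @param config `cvae_config`
#' @param cond_dim condition-vector length (0 for an unconditional VAE)
#' @param schema optional named vector of condition block sizes
#' @return untrained model of class `cvae_model`
#' @export
cvae_init <- function(config = cvae_config(), cond_dim = 0, schema = NULL) {
  C1 <- config$conv_channels[1]; C2 <- config$conv_channels[2]
  K1 <- config$kernel[1]; K2 <- config$kernel[2]
  f <- config$pool
  Tc <- 400 / (f * f)              # coarse time length after two pools
  flat <- C2 * Tc
  ld <- config$latent_dim
  c_dim <- cond_dim
  with_seed(config$seed, {
    params <- list(
      W1 = glorot(c(C1, 1, K1), K1, C1 * K1),
      b1 = numeric(C1),
      g1 = rep(1, C1), be1 = numeric(C1),
      W2 = glorot(c(C2, C1 * 12, K2), C1 * 12 * K2, C2 * K2),
      b2 = numeric(C2),
      g2 = rep(1, C2), be2 = numeric(C2),
      Wmu = glorot(c(ld, flat + c_dim), flat + c_dim, ld),
      bmu = numeric(ld),
      Wlv = glorot(c(ld, flat + c_dim), flat + c_dim, ld),
      blv = numeric(ld),
      Wd = glorot(c(flat, ld + c_dim), ld + c_dim, flat),
      bd = numeric(flat),
      We = glorot(c(C1 * 12, C2, K2), C2 * K2, C1 * 12 * K2),
      be = numeric(C1 * 12),
      Wt = glorot(c(C1, f, 2), C1 * 2, f),
      bt = numeric(12),
      w_risk = numeric(ld),
      b_risk = 0)
    # start the log-variance head near a unit-variance posterior
    params$Wlv <- params$Wlv * 0.1
  })
  structure(list(config = config, cond_dim = c_dim, schema = schema,
                 params = params,
                 bn = list(m1 = numeric(C1), v1 = rep(1, C1),
                           m2 = numeric(C2), v2 = rep(1, C2)),
                 cond_mean = numeric(c_dim), cond_sd = rep(1, c_dim),
                 trained = FALSE, history = NULL),
            class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  cat(sprintf("<cvae_model> latent %d, cond %d, conv (%d, %d), %s\n",
              x$config$latent_dim, x$cond_dim, x$config$conv_channels[1],
              x$config$conv_channels[2],
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

std_cond <- function(model, cond) {
  if (model$cond_dim == 0) return(matrix(0, nrow(cond), 0))
  sweep(sweep(cond, 2, model$cond_mean), 2, model$cond_sd, `/`)
}

check_cond <- function(model, cond, n) {
  if (is.null(cond)) cond <- matrix(0, n, 0)
  if (!is.matrix(cond)) cond <- matrix(cond, nrow = 1)
  if (ncol(cond) != model$cond_dim || nrow(cond) != n || !all(is.finite(cond))) {
    abort_ecgvae(sprintf("condition must be %d x %d and finite", n, model$cond_dim),
                 "condition_schema_mismatch")
  }
  cond
}

# beats: N x 12 x 400 array (or 12 x 400 matrix) -> [1, 12, 400, N] tensor
beats_to_tensor <- function(beats) {
  if (is.matrix(beats)) beats <- array(beats, c(1, dim(beats)))
  d <- dim(beats)
  if (length(d) != 3 || d[2] != 12 || d[3] != 400) {
    abort_ecgvae("beats must be N x 12 x 400", "shape_mismatch")
  }
  array(aperm(beats, c(2, 3, 1)), c(1, 12, 400, d[1]))
}

tensor_to_beats <- function(x) {
  # [12, 400, N] -> N x 12 x 400
  aperm(x, c(3, 1, 2))
}

encoder_fwd <- function(model, x, cond_std, training = FALSE) {
  p <- model$params; cfg <- model$config
  N <- dim(x)[4]
  c1 <- conv_time_fwd(x, p$W1, p$b1)
  bn1 <- bn_fwd(c1$out, p$g1, p$be1, model$bn$m1, model$bn$v1, training)
  a1 <- elu_fwd(bn1$out)
  p1 <- pool_time_fwd(a1, cfg$pool)
  d1 <- dim(p1)
  p1r <- array(p1, c(d1[1] * 12, 1, d1[3], N))   # fold leads into channels
  c2 <- conv_time_fwd(p1r, p$W2, p$b2)
  bn2 <- bn_fwd(c2$out, p$g2, p$be2, model$bn$m2, model$bn$v2, training)
  a2 <- elu_fwd(bn2$out)
  p2 <- pool_time_fwd(a2, cfg$pool)
  flat <- matrix(p2, ncol = N)                    # [C2*Tc, N]
  hin <- rbind(flat, t(cond_std))                 # concat condition
  mu <- dense_fwd(hin, p$Wmu, p$bmu)
  lv <- dense_fwd(hin, p$Wlv, p$blv)
  list(mu = mu, lv = lv,
       cache = list(x = x, c1 = c1, bn1 = bn1[c("mu", "istd")], a1 = a1,
                    p1dim = dim(p1), p1r = p1r, c2 = c2,
                    bn2 = bn2[c("mu", "istd")], a2 = a2, p2dim = dim(p2),
                    hin = hin),
       bn_new = list(m1 = bn1$run_mean, v1 = bn1$run_var,
                     m2 = bn2$run_mean, v2 = bn2$run_var))
}

decoder_fwd <- function(model, z, cond_std) {
  p <- model$params; cfg <- model$config
  N <- ncol(z)
  C1 <- cfg$conv_channels[1]; C2 <- cfg$conv_channels[2]
  f <- cfg$pool; Tc <- 400 / (f * f)
  zin <- rbind(z, t(cond_std))
  h1 <- dense_fwd(zin, p$Wd, p$bd)
  a1 <- elu_fwd(h1)
  h4 <- array(a1, c(C2, 1, Tc, N))
  u1 <- upsample_time_fwd(h4, f)                  # [C2, 1, Tc*f, N]
  e1 <- conv_time_fwd(u1, p$We, p$be)             # [C1*12, 1, Tc*f, N]
  e1r <- array(e1$out, c(C1, 12, Tc * f, N))
  a2 <- elu_fwd(e1r)
  dc <- deconv_out_fwd(a2, p$Wt, p$bt)            # [12, 400, N]
  list(out = dc$out,
       cache = list(zin = zin, h1 = h1, a1 = a1, h4dim = dim(h4), u1 = u1,
                    e1 = e1, a2 = a2, dc = dc, N = N))
}

decoder_bwd <- function(model, dout, cache) {
  p <- model$params; cfg <- model$config
  C1 <- cfg$conv_channels[1]
  f <- cfg$pool
  g <- list()
  bdc <- deconv_out_bwd(dout, cache$dc$hp, p$Wt)
  g$Wt <- bdc$dW; g$bt <- bdc$db_lead
  da2 <- elu_bwd(bdc$dh, cache$a2)
  da2r <- array(da2, c(C1 * 12, 1, dim(da2)[3], dim(da2)[4]))
  be1 <- conv_time_bwd(da2r, cache$e1$xp, p$We)
  g$We <- be1$dW; g$be <- be1$db
  du1 <- upsample_time_bwd(be1$dx, f)
  da1 <- elu_bwd(matrix(du1, ncol = cache$N), cache$a1)
  bd1 <- dense_bwd(da1, cache$zin, p$Wd)
  g$Wd <- bd1$dW; g$bd <- bd1$db
  ld <- cfg$latent_dim
  list(grads = g, dz = bd1$dx[seq_len(ld), , drop = FALSE])
}

encoder_bwd <- function(model, dmu, dlv, cache) {
  p <- model$params; cfg <- model$config
  g <- list()
  bmu <- dense_bwd(dmu, cache$hin, p$Wmu)
  blv <- dense_bwd(dlv, cache$hin, p$Wlv)
  g$Wmu <- bmu$dW; g$bmu <- bmu$db
  g$Wlv <- blv$dW; g$blv <- blv$db
  dhin <- bmu$dx + blv$dx
  flat_len <- prod(cache$p2dim[1:3])
  dflat <- dhin[seq_len(flat_len), , drop = FALSE]
  dp2 <- array(dflat, cache$p2dim)
  da2 <- pool_time_bwd(dp2, cfg$pool)
  dbn2 <- elu_bwd(da2, cache$a2)
  b2 <- bn_bwd(dbn2, cache$c2$out, cache$bn2$mu, cache$bn2$istd, p$g2)
  g$g2 <- b2$dgamma; g$be2 <- b2$dbeta
  bc2 <- conv_time_bwd(b2$dx, cache$c2$xp, p$W2)
  g$W2 <- bc2$dW; g$b2 <- bc2$db
  dp1 <- array(bc2$dx, cache$p1dim)
  da1 <- pool_time_bwd(dp1, cfg$pool)
  dbn1 <- elu_bwd(da1, cache$a1)
  b1 <- bn_bwd(dbn1, cache$c1$out, cache$bn1$mu, cache$bn1$istd, p$g1)
  g$g1 <- b1$dgamma; g$be1 <- b1$dbeta
  bc1 <- conv_time_bwd(b1$dx, cache$c1$xp, p$W1)
  g$W1 <- bc1$dW; g$b1 <- bc1$db
  g
}

#' Encode beats to the latent posterior
#'
#' Deterministic in evaluation mode (batch-normalization running statistics).
#'
#' @param model `cvae_model`
#' @param beats N x 12 x 400 array (or a single 12 x 400 matrix), raw units
#' @param cond N x c condition matrix matching the model's schema (NULL when
#'   `cond_dim` is 0)
#' @return list with `mu` and `logvar`, each N x latent_dim
#' @export
encode <- function(model, beats, cond = NULL) {
  stopifnot(inherits(model, "cvae_model"))
  x <- beats_to_tensor(beats) / model$config$signal_scale
  N <- dim(x)[4]
  cond <- check_cond(model, cond, N)
  enc <- encoder_fwd(model, x, std_cond(model, cond), training = FALSE)
  list(mu = t(enc$mu), logvar = t(enc$lv))
}

#' Sample the latent with the reparameterization trick
#'
#' z = mu + exp(logvar / 2) * eps with eps ~ N(0, I).
#'
#' @param state list with `mu` and `logvar` (N x latent_dim)
#' @param seed RNG seed for the draw
#' @return N x latent_dim matrix of latent samples
#' @export
reparameterize <- function(state, seed = 1) {
  mu <- state$mu; lv <- state$logvar
  if (is.null(dim(mu))) { mu <- matrix(mu, 1); lv <- matrix(lv, 1) }
  eps <- with_seed(seed, matrix(stats::rnorm(length(mu)), nrow(mu)))
  mu + exp(lv / 2) * eps
}

#' Decode latent samples into beats
#'
#' @param model `cvae_model`
#' @param z N x latent_dim matrix (or a single latent vector)
#' @param cond N x c condition matrix
#' @return N x 12 x 400 array of beats in raw units
#' @export
decode <- function(model, z, cond = NULL) {
  stopifnot(inherits(model, "cvae_model"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$config$latent_dim || !all(is.finite(z))) {
    abort_ecgvae("z must be N x latent_dim and finite", "shape_mismatch")
  }
  N <- nrow(z)
  cond <- check_cond(model, cond, N)
  dec <- decoder_fwd(model, t(z), std_cond(model, cond))
  tensor_to_beats(dec$out) * model$config$signal_scale
}

#' Closed-form KL divergence to the standard-normal prior
#'
#' (1/2) sum_i (mu_i^2 + exp(logvar_i) - 1 - logvar_i), summed over latent
#' dimensions; for a batch, the mean of the per-example sums.
#'
#' @param state list with `mu` and `logvar` (vectors or N x d matrices)
#' @return scalar, non-negative
#' @export
kl_loss <- function(state) {
  mu <- state$mu; lv <- state$logvar
  if (is.null(dim(mu))) { mu <- matrix(mu, 1); lv <- matrix(lv, 1) }
  per <- 0.5 * rowSums(mu^2 + exp(lv) - 1 - lv)
  mean(per)
}

#' Mean-squared-error reconstruction loss
#'
#' Mean over all 12 x 400 entries (and over the batch) of the squared
#' difference.
#'
#' @param x,x_hat arrays of identical shape
#' @return scalar, non-negative
#' @export
recon_loss <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)) || !identical(length(x), length(x_hat))) {
    abort_ecgvae("x and x_hat must have identical shape", "shape_mismatch")
  }
  mean((x - x_hat)^2)
}

#' Risk score from a latent vector
#'
#' Single dense layer with sigmoid output: r = sigmoid(w . z + b), the model's
#' bounded log-relative-hazard surrogate.
#'
#' @param model `cvae_model`
#' @param z N x latent_dim matrix (typically the posterior mean)
#' @return numeric vector of risks in (0, 1)
#' @export
risk_head <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  as.numeric(stats::plogis(z %*% model$params$w_risk + model$params$b_risk))
}

#' Risk scores for beats
#'
#' Encodes the beats and applies the risk head to the posterior mean (not a
#' stochastic sample), removing sampling noise from reported risks.
#'
#' @param model trained `cvae_model`
#' @param beats N x 12 x 400 array, raw units
#' @param cond condition matrix
#' @return numeric vector of risks in (0, 1)
#' @export
risk_score <- function(model, beats, cond = NULL) {
  risk_head(model, encode(model, beats, cond)$mu)
}

#' Train the conditional VAE
#'
#' Minimizes reconstruction + beta * KL (+ survival when `records` is given,
#' with the configured loss weights) with Adam, shuffled seeded minibatches
#' and within-batch Cox risk sets. Conditions are standardized (zero mean,
#' unit scale) over the training set; the statistics are stored in the model.
#'
#' @param beats N x 12 x 400 array of median beats, raw units
#' @param cond N x c condition matrix (NULL for an unconditional VAE)
#' @param config `cvae_config`
#' @param records optional survival data.frame (`time`, `event`) aligned with
#'   the beats; enables the joint survival objective
#' @param schema optional named condition block sizes, stored for provenance
#' @param verbose print per-epoch losses
#' @return trained `cvae_model` with a `history` data.frame (epoch, recon,
#'   kl, surv)
#' @export
train_cvae <- function(beats, cond = NULL, config = cvae_config(),
                       records = NULL, schema = NULL, verbose = FALSE) {
  d <- dim(beats)
  if (length(d) != 3 || d[2] != 12 || d[3] != 400) {
    abort_ecgvae("beats must be N x 12 x 400", "shape_mismatch")
  }
  N <- d[1]
  if (N < 2 * config$batch_size) abort_ecgvae("need at least 2 batches of data", "data_too_small")
  if (is.null(cond)) cond <- matrix(0, N, 0)
  cond <- as.matrix(cond)
  if (!is.null(records)) stopifnot(nrow(records) == N)
  model <- cvae_init(config, cond_dim = ncol(cond), schema = schema)
  if (ncol(cond) > 0) {
    model$cond_mean <- colMeans(cond)
    sds <- apply(cond, 2, stats::sd)
    model$cond_sd <- ifelse(is.na(sds) | sds < 1e-12, 1, sds)
  }
  cs_all <- std_cond(model, cond)
  x_all <- beats_to_tensor(beats) / config$signal_scale
  joint <- !is.null(records)
  lw <- config$loss_weights
  state <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), recon = numeric(0), kl = numeric(0),
                     surv = numeric(0))
  ld <- config$latent_dim
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + 1000L + ep, sample.int(N))
    ep_rec <- ep_kl <- ep_surv <- 0; nb <- 0
    starts <- seq(1, N, by = config$batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, N)]
      nB <- length(idx)
      if (nB < 2) next
      xb <- x_all[, , , idx, drop = FALSE]
      cb <- cs_all[idx, , drop = FALSE]
      enc <- encoder_fwd(model, xb, cb, training = TRUE)
      model$bn <- enc$bn_new
      eps <- with_seed(config$seed + 5000L * ep + bi,
                       matrix(stats::rnorm(ld * nB), ld, nB))
      sd_z <- exp(enc$lv / 2)
      z <- enc$mu + sd_z * eps
      dec <- decoder_fwd(model, z, cb)
      xt <- array(xb, dim(dec$out))
      resid <- dec$out - xt
      l_rec <- mean(resid^2)
      l_kl <- mean(0.5 * colSums(enc$mu^2 + exp(enc$lv) - 1 - enc$lv))
      # gradients
      dout <- 2 * resid / length(resid)                      # d l_rec
      dout <- dout * lw[1]
      bdec <- decoder_bwd(model, dout, dec$cache)
      dz <- bdec$dz
      l_surv <- 0
      dmu_surv <- 0
      if (joint) {
        # the risk head reads the posterior mean: the survival gradient is
        # then free of reparameterization noise (evaluation also scores mu)
        rb <- records[idx, , drop = FALSE]
        srisk <- as.numeric(crossprod(enc$mu, model$params$w_risk)) + model$params$b_risk
        r <- stats::plogis(srisk)
        if (sum(rb$event) > 0) {
          l_surv <- cox_loss(r, rb)
          dr <- cox_loss_grad(r, rb) * lw[3]
          ds <- dr * r * (1 - r)
          bdec$grads$w_risk <- as.numeric(enc$mu %*% ds)
          bdec$grads$b_risk <- sum(ds)
          dmu_surv <- model$params$w_risk %o% ds
        } else {
          bdec$grads$w_risk <- numeric(ld)
          bdec$grads$b_risk <- 0
        }
      } else {
        bdec$grads$w_risk <- numeric(ld)
        bdec$grads$b_risk <- 0
      }
      kb <- config$beta * lw[2]
      dmu <- dz + dmu_surv + kb * enc$mu / nB
      dlv <- dz * eps * sd_z / 2 + kb * 0.5 * (exp(enc$lv) - 1) / nB
      genc <- encoder_bwd(model, dmu, dlv, enc$cache)
      grads <- c(genc, bdec$grads)
      grads <- grads[names(model$params)]
      upd <- adam_step(model$params, grads, state, config$learning_rate,
                       lr_mult = list(w_risk = config$risk_lr_mult,
                                      b_risk = config$risk_lr_mult))
      model$params <- upd$params
      state <- upd$state
      ep_rec <- ep_rec + l_rec; ep_kl <- ep_kl + l_kl; ep_surv <- ep_surv + l_surv
      nb <- nb + 1
    }
    hist <- rbind(hist, data.frame(epoch = ep, recon = ep_rec / nb,
                                   kl = ep_kl / nb, surv = ep_surv / nb))
    if (verbose) {
      message(sprintf("epoch %3d  recon %.5f  kl %.3f  surv %.4f",
                      ep, ep_rec / nb, ep_kl / nb, ep_surv / nb))
    }
  }
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Jointly train the cVAE with the Cox risk head
#'
#' Convenience wrapper around [train_cvae()] with survival records required.
#'
#' @inheritParams train_cvae
#' @param records survival data.frame with `time` and `event`, aligned with
#'   the beats
#' @return trained `cvae_model`
#' @export
train_joint <- function(beats, cond, records, config = cvae_config(),
                        schema = NULL, verbose = FALSE) {
  stopifnot(!is.null(records))
  train_cvae(beats, cond, config, records = records, schema = schema,
             verbose = verbose)
}

#' Generate beats for a condition
#'
#' Draws z ~ N(0, I) and decodes with the given condition.
#'
#' @param model trained `cvae_model`
#' @param cond a single condition vector (length `cond_dim`)
#' @param n number of beats
#' @param seed RNG seed
#' @return n x 12 x 400 array of generated beats, raw units
#' @export
generate <- function(model, cond = NULL, n = 1, seed = 1) {
  stopifnot(inherits(model, "cvae_model"))
  if (!model$trained) abort_ecgvae("model is untrained", "untrained_model")
  z <- with_seed(seed, matrix(stats::rnorm(n * model$config$latent_dim), n))
  cm <- if (model$cond_dim > 0) {
    matrix(rep(as.numeric(cond), each = n), n)
  } else NULL
  decode(model, z, cm)
}

#' Save a model checkpoint
#'
#' Single-file archive holding the configuration, weights, batch-norm running
#' statistics, condition schema and normalization statistics.
#'
#' @param model `cvae_model`
#' @param path output file (RDS)
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()]
#' @return `cvae_model`
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "cvae_model")
}
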