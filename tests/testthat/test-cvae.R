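# Conditional VAE: layer gradients, losses, reparameterization, determinism
# and training behaviour on small cohorts.

test_that("compiled layer kernels match the pure-R reference implementations", {
  set.seed(71)
  x <- array(stats::rnorm(3 * 12 * 40 * 5), c(3, 12, 40, 5))
  W <- array(stats::rnorm(4 * 3 * 7), c(4, 3, 7)); b <- stats::rnorm(4)
  f1 <- ecgvae:::conv_time_fwd_r(x, W, b)
  f2 <- ecgvae:::conv_time_fwd_cpp(x, W, b)
  expect_equal(f2$out, f1$out, tolerance = 1e-12)
  dout <- array(stats::rnorm(length(f1$out)), dim(f1$out))
  g1 <- ecgvae:::conv_time_bwd_r(dout, f1$xp, W)
  g2 <- ecgvae:::conv_time_bwd_cpp(dout, f2$xp, W)
  expect_equal(g2$dx, g1$dx, tolerance = 1e-12)
  expect_equal(g2$dW, g1$dW, tolerance = 1e-10)
  expect_equal(g2$db, g1$db, tolerance = 1e-10)

  h <- array(stats::rnorm(4 * 12 * 25 * 5), c(4, 12, 25, 5))
  Wd <- array(stats::rnorm(4 * 4 * 2), c(4, 4, 2)); bl <- stats::rnorm(12)
  d1 <- ecgvae:::deconv_out_fwd_r(h, Wd, bl)
  d2 <- ecgvae:::deconv_out_fwd_cpp(h, Wd, bl)
  expect_equal(d2$out, d1$out, tolerance = 1e-12)
  dd <- array(stats::rnorm(length(d1$out)), dim(d1$out))
  q1 <- ecgvae:::deconv_out_bwd_r(dd, d1$hp, Wd)
  q2 <- ecgvae:::deconv_out_bwd_cpp(dd, d2$hp, Wd)
  expect_equal(q2$dh, q1$dh, tolerance = 1e-12)
  expect_equal(q2$dW, q1$dW, tolerance = 1e-10)

  expect_equal(ecgvae:::elu_fwd_cpp(x), ecgvae:::elu_fwd_r(x), tolerance = 1e-14)
  expect_equal(ecgvae:::pool_time_fwd_cpp(x, 4L), ecgvae:::pool_time_fwd_r(x, 4),
               tolerance = 1e-14)
  expect_equal(ecgvae:::upsample_time_fwd_cpp(x, 3L),
               ecgvae:::upsample_time_fwd_r(x, 3), tolerance = 1e-14)
  bf1 <- ecgvae:::bn_fwd_r(x, rep(1.2, 3), rep(0.1, 3), numeric(3), rep(1, 3), TRUE)
  bf2 <- ecgvae:::bn_fwd_cpp(x, rep(1.2, 3), rep(0.1, 3), numeric(3), rep(1, 3),
                             TRUE, 0.1, 1e-5)
  expect_equal(bf2$out, bf1$out, tolerance = 1e-12)
  expect_equal(bf2$run_mean, bf1$run_mean, tolerance = 1e-12)
})

test_that("whole-model analytic gradients match finite differences", {
  set.seed(72)
  cfg <- cvae_config(latent_dim = 5, conv_channels = c(3, 4), seed = 3,
                     signal_scale = 1)
  model <- cvae_init(cfg, cond_dim = 2)
  N <- 3
  x <- array(stats::rnorm(N * 12 * 400), c(1, 12, 400, N))
  cs <- matrix(stats::rnorm(N * 2), N, 2)
  eps <- matrix(stats::rnorm(5 * N), 5, N)
  recs <- data.frame(time = c(5, 2, 9), event = c(1, 1, 0))
  loss_fn <- function(params) {
    m <- model; m$params <- params
    enc <- ecgvae:::encoder_fwd(m, x, cs, training = TRUE)
    z <- enc$mu + exp(enc$lv / 2) * eps
    dec <- ecgvae:::decoder_fwd(m, z, cs)
    r <- stats::plogis(as.numeric(crossprod(z, params$w_risk)) + params$b_risk)
    mean((dec$out - array(x, dim(dec$out)))^2) +
      mean(0.5 * colSums(enc$mu^2 + exp(enc$lv) - 1 - enc$lv)) +
      cox_loss(r, recs)
  }
  m <- model
  enc <- ecgvae:::encoder_fwd(m, x, cs, training = TRUE)
  sd_z <- exp(enc$lv / 2); z <- enc$mu + sd_z * eps
  dec <- ecgvae:::decoder_fwd(m, z, cs)
  resid <- dec$out - array(x, dim(dec$out))
  bdec <- ecgvae:::decoder_bwd(m, 2 * resid / length(resid), dec$cache)
  dz <- bdec$dz
  r <- stats::plogis(as.numeric(crossprod(z, m$params$w_risk)) + m$params$b_risk)
  ds <- cox_loss_grad(r, recs) * r * (1 - r)
  bdec$grads$w_risk <- as.numeric(z %*% ds)
  bdec$grads$b_risk <- sum(ds)
  dz <- dz + m$params$w_risk %o% ds
  genc <- ecgvae:::encoder_bwd(m, dz + enc$mu / N,
                               dz * eps * sd_z / 2 + 0.5 * (exp(enc$lv) - 1) / N,
                               enc$cache)
  grads <- c(genc, bdec$grads)
  h <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    idx <- sample(length(p), min(3, length(p)))
    for (i in idx) {
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      # absolute floor absorbs FD noise on near-zero gradients (e.g. conv
      # biases made irrelevant by the following batch norm)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("kl_loss closed form: exact values and Monte-Carlo agreement", {
  expect_identical(kl_loss(list(mu = numeric(4), logvar = numeric(4))), 0)
  st <- list(mu = c(2, 0), logvar = c(0, 0))
  expect_equal(kl_loss(st), 2)
  set.seed(73)
  nmc <- 1e6
  for (i in 1:50) {
    d <- 8
    mu <- stats::rnorm(d, sd = 0.8)
    lv <- stats::rnorm(d, sd = 0.5)
    closed <- kl_loss(list(mu = mu, logvar = lv))
    # antithetic pairs (eps, -eps): cancels the odd-moment noise exactly
    eps <- matrix(stats::rnorm(nmc / 2 * d), nmc / 2, d)
    logratio <- function(e) {
      zz <- sweep(sweep(e, 2, exp(lv / 2), `*`), 2, mu, `+`)
      rowSums(sweep(-0.5 * e^2, 2, 0.5 * lv, `-`) + 0.5 * zz^2)
    }
    per_pair <- (logratio(eps) + logratio(-eps)) / 2
    se <- stats::sd(per_pair) / sqrt(nmc / 2)
    expect_lt(abs(mean(per_pair) - closed), 3 * se + 1e-12)
  }
})

test_that("recon_loss is the mean squared difference", {
  x <- array(stats::rnorm(2 * 12 * 400), c(2, 12, 400))
  expect_identical(recon_loss(x, x), 0)
  expect_equal(recon_loss(x, x + 1), 1)
  y <- array(stats::rnorm(length(x)), dim(x))
  brute <- 0
  for (i in 1:2) for (l in 1:12) for (t in 1:400) brute <- brute + (x[i, l, t] - y[i, l, t])^2
  expect_equal(recon_loss(x, y), brute / length(x), tolerance = 1e-12)
  expect_error(recon_loss(x, x[1, , , drop = FALSE]), class = "ecgvae_shape_mismatch")
})

test_that("reparameterization: vanishing noise, unit statistics, determinism", {
  st <- list(mu = matrix(stats::rnorm(8), 2), logvar = matrix(-100, 2, 4))
  z <- reparameterize(st, seed = 1)
  expect_equal(z, st$mu, tolerance = 1e-10)
  st0 <- list(mu = matrix(0, 1e5, 2), logvar = matrix(0, 1e5, 2))
  z0 <- reparameterize(st0, seed = 2)
  expect_lt(max(abs(colMeans(z0))), 0.02)
  expect_true(all(apply(z0, 2, stats::var) > 0.97 & apply(z0, 2, stats::var) < 1.03))
  expect_identical(reparameterize(st0, seed = 9), reparameterize(st0, seed = 9))
})

test_that("risk head is a sigmoid readout of the latent", {
  cfg <- cvae_config(latent_dim = 4, conv_channels = c(2, 3), seed = 1)
  m <- cvae_init(cfg, 0)
  m$params$w_risk <- numeric(4); m$params$b_risk <- 0
  expect_equal(risk_head(m, matrix(stats::rnorm(8), 2)), c(0.5, 0.5))
  m$params$b_risk <- 50
  expect_gte(risk_head(m, matrix(0, 1, 4)), 1 - 1e-20)
  m$params$w_risk <- c(1, 0, 0, 0); m$params$b_risk <- 0
  r <- risk_head(m, cbind(c(-1, 0, 2), 0, 0, 0))
  expect_true(all(diff(r) > 0))
})

test_that("encode/decode are deterministic, finite and shape-checked", {
  tt <- tiny_trained()
  m <- tt$model; cohort <- tt$cohort
  b <- cohort$beats[1:3, , ]
  cc <- cohort$cond[1:3, ]
  e1 <- encode(m, b, cc); e2 <- encode(m, b, cc)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1$mu)) && all(is.finite(e1$logvar)))
  expect_identical(dim(e1$mu), c(3L, 64L))
  z <- reparameterize(e1, seed = 4)
  out <- decode(m, z, cc)
  expect_identical(dim(out), c(3L, 12L, 400L))
  expect_identical(out, decode(m, z, cc))
  expect_error(encode(m, b, cc[, 1:3]), class = "ecgvae_condition_schema_mismatch")
  expect_error(decode(m, z[, 1:10], cc), class = "ecgvae_shape_mismatch")
  # untrained model still produces finite outputs
  m0 <- cvae_init(cvae_config(seed = 2), cond_dim = ncol(cc))
  e0 <- encode(m0, array(0, c(1, 12, 400)), matrix(0, 1, ncol(cc)))
  expect_true(all(is.finite(unlist(e0))))
})

test_that("training reduces reconstruction loss and is seed-reproducible", {
  tt <- tiny_trained()
  hist <- tt$model$history
  expect_lt(hist$recon[nrow(hist)], hist$recon[1])
  cohort <- tt$cohort
  cfg <- cvae_config(epochs = 2, batch_size = 32, seed = 5)
  m1 <- train_cvae(cohort$beats, cohort$cond, cfg)
  m2 <- train_cvae(cohort$beats, cohort$cond, cfg)
  expect_equal(m1$history$recon, m2$history$recon, tolerance = 1e-6)
  expect_equal(m1$params$Wmu, m2$params$Wmu, tolerance = 1e-8)
  expect_error(train_cvae(cohort$beats[1:40, , ], cohort$cond[1:40, ],
                          cvae_config(batch_size = 64)),
               class = "ecgvae_data_too_small")
})

test_that("a dataset of identical beats is memorized to near zero error", {
  beat <- simulate_beat(sample_population(1, seed = 77)[[1]])$signals
  n <- 64
  beats <- array(0, c(n, 12, 400))
  for (i in seq_len(n)) beats[i, , ] <- beat
  cfg <- cvae_config(epochs = 150, learning_rate = 0.003, batch_size = 16,
                     seed = 6)
  m <- train_cvae(beats, NULL, cfg)
  hist <- m$history
  # residual mse (raw units^2) under 1% of the beat's signal variance
  expect_lt(hist$recon[nrow(hist)] * cfg$signal_scale^2,
            0.01 * stats::var(as.numeric(beat)))
  # with nothing left to encode, the posterior collapses onto the prior
  expect_lt(hist$kl[nrow(hist)], 0.01)
})

test_that("conditions flow through the model (encoder and decoder)", {
  tt <- tiny_trained()
  m <- tt$model; cohort <- tt$cohort
  b <- cohort$beats[1:8, , ]
  cc <- cohort$cond[1:8, ]
  mu1 <- encode(m, b, cc)$mu
  cc2 <- cc; cc2[, 4] <- cc2[, 4] + 5  # perturb one condition entry
  mu2 <- encode(m, b, cc2)$mu
  expect_gt(max(abs(mu1 - mu2)), 0)
  z <- matrix(0, 8, 64)
  d1 <- decode(m, z, cc); d2 <- decode(m, z, cc2)
  expect_gt(mean(abs(d1 - d2)), 0)
})

test_that("generation is seeded, produces distinct beats, needs training", {
  tt <- tiny_trained()
  m <- tt$model; cohort <- tt$cohort
  cond <- cohort$cond[1, ]
  g1 <- generate(m, cond, n = 5, seed = 11)
  g2 <- generate(m, cond, n = 5, seed = 11)
  expect_identical(g1, g2)
  expect_identical(dim(g1), c(5L, 12L, 400L))
  expect_gt(min(apply(g1, 1, stats::sd)), 0)
  expect_gt(max(abs(g1[1, , ] - g1[2, , ])), 0)
  m0 <- cvae_init(cvae_config(), cond_dim = length(cond))
  expect_error(generate(m0, cond, 1), class = "ecgvae_untrained_model")
})

test_that("checkpoints round trip through a single file", {
  tt <- tiny_trained()
  dir <- withr::local_tempdir()
  f <- file.path(dir, "model.rds")
  save_checkpoint(tt$model, f)
  m2 <- load_checkpoint(f)
  expect_s3_class(m2, "cvae_model")
  b <- tt$cohort$beats[1:2, , ]; cc <- tt$cohort$cond[1:2, ]
  expect_identical(encode(tt$model, b, cc), encode(m2, b, cc))
})

test_that("beats dataset container round trips", {
  dir <- withr::local_tempdir()
  cohort <- tiny_trained()$cohort
  f <- file.path(dir, "beats.rds")
  save_beats(cohort$beats, cohort$cond, cohort$schema, f)
  ds <- load_beats(f)
  expect_identical(ds$beats, cohort$beats)
  expect_identical(ds$schema, cohort$schema)
})
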