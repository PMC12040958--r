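# Fixture builders shared across test files. Everything is generated in code
# under fixed seeds; no stored data.

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# A well-conditioned random plane triple through a known point.
random_plane_triple <- function() {
  repeat {
    n1 <- random_unit(); n2 <- random_unit(); n3 <- random_unit()
    A <- rbind(n1, n2, n3)
    d <- svd(A, nu = 0, nv = 0)$d
    if (d[1] / d[3] < 50) break
  }
  pt <- stats::rnorm(3, sd = 50)
  list(planes = list(plane3d(n1, pt + 10 * pracma_null(n1)),
                     plane3d(n2, pt + 10 * pracma_null(n2)),
                     plane3d(n3, pt + 10 * pracma_null(n3))),
       point = pt)
}

# A vector orthogonal to v (shifts the plane's anchor point off the
# intersection while keeping the plane itself through it).
pracma_null <- function(v) {
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- u - sum(u * v) * v
  w / sqrt(sum(w^2))
}

# A random right-handed orthonormal frame.
random_frame <- function() {
  repeat {
    a <- random_unit(); b <- stats::rnorm(3)
    b <- b - sum(b * a) * a
    if (sqrt(sum(b^2)) > 1e-3) break
  }
  b <- b / sqrt(sum(b^2))
  cc <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  list(eX = a, eY = b, eZ = cc)
}

# Small synthetic survival batch with ties and censoring.
random_surv_batch <- function(n, tie_frac = 0.3) {
  tt <- stats::rexp(n, 0.1)
  ntie <- floor(n * tie_frac)
  if (ntie >= 2) tt[seq_len(ntie)] <- rep(tt[1], ntie)
  data.frame(time = tt, event = stats::rbinom(n, 1, 0.6))
}

# Brute-force Cox partial-likelihood loss: explicit risk-set enumeration.
cox_loss_bruteforce <- function(risks, records) {
  n <- length(risks)
  total <- 0
  for (i in seq_len(n)) {
    if (records$event[i] == 1) {
      rs <- which(records$time >= records$time[i])
      total <- total + (risks[i] - log(sum(exp(risks[rs]))))
    }
  }
  -total / n
}

# Brute-force Harrell C: O(N^2) pair enumeration.
cindex_bruteforce <- function(risks, records) {
  conc <- 0; comp <- 0
  n <- length(risks)
  for (i in seq_len(n)) {
    if (records$event[i] != 1) next
    for (j in seq_len(n)) {
      if (records$time[j] > records$time[i]) {
        comp <- comp + 1
        if (risks[i] > risks[j]) conc <- conc + 1
        else if (risks[i] == risks[j]) conc <- conc + 0.5
      }
    }
  }
  if (comp == 0) return(0.5)
  conc / comp
}

# Single-sinusoid amplitude gain through a filter, measured by projection on
# the analytic exponential over the central half of the record.
tone_gain <- function(filter_fn, freq_hz, fs = 500, dur_s = 20) {
  tt <- seq_len(dur_s * fs) / fs
  x <- sin(2 * pi * freq_hz * tt)
  sig <- matrix(rep(x, each = 12), 12)
  y <- filter_fn(ecg_record(sig, fs = fs))$signals[1, ]
  mid <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
  num <- abs(sum(y[mid] * exp(-2i * pi * freq_hz * tt[mid])))
  den <- abs(sum(x[mid] * exp(-2i * pi * freq_hz * tt[mid])))
  num / den
}

# A tiny trained model cached across test files (unconditional-free; pose +
# demographics conditioning, small cohort, few epochs).
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- simulate_cohort(160, seed = 42)
      cfg <- cvae_config(epochs = 4, batch_size = 32, seed = 3)
      cache <<- list(
        cohort = cohort,
        model = train_cvae(cohort$beats, cohort$cond, cfg, schema = cohort$schema))
    }
    cache
  }
})
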