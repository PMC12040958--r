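# Dipole forward model, lead derivation, population sampling and the
# proportional-hazards survival generator.

test_that("dipole potential has the closed-form value and scaling", {
  # p perpendicular to displacement
  expect_equal(dipole_potential(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), sigma = 1), 0)
  # aligned unit case with sigma = 1/(4 pi)
  expect_equal(dipole_potential(c(1, 0, 0), c(0, 0, 0), c(1, 0, 0),
                                sigma = 1 / (4 * pi)), 1)
  # doubling distance quarters the potential
  p <- c(0.3, -0.2, 0.5)
  phi1 <- dipole_potential(p, c(0, 0, 0), c(0.1, 0.05, -0.2))
  phi2 <- dipole_potential(p, c(0, 0, 0), 2 * c(0.1, 0.05, -0.2))
  expect_equal(phi1 / phi2, 4)
  expect_error(dipole_potential(p, c(0, 0, 0), c(1e-9, 0, 0)),
               class = "ecgvae_singular_point")
})

test_that("lead derivation matches the defining formulas and identities", {
  phi <- c(RA = 0, LA = 1, RL = 0.2, LL = 0, V1 = 0.5, V2 = -0.1, V3 = 0.2,
           V4 = 0, V5 = 0.3, V6 = -0.4)
  lv <- lead_voltages(phi)
  expect_equal(as.numeric(lv["I"]), 1)
  expect_equal(as.numeric(lv["II"]), 0)
  expect_equal(as.numeric(lv["III"]), -1)
  set.seed(31)
  for (i in 1:20) {
    phi <- stats::rnorm(10); names(phi) <- electrode_names()
    lv <- lead_voltages(phi)
    # direct re-evaluation
    wct <- mean(phi[c("RA", "LA", "LL")])
    expect_equal(as.numeric(lv["aVR"]), phi[["RA"]] - (phi[["LA"]] + phi[["LL"]]) / 2)
    expect_equal(as.numeric(lv["V3"]), phi[["V3"]] - wct, tolerance = 1e-15)
    expect_identical(as.numeric(lv["III"]), as.numeric(lv["II"] - lv["I"]))
    expect_equal(as.numeric(lv["aVR"] + lv["aVL"] + lv["aVF"]), 0)
  }
  expect_error(lead_voltages(phi[-1]), class = "ecgvae_missing_electrode")
})

test_that("simulated beats satisfy the lead identities machine-exactly", {
  subs <- sample_population(5, seed = 8)
  for (s in subs) {
    b <- simulate_beat(s)$signals
    expect_lt(max(abs(b["III", ] - (b["II", ] - b["I", ]))), 1e-10)
    expect_lt(max(abs(colSums(b[c("aVR", "aVL", "aVF"), ]))), 1e-10)
  }
})

test_that("zero trajectory gives a zero beat; amplitudes scale linearly", {
  s <- sample_population(1, seed = 3)[[1]]
  s0 <- s
  s0$trajectory <- dipole_trajectory(amplitudes = matrix(0, 3, 5))
  expect_true(all(simulate_beat(s0)$signals == 0))
  s2 <- s
  s2$trajectory <- dipole_trajectory(amplitudes = 2 * s$trajectory$amplitudes,
                                     centers = s$trajectory$centers,
                                     widths = s$trajectory$widths)
  expect_equal(simulate_beat(s2)$signals, 2 * simulate_beat(s)$signals,
               tolerance = 1e-12)
})

test_that("joint rigid motion of heart and electrodes leaves leads unchanged", {
  set.seed(17)
  s <- sample_population(1, seed = 3)[[1]]
  base <- simulate_beat(s)$signals
  for (i in 1:5) {
    ax <- random_unit(); ang <- stats::runif(1, -60, 60)
    R <- ecgvae:::rotation_matrix(ax, ang)
    shift <- stats::rnorm(3, sd = 40)
    s2 <- s
    s2$pose <- heart_pose(as.numeric(R %*% s$pose$position) + shift,
                          list(eX = as.numeric(R %*% s$pose$eX),
                               eY = as.numeric(R %*% s$pose$eY),
                               eZ = as.numeric(R %*% s$pose$eZ)))
    s2$layout <- electrode_layout(
      t(apply(s$layout$coords, 1, function(p) as.numeric(R %*% p) + shift)),
      frame = "anatomical")
    expect_equal(simulate_beat(s2)$signals, base, tolerance = 1e-9)
  }
})

test_that("long-axis rotation produces a monotone R-amplitude trend in V4", {
  s <- sample_population(1, seed = 3)[[1]]
  grid <- seq(-40, 40, by = 10)
  amp <- vapply(grid, function(a) {
    s2 <- s; s2$pose <- rotate_pose(s$pose, "eZ", a)
    max(simulate_beat(s2)$signals["V4", ])
  }, numeric(1))
  expect_true(all(diff(amp) > 0) || all(diff(amp) < 0))
})

test_that("population sampling is seeded and respects the torso shell", {
  pop1 <- sample_population(50, seed = 6)
  pop2 <- sample_population(50, seed = 6)
  expect_equal(pop1[[27]]$pose$position, pop2[[27]]$pose$position)
  expect_equal(pop1[[50]]$layout$coords, pop2[[50]]$layout$coords)
  for (s in pop1) {
    d <- sqrt(rowSums(sweep(s$layout$coords, 2, s$pose$position)^2)) / 1000
    expect_true(all(d >= 0.1 & d <= 0.4))
    expect_gte(s$demographics$age, 40)
    expect_lte(s$demographics$age, 80)
    ang <- acos((sum(diag(ecgvae:::rotation_of(s$pose))) - 1) / 2) * 180 / pi
    expect_lte(ang, 3 * 30 + 1e-6)  # composition of three bounded rotations
  }
})

test_that("survival generator: null betas give chance-level concordance", {
  subs <- sample_population(300, seed = 12)
  feats <- cohort_features(subs)
  cis <- vapply(1:20, function(k) {
    sv <- simulate_survival(subs, beta = c(r_amp_ii = 0), censor_frac = 0.3,
                            seed = 100 + k, features = feats)
    set.seed(k)
    concordance_index(stats::runif(nrow(sv)), sv)
  }, numeric(1))
  expect_lt(abs(mean(cis) - 0.5), 0.02)
})

test_that("survival generator recovers a strong single-feature signal", {
  subs <- sample_population(800, seed = 14)
  feats <- cohort_features(subs)
  sv <- simulate_survival(subs, beta = c(r_amp_ii = 2), censor_frac = 0,
                          seed = 5, features = feats)
  ci_feat <- concordance_index(feats$r_amp_ii, sv)
  # closed-form-free reference: concordance of the true log hazard itself
  ci_true <- concordance_index(sv$true_log_hazard, sv)
  expect_equal(ci_feat, ci_true, tolerance = 1e-12)
  expect_gt(ci_feat, 0.7)
})

test_that("censoring tuning hits the requested fraction", {
  subs <- sample_population(500, seed = 19)
  sv <- simulate_survival(subs, censor_frac = 0.7, seed = 2)
  frac <- 1 - mean(sv$event)
  expect_gte(frac, 0.65); expect_lte(frac, 0.75)
})

test_that("condition matrices follow the declared schema", {
  subs <- sample_population(4, seed = 23)
  cc <- build_conditions(subs, blocks = c("heart_position", "electrodes", "age"))
  expect_identical(unname(cc$schema), c(3, 30, 1))
  expect_identical(dim(cc$values), c(4L, 34L))
  expect_equal(cc$values[2, 1:3], subs[[2]]$pose$position)
  expect_equal(cc$values[3, 34], subs[[3]]$demographics$age)
  hf <- to_heart_frame(subs[[1]]$layout, subs[[1]]$pose)
  expect_equal(cc$values[1, 4:33], flatten_layout(hf))
  expect_error(build_conditions(subs, blocks = "bogus"), class = "ecgvae_bad_schema")
})
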