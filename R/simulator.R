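# Synthetic-data generator: a single time-varying current dipole in an
# infinite homogeneous volume conductor, evaluated at 10 body-surface
# electrodes and combined into the standard 12 leads. The dipole trajectory is
# expressed in the heart-local frame, so heart pose and electrode placement
# systematically shape the simulated beats -- giving the generative model a
# verifiable pose -> morphology ground truth. Survival outcomes follow a
# proportional-hazards law whose covariates include a beat-derived amplitude
# feature, so risk is genuinely ECG-linked.
#
# Deliberate simplifications: no torso boundary (infinite medium), a single
# dipole (no multi-source electrophysiology), and a median beat only (no
# rhythm). These retain the pose/electrode dependence the package needs while
# running in milliseconds per subject.

#' Construct a dipole trajectory
#'
#' Each spatial axis of the heart-frame dipole moment is a sum of Gaussian
#' deflections shaping the P, Q, R, S and T waves over one beat. Centers are
#' fractions of the beat (ordered P < Q < R < S < T), widths are fractions of
#' the beat, amplitudes are dipole-moment units (A.m).
#'
#' @param amplitudes 3x5 matrix (rows x,y,z of the heart frame; columns
#'   P,Q,R,S,T)
#' @param centers length-5 increasing vector in (0,1)
#' @param widths length-5 positive vector
#' @return object of class `dipole_trajectory`
#' @export
dipole_trajectory <- function(amplitudes = default_trajectory_amplitudes(),
                              centers = c(P = 0.15, Q = 0.33, R = 0.375,
                                          S = 0.42, T = 0.70),
                              widths = c(P = 0.040, Q = 0.012, R = 0.014,
                                         S = 0.014, T = 0.070)) {
  amplitudes <- as.matrix(amplitudes)
  stopifnot(nrow(amplitudes) == 3, ncol(amplitudes) == 5,
            length(centers) == 5, length(widths) == 5,
            all(widths > 0), all(diff(centers) > 0),
            all(centers > 0 & centers < 1))
  structure(list(amplitudes = amplitudes, centers = as.numeric(centers),
                 widths = as.numeric(widths)),
            class = "dipole_trajectory")
}

#' Default dipole deflection amplitudes
#'
#' Scaled so that a subject at a typical pose and electrode layout produces an
#' R wave of roughly 100-150 raw amplitude units (the stored mV/100 scale,
#' i.e. 1.0-1.5 mV) in the precordial leads.
#'
#' @return 3x5 numeric matrix
#' @export
default_trajectory_amplitudes <- function() {
  base <- rbind(x = c(P = 0.04, Q = -0.12, R = 1.00, S = -0.25, T = 0.30),
                y = c(P = 0.03, Q = -0.05, R = 0.55, S = -0.15, T = 0.18),
                z = c(P = 0.02, Q = 0.06, R = -0.45, S = 0.12, T = 0.10))
  6e-5 * base  # A.m; sets the overall voltage scale
}

#' Evaluate the heart-frame dipole moment over a beat
#'
#' @param trajectory `dipole_trajectory`
#' @param t vector of beat fractions in [0, 1]
#' @return 3 x length(t) matrix of dipole moment (A.m), heart frame
#' @export
dipole_moment <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "dipole_trajectory"))
  m <- matrix(0, 3, length(t))
  for (k in 1:5) {
    g <- exp(-0.5 * ((t - trajectory$centers[k]) / trajectory$widths[k])^2)
    m <- m + trajectory$amplitudes[, k] %o% g
  }
  m
}

#' Potential of a current dipole in an infinite homogeneous conductor
#'
#' phi = p . (r_e - r_s) / (4 pi sigma |r_e - r_s|^3), the classical
#' far-field single-dipole potential.
#'
#' @param p dipole moment, length-3, A.m
#' @param r_source source location, length-3, meters
#' @param r_electrode electrode location, length-3, meters
#' @param sigma conductivity, S/m
#' @return scalar potential in volts
#' @export
dipole_potential <- function(p, r_source, r_electrode, sigma = 0.2) {
  d <- r_electrode - r_source
  dist <- vnorm(d)
  if (dist < 1e-6) abort_ecgvae("electrode coincides with the dipole source", "singular_point")
  sum(p * d) / (4 * pi * sigma * dist^3)
}

#' Derive the 12 standard leads from 10 electrode potentials
#'
#' Einthoven limb leads, Goldberger augmented leads and Wilson-central-terminal
#' precordial leads. RL serves as ground and does not enter any lead.
#'
#' @param potentials named numeric vector (or 10 x T matrix with rownames)
#'   over the electrodes of [electrode_names()]
#' @return length-12 vector (or 12 x T matrix) in the order of [lead_names()]
#' @export
lead_voltages <- function(potentials) {
  if (is.null(dim(potentials))) potentials <- matrix(potentials,
                                                     ncol = 1,
                                                     dimnames = list(names(potentials)))
  if (!all(electrode_names() %in% rownames(potentials))) {
    abort_ecgvae("missing electrode potential", "missing_electrode")
  }
  ra <- potentials["RA", ]; la <- potentials["LA", ]; ll <- potentials["LL", ]
  wct <- (ra + la + ll) / 3
  lead_i <- la - ra
  lead_ii <- ll - ra
  out <- rbind(I   = lead_i,
               II  = lead_ii,
               III = lead_ii - lead_i,  # Einthoven identity, bit-exact
               aVR = ra - (la + ll) / 2,
               aVL = la - (ra + ll) / 2,
               aVF = ll - (ra + la) / 2,
               V1 = potentials["V1", ] - wct, V2 = potentials["V2", ] - wct,
               V3 = potentials["V3", ] - wct, V4 = potentials["V4", ] - wct,
               V5 = potentials["V5", ] - wct, V6 = potentials["V6", ] - wct)
  if (ncol(out) == 1) out[, 1] else out
}

#' Construct a synthetic subject
#'
#' @param pose `heart_pose`
#' @param layout anatomical-frame `electrode_layout` (mm)
#' @param demographics list with `age` (years), `sex` (0/1), `bmi`
#' @param trajectory `dipole_trajectory`
#' @param subject_id identifier
#' @return object of class `synthetic_subject`
#' @export
synthetic_subject <- function(pose, layout, demographics, trajectory,
                              subject_id = "S1") {
  stopifnot(inherits(pose, "heart_pose"), inherits(layout, "electrode_layout"),
            layout$frame == "anatomical", inherits(trajectory, "dipole_trajectory"))
  d <- sqrt(rowSums(sweep(layout$coords, 2, pose$position)^2)) / 1000
  if (any(d < 0.1 - 1e-9 | d > 0.4 + 1e-9)) {
    abort_ecgvae("electrodes must lie on a 0.1-0.4 m shell around the heart", "bad_layout")
  }
  structure(list(subject_id = subject_id, pose = pose, layout = layout,
                 demographics = demographics, trajectory = trajectory),
            class = "synthetic_subject")
}

#' Simulate a 12-lead median beat for one subject
#'
#' The heart-frame dipole trajectory is rotated and translated into the
#' anatomical frame by the subject's pose, its potential evaluated at every
#' electrode and sample, and the 12 leads derived. Output is in raw amplitude
#' units (stored mV/100 scale, i.e. volts x 1e5).
#'
#' @param subject `synthetic_subject`
#' @param n_samples beat length (default 400)
#' @param noise_sd additive Gaussian noise, raw units (default 0)
#' @param sigma conductivity S/m
#' @param seed optional seed for the noise
#' @return `median_beat` (12 x n_samples)
#' @export
simulate_beat <- function(subject, n_samples = 400, noise_sd = 0, sigma = 0.2,
                          seed = NULL) {
  stopifnot(inherits(subject, "synthetic_subject"))
  tfrac <- (seq_len(n_samples) - 0.5) / n_samples
  m_heart <- dipole_moment(subject$trajectory, tfrac)        # 3 x T, A.m
  R <- rotation_of(subject$pose)
  m_anat <- R %*% m_heart                                     # 3 x T
  src <- subject$pose$position / 1000                         # m
  el <- subject$layout$coords / 1000                          # 10 x 3, m
  disp <- sweep(el, 2, src)                                   # r_e - r_s
  dist3 <- (sqrt(rowSums(disp^2)))^3
  pots <- (disp %*% m_anat) / (4 * pi * sigma * dist3)        # 10 x T volts
  rownames(pots) <- rownames(el)
  sig <- lead_voltages(pots) * 1e5                            # raw (mV/100) units
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      matrix(stats::rnorm(length(sig), sd = noise_sd), nrow(sig))
    } else {
      with_seed(seed, matrix(stats::rnorm(length(sig), sd = noise_sd), nrow(sig)))
    }
    sig <- sig + noise
  }
  new_median_beat(sig, fs = 500)
}

#' Simulate a raw 10-s 12-lead record for one subject
#'
#' Tiles noise-free beats at a fixed RR interval, adds baseline wander and
#' white noise, and reports the ground-truth R-peak sample indices. Used to
#' exercise the preprocessing chain against a known answer.
#'
#' @param subject `synthetic_subject`
#' @param duration_s record length in seconds
#' @param fs sampling rate, Hz
#' @param rr_s RR interval, seconds
#' @param noise_sd white-noise standard deviation, raw units
#' @param wander_amp baseline-wander amplitude, raw units (0.25 Hz sinusoid)
#' @param seed seed for the noise
#' @return list with `record` (an `ecg_record`) and `r_peaks` (sample indices)
#' @export
simulate_record <- function(subject, duration_s = 10, fs = 500, rr_s = 0.8,
                            noise_sd = 2, wander_amp = 30, seed = 1) {
  n_total <- round(duration_s * fs)
  beat_len <- round(0.8 * fs)  # the beat template spans 0.8 s
  beat <- simulate_beat(subject, n_samples = beat_len)$signals
  sig <- matrix(0, 12, n_total)
  onsets <- seq(1, n_total - beat_len + 1, by = round(rr_s * fs))
  for (on in onsets) sig[, on:(on + beat_len - 1)] <- sig[, on:(on + beat_len - 1)] + beat
  r_idx <- round(0.375 * beat_len)  # R center at beat fraction 0.375
  r_peaks <- onsets + r_idx - 1
  tt <- seq_len(n_total) / fs
  with_seed(seed, {
    wander <- wander_amp * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
    sig <- sweep(sig, 2, wander, `+`) +
      matrix(stats::rnorm(length(sig), sd = noise_sd), 12)
  })
  list(record = ecg_record(sig, fs = fs, subject_id = subject$subject_id),
       r_peaks = r_peaks)
}

#' Template electrode layout on a torso shell
#'
#' Anatomical frame, mm; x left, y anterior, z superior; heart near the origin.
#'
#' @return `electrode_layout`
#' @export
template_layout <- function() {
  m <- rbind(RA = c(-180,  60,  180),
             LA = c( 200,  60,  180),
             RL = c(-120,  40, -350),
             LL = c( 130,  40, -350),
             V1 = c( -35, 125,   20),
             V2 = c(  15, 130,   20),
             V3 = c(  40, 125,  -15),
             V4 = c(  65, 120,  -35),
             V5 = c( 100, 105,  -40),
             V6 = c( 130,  85,  -45))
  electrode_layout(m, frame = "anatomical")
}

rotation_matrix <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- normalize(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Rotate a heart pose about one of its local axes
#'
#' Rotates the frame (eX, eY, eZ) rigidly about the chosen heart-frame axis;
#' position is unchanged. Euler angles are recomputed.
#'
#' @param pose `heart_pose`
#' @param axis "eX", "eY" (left-to-right ventricle axis) or "eZ" (long axis)
#' @param angle_deg rotation angle in degrees
#' @return rotated `heart_pose`
#' @export
rotate_pose <- function(pose, axis = c("eZ", "eY", "eX"), angle_deg) {
  axis <- match.arg(axis)
  Rrot <- rotation_matrix(pose[[axis]], angle_deg)
  heart_pose(pose$position,
             list(eX = as.numeric(Rrot %*% pose$eX),
                  eY = as.numeric(Rrot %*% pose$eY),
                  eZ = as.numeric(Rrot %*% pose$eZ)))
}

#' Translate a heart pose
#'
#' @param pose `heart_pose`
#' @param delta_mm length-3 translation in anatomical mm
#' @return translated `heart_pose`
#' @export
translate_pose <- function(pose, delta_mm) {
  heart_pose(pose$position + delta_mm,
             list(eX = pose$eX, eY = pose$eY, eZ = pose$eZ), euler = pose$euler)
}

#' Imaging planes consistent with a pose (synthetic construction)
#'
#' Builds three planes through the heart position with normals eY (labelled
#' SAX), eX (2CH) and eZ (4CH), so that [pose_from_planes()] recovers the pose
#' exactly. A synthetic stand-in for DICOM-derived plane metadata.
#'
#' @param pose `heart_pose`
#' @return list with `SAX`, `2CH`, `4CH` `plane3d` entries
#' @export
planes_from_pose <- function(pose) {
  list(SAX    = plane3d(pose$eY, pose$position),
       `2CH`  = plane3d(pose$eX, pose$position),
       `4CH`  = plane3d(pose$eZ, pose$position))
}

#' Sample a synthetic cohort
#'
#' Poses are jittered around the identity orientation (rotations uniform within
#' +/- `rot_range_deg` about each axis, positions uniform within +/-
#' `pos_range_mm`); electrodes are the template layout with independent
#' placement noise, radially clamped to the 0.1-0.4 m shell; demographics are
#' age ~ U(40, 80), sex ~ Bernoulli(0.5), BMI ~ N(27, 4) truncated to [16, 45];
#' each subject's trajectory amplitudes are jittered log-normally (sd 0.15
#' overall, 0.05 per wave).
#'
#' @param n cohort size
#' @param seed RNG seed (all randomness flows from it)
#' @param rot_range_deg rotation jitter half-range, degrees (default 30)
#' @param pos_range_mm position jitter half-range, mm (default 30)
#' @param electrode_sd_mm electrode placement noise, mm (default 20)
#' @return list of `synthetic_subject`
#' @export
sample_population <- function(n, seed = 1, rot_range_deg = 30, pos_range_mm = 30,
                              electrode_sd_mm = 20) {
  stopifnot(n >= 1)
  template <- template_layout()
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ang <- stats::runif(3, -rot_range_deg, rot_range_deg)
      R <- rotation_matrix(c(0, 0, 1), ang[1]) %*%
        rotation_matrix(c(0, 1, 0), ang[2]) %*%
        rotation_matrix(c(1, 0, 0), ang[3])
      pos <- stats::runif(3, -pos_range_mm, pos_range_mm)
      pose <- heart_pose(pos, list(eX = R[, 1], eY = R[, 2], eZ = R[, 3]))
      co <- template$coords + matrix(stats::rnorm(30, sd = electrode_sd_mm), 10, 3)
      # clamp radially onto the torso shell
      d <- sweep(co, 2, pos)
      r <- sqrt(rowSums(d^2))
      rc <- clamp(r, 102, 398)
      co <- sweep(d * (rc / r), 2, pos, `+`)
      lay <- electrode_layout(co, frame = "anatomical")
      amp <- default_trajectory_amplitudes() *
        exp(stats::rnorm(1, 0, 0.15)) *
        matrix(exp(stats::rnorm(15, 0, 0.05)), 3, 5)
      demo <- list(age = stats::runif(1, 40, 80),
                   sex = stats::rbinom(1, 1, 0.5),
                   bmi = clamp(stats::rnorm(1, 27, 4), 16, 45))
      synthetic_subject(pose, lay, demo, dipole_trajectory(amplitudes = amp),
                        subject_id = sprintf("S%04d", i))
    })
  })
}

#' Beat-derived hazard features for a cohort
#'
#' Computes, per subject, the noise-free lead-II R amplitude (maximum of the
#' simulated lead II beat), age and sex -- the default covariates of the
#' survival generator.
#'
#' @param subjects list of `synthetic_subject`
#' @return data.frame with subject_id, r_amp_ii, age, sex, bmi
#' @export
cohort_features <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s) {
    b <- simulate_beat(s)
    data.frame(subject_id = s$subject_id,
               r_amp_ii = max(b$signals["II", ]),
               age = s$demographics$age, sex = s$demographics$sex,
               bmi = s$demographics$bmi)
  }))
}

#' Simulate proportional-hazards survival outcomes
#'
#' Event times are exponential with rate `base_rate * exp(sum(beta * x_std))`
#' over standardized covariates; censoring times are uniform on (0, c_max)
#' with c_max tuned so the expected censoring fraction matches `censor_frac`.
#'
#' @param subjects list of `synthetic_subject`
#' @param beta named log-hazard-ratio vector over columns of
#'   [cohort_features()] (default c(r_amp_ii = 1.5, age = 0.5, sex = 0.3))
#' @param censor_frac target censoring fraction (default 0.7)
#' @param base_rate baseline hazard, events per day (default 1/2000)
#' @param seed RNG seed
#' @param features optional precomputed [cohort_features()] table
#' @return data.frame: subject_id, time (days), event (0/1), subtype,
#'   true_log_hazard
#' @export
simulate_survival <- function(subjects, beta = c(r_amp_ii = 1.5, age = 0.5, sex = 0.3),
                              censor_frac = 0.7, base_rate = 1 / 2000, seed = 1,
                              features = NULL) {
  if (is.null(features)) features <- cohort_features(subjects)
  lp <- rep(0, nrow(features))
  for (nm in names(beta)) {
    x <- features[[nm]]
    s <- stats::sd(x)
    xs <- if (is.na(s) || s < 1e-12) x * 0 else (x - mean(x)) / s
    lp <- lp + beta[[nm]] * xs
  }
  subtypes <- c("I20", "I21", "I22", "I23", "I24", "I25", "I50")
  with_seed(seed, {
    T_ev <- stats::rexp(length(lp), rate = base_rate * exp(lp))
    if (censor_frac > 0) {
      f <- function(cm) mean(pmin(T_ev, cm) / cm) - censor_frac
      cmax <- stats::uniroot(f, lower = min(T_ev) * 1e-3,
                             upper = max(T_ev) * 1e3, tol = 1e-8)$root
      C <- stats::runif(length(lp), 0, cmax)
    } else {
      C <- rep(Inf, length(lp))
    }
    event <- as.integer(T_ev <= C)
    data.frame(subject_id = features$subject_id,
               time = pmax(pmin(T_ev, C), 1e-6),
               event = event,
               subtype = ifelse(event == 1,
                                sample(subtypes, length(lp), replace = TRUE,
                                       prob = c(.2, .2, .05, .05, .1, .2, .2)),
                                NA_character_),
               true_log_hazard = lp,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full cohort: beats, conditions, survival
#'
#' One-call generator combining [sample_population()], [simulate_beat()] (with
#' observation noise), condition construction and [simulate_survival()].
#'
#' @param n cohort size
#' @param seed RNG seed
#' @param noise_sd beat observation noise, raw units (default 3)
#' @param blocks condition blocks, see [build_conditions()]
#' @param beta,censor_frac passed to [simulate_survival()]
#' @return list: subjects, beats (n x 12 x 400 array), cond (matrix), schema,
#'   features, survival (data.frame)
#' @export
simulate_cohort <- function(n, seed = 1, noise_sd = 3,
                            blocks = c("heart_position", "heart_orientation",
                                       "sex", "age", "bmi"),
                            beta = c(r_amp_ii = 1.5, age = 0.5, sex = 0.3),
                            censor_frac = 0.7) {
  subjects <- sample_population(n, seed = seed)
  beats <- array(0, c(n, 12, 400), dimnames = list(NULL, lead_names(), NULL))
  for (i in seq_len(n)) {
    beats[i, , ] <- simulate_beat(subjects[[i]], noise_sd = noise_sd,
                                  seed = seed + 7L * i)$signals
  }
  cond <- build_conditions(subjects, blocks = blocks)
  features <- cohort_features(subjects)
  surv <- simulate_survival(subjects, beta = beta, censor_frac = censor_frac,
                            seed = seed + 1L, features = features)
  list(subjects = subjects, beats = beats, cond = cond$values,
       schema = cond$schema, features = features, survival = surv)
}

#' Build condition vectors for a list of subjects
#'
#' Blocks (in order): heart_position (3), heart_orientation (3 Euler angles,
#' degrees), electrodes (30; heart-frame coordinates, flattened in canonical
#' order), sex (1), age (1), bmi (1). Values are raw; standardization happens
#' inside model training.
#'
#' @param subjects list of `synthetic_subject` (or lists with pose/layout/
#'   demographics)
#' @param blocks character vector of block names
#' @return list with `values` (n x c matrix) and `schema` (named block sizes)
#' @export
build_conditions <- function(subjects,
                             blocks = c("heart_position", "heart_orientation",
                                        "sex", "age", "bmi")) {
  sizes <- c(heart_position = 3, heart_orientation = 3, electrodes = 30,
             sex = 1, age = 1, bmi = 1)
  bad <- setdiff(blocks, names(sizes))
  if (length(bad)) abort_ecgvae(paste("unknown condition block:", bad[1]), "bad_schema")
  rows <- lapply(subjects, function(s) {
    out <- numeric(0)
    for (b in blocks) {
      out <- c(out, switch(b,
        heart_position = s$pose$position,
        heart_orientation = as.numeric(s$pose$euler),
        electrodes = flatten_layout(to_heart_frame(s$layout, s$pose)),
        sex = s$demographics$sex,
        age = s$demographics$age,
        bmi = s$demographics$bmi))
    }
    out
  })
  values <- do.call(rbind, rows)
  if (is.null(values)) values <- matrix(0, 0, sum(sizes[blocks]))
  list(values = values, schema = sizes[blocks])
}

#' Condition vector for a single subject under a schema
#'
#' @param subject `synthetic_subject` (or pose/layout/demographics list)
#' @param blocks condition blocks
#' @return numeric condition vector
#' @export
subject_condition <- function(subject, blocks) {
  as.numeric(build_conditions(list(subject), blocks = blocks)$values[1, ])
}
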