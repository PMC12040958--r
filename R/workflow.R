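# End-to-end experiment orchestration at desk scale:
#   E1 -- pose-conditioned generation sweeps (rotation about the long and
#         left-to-right ventricle axes; translation along the lateral and
#         cranio-caudal directions), with the simulator forward model as the
#         directional reference;
#   E2 -- the same sweeps with electrode positions as the only condition
#         input (heart-frame electrode coordinates carry pose + torso);
#   E3 -- joint generative/survival training across conditioning arms, with
#         C-index per arm, median-risk stratification and Kaplan-Meier
#         curves.

#' Experiment configuration
#'
#' @param experiment "E1", "E2" or "E3"
#' @param n_subjects cohort size
#' @param seed master seed
#' @param epochs training epochs
#' @param rotation_grid_deg rotation sweep grid, degrees (default
#'   c(-40, -20, 0, 20, 40))
#' @param translation_grid_cm translation sweep grid, cm (default
#'   c(-4, -2, 0, 2, 4))
#' @param arms condition-schema arms for E3 (named list of block vectors);
#'   defaults to baseline, +electrodes, +sex+age, +sex+age+electrodes
#' @param n_draws generated draws per sweep point (default 8)
#' @param config optional `cvae_config` overriding the derived one
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(experiment = c("E1", "E2", "E3"),
                              n_subjects = 600, seed = 1, epochs = 12,
                              rotation_grid_deg = c(-40, -20, 0, 20, 40),
                              translation_grid_cm = c(-4, -2, 0, 2, 4),
                              arms = NULL, n_draws = 8, config = NULL) {
  experiment <- match.arg(experiment)
  if (is.null(arms)) {
    arms <- list(
      baseline = character(0),
      electrodes = "electrodes",
      sex_age = c("sex", "age"),
      sex_age_electrodes = c("sex", "age", "electrodes"))
  }
  stopifnot(length(seed) >= 1)
  structure(list(experiment = experiment, n_subjects = n_subjects, seed = seed,
                 epochs = epochs, rotation_grid_deg = rotation_grid_deg,
                 translation_grid_cm = translation_grid_cm, arms = arms,
                 n_draws = n_draws, config = config),
            class = "experiment_config")
}

peak_amplitude <- function(beat_matrix) apply(beat_matrix, 1, max)

# Slope of peak amplitude vs sweep value, per lead (leads I, II, V1-V6 are
# the ones reported in the pose-sweep figures).
sweep_slopes <- function(amp_by_point, grid) {
  leads <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
  sl <- vapply(leads, function(ld) {
    y <- amp_by_point[ld, ]
    as.numeric(stats::coef(stats::lm(y ~ grid))[2])
  }, numeric(1))
  data.frame(lead = leads, slope = sl, row.names = NULL)
}

#' Forward-model amplitude trend for a pose sweep
#'
#' Simulates noise-free beats for the reference subject at each sweep point
#' and returns per-lead peak-amplitude regression slopes -- the directional
#' ground truth generated beats are compared against.
#'
#' @param subject reference `synthetic_subject`
#' @param sweep "rotation_long", "rotation_lr", "translation_lateral" or
#'   "translation_craniocaudal"
#' @param grid sweep values (degrees for rotations, cm for translations)
#' @return list with `slopes` (data.frame lead, slope) and `amplitudes`
#'   (lead x grid matrix)
#' @export
forward_sweep <- function(subject, sweep, grid) {
  amp <- sapply(grid, function(v) {
    s2 <- sweep_subject(subject, sweep, v)
    peak_amplitude(simulate_beat(s2)$signals)
  })
  rownames(amp) <- lead_names()
  list(slopes = sweep_slopes(amp, grid), amplitudes = amp)
}

# Apply one sweep step to a subject (pose modified; electrodes fixed in the
# anatomical frame).
sweep_subject <- function(subject, sweep, value) {
  pose <- switch(sweep,
    rotation_long = rotate_pose(subject$pose, "eZ", value),
    rotation_lr = rotate_pose(subject$pose, "eY", value),
    translation_lateral = translate_pose(subject$pose, c(value * 10, 0, 0)),
    translation_craniocaudal = translate_pose(subject$pose, c(0, 0, value * 10)),
    abort_ecgvae("unknown sweep", "config_error"))
  s2 <- subject
  s2$pose <- pose
  s2
}

#' Generated-beat amplitude trend for a condition sweep
#'
#' Sweeps the model's conditioning input along a pose grid, generates
#' `n_draws` beats per point, and returns per-lead mean peak-amplitude slopes.
#'
#' @param model trained `cvae_model`
#' @param subject reference subject whose condition is swept
#' @param sweep sweep name, see [forward_sweep()]
#' @param grid sweep values
#' @param blocks condition blocks the model was trained with
#' @param n_draws draws per grid point
#' @param seed RNG seed
#' @return list with `slopes` and `amplitudes` as in [forward_sweep()]
#' @export
generated_sweep <- function(model, subject, sweep, grid, blocks, n_draws = 8,
                            seed = 1) {
  amp <- sapply(seq_along(grid), function(i) {
    s2 <- sweep_subject(subject, sweep, grid[i])
    cond <- subject_condition(s2, blocks)
    g <- generate(model, cond, n = n_draws, seed = seed + i)
    peak_amplitude(apply(g, c(2, 3), mean))
  })
  rownames(amp) <- lead_names()
  list(slopes = sweep_slopes(amp, grid), amplitudes = amp)
}

#' Agreement between generated and forward-model sweep trends
#'
#' @param gen,fwd outputs of [generated_sweep()] and [forward_sweep()]
#' @return data.frame with lead, slope_generated, slope_forward, sign_match
#' @export
sweep_agreement <- function(gen, fwd) {
  df <- merge(gen$slopes, fwd$slopes, by = "lead", suffixes = c("_generated", "_forward"))
  df$sign_match <- sign(df$slope_generated) == sign(df$slope_forward)
  df[order(match(df$lead, lead_names())), ]
}

#' Run one experiment end to end
#'
#' E1/E2 train a cVAE on a simulated cohort and compare generated sweep trends
#' with the forward model; E3 trains one joint model per conditioning arm on a
#' shared stratified split and evaluates C-index, median-risk stratification
#' and Kaplan-Meier summaries. The returned report is a plain list that can be
#' serialized to JSON and regenerated deterministically from the same
#' configuration and seed.
#'
#' @param cfg `experiment_config`
#' @param out_dir optional directory for the JSON report and figures
#' @return report list
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  report <- switch(cfg$experiment,
                   E1 = run_sweep_experiment(cfg, electrode_only = FALSE),
                   E2 = run_sweep_experiment(cfg, electrode_only = TRUE),
                   E3 = run_survival_experiment(cfg))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, paste0(cfg$experiment, "_report.json")),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_experiment_figures(report, cfg, out_dir)
  }
  report
}

run_sweep_experiment <- function(cfg, electrode_only) {
  blocks <- if (electrode_only) "electrodes" else c("heart_position", "heart_orientation")
  cohort <- simulate_cohort(cfg$n_subjects, seed = cfg$seed[1], blocks = blocks)
  mcfg <- cfg$config
  # generation experiments use the larger signal scale: the posterior then
  # stays close to the prior, so z ~ N(0, I) decodes in-distribution
  if (is.null(mcfg)) mcfg <- cvae_config(epochs = cfg$epochs, seed = cfg$seed[1],
                                         signal_scale = 8)
  model <- train_cvae(cohort$beats, cohort$cond, mcfg, schema = cohort$schema)
  ref <- cohort$subjects[[1]]
  sweeps <- list(rotation_long = cfg$rotation_grid_deg,
                 rotation_lr = cfg$rotation_grid_deg,
                 translation_lateral = cfg$translation_grid_cm,
                 translation_craniocaudal = cfg$translation_grid_cm)
  out <- lapply(names(sweeps), function(sw) {
    fwd <- forward_sweep(ref, sw, sweeps[[sw]])
    gen <- generated_sweep(model, ref, sw, sweeps[[sw]], blocks,
                           n_draws = cfg$n_draws, seed = cfg$seed[1])
    agg <- sweep_agreement(gen, fwd)
    list(grid = sweeps[[sw]], agreement = agg,
         n_sign_matches = sum(agg$sign_match),
         amplitudes_generated = gen$amplitudes,
         amplitudes_forward = fwd$amplitudes)
  })
  names(out) <- names(sweeps)
  list(experiment = if (electrode_only) "E2" else "E1",
       n_subjects = cfg$n_subjects, seed = cfg$seed[1], blocks = blocks,
       final_losses = as.list(model$history[nrow(model$history), ]),
       sweeps = out)
}

run_survival_experiment <- function(cfg) {
  cohort <- simulate_cohort(cfg$n_subjects, seed = cfg$seed[1],
                            blocks = c("heart_position", "heart_orientation",
                                       "electrodes", "sex", "age", "bmi"))
  surv <- cohort$survival
  strata <- data.frame(subject_id = surv$subject_id,
                       stratum = ifelse(surv$event == 1, surv$subtype, "healthy"))
  split <- stratified_split(strata, test_frac = 0.2, seed = cfg$seed[1])
  test_idx <- match(split$test$subject_id, surv$subject_id)
  train_idx <- match(split$train$subject_id, surv$subject_id)
  subjects <- cohort$subjects
  arms <- lapply(names(cfg$arms), function(arm) {
    blocks <- cfg$arms[[arm]]
    cond <- if (length(blocks)) build_conditions(subjects, blocks)$values else NULL
    mcfg <- cfg$config
    if (is.null(mcfg)) mcfg <- cvae_config(epochs = cfg$epochs, seed = cfg$seed[1])
    model <- train_joint(cohort$beats[train_idx, , , drop = FALSE],
                         if (is.null(cond)) NULL else cond[train_idx, , drop = FALSE],
                         surv[train_idx, , drop = FALSE], mcfg)
    risks <- risk_score(model, cohort$beats[test_idx, , , drop = FALSE],
                        if (is.null(cond)) NULL else cond[test_idx, , drop = FALSE])
    test_surv <- surv[test_idx, , drop = FALSE]
    ci <- concordance_index(risks, test_surv)
    groups <- stratify_by_median(risks, test_surv)
    list(arm = arm, blocks = blocks, c_index = ci,
         event_frac_low = mean(groups$low$event),
         event_frac_high = mean(groups$high$event),
         km_low = kaplan_meier(groups$low), km_high = kaplan_meier(groups$high),
         test_ids = test_surv$subject_id, risks = risks)
  })
  names(arms) <- names(cfg$arms)
  ci_true <- concordance_index(surv$true_log_hazard[test_idx],
                               surv[test_idx, , drop = FALSE])
  list(experiment = "E3", n_subjects = cfg$n_subjects, seed = cfg$seed[1],
       c_index_true_ranking = ci_true,
       test_ids = surv$subject_id[test_idx],
       arms = lapply(arms, function(a) a[setdiff(names(a), c("km_low", "km_high"))]),
       km = lapply(arms, function(a) list(low = a$km_low, high = a$km_high)))
}

#' Compare conditioning arms of an E3 report
#'
#' @param report output of [run_experiment()] for E3 (or a list of arm
#'   sublists with `c_index` and `test_ids`)
#' @return data.frame of per-arm C-index plus pairwise differences
#' @export
compare_arms <- function(report) {
  arms <- if (!is.null(report$arms)) report$arms else report
  if (length(arms) < 2) abort_ecgvae("need at least 2 arms", "config_error")
  ids <- lapply(arms, function(a) a$test_ids)
  if (length(unique(vapply(ids, paste, character(1), collapse = "|"))) != 1) {
    abort_ecgvae("arms were evaluated on different test splits", "split_mismatch")
  }
  nm <- names(arms)
  ci <- vapply(arms, function(a) a$c_index, numeric(1))
  base <- data.frame(arm = nm, c_index = ci, row.names = NULL)
  deltas <- outer(ci, ci, `-`)
  dimnames(deltas) <- list(nm, nm)
  attr(base, "deltas") <- deltas
  base
}

write_experiment_figures <- function(report, cfg, out_dir) {
  if (report$experiment %in% c("E1", "E2")) {
    for (sw in names(report$sweeps)) {
      s <- report$sweeps[[sw]]
      df <- do.call(rbind, lapply(c("generated", "forward"), function(src) {
        m <- s[[paste0("amplitudes_", src)]]
        data.frame(lead = rep(rownames(m), ncol(m)),
                   value = rep(s$grid, each = nrow(m)),
                   amplitude = as.numeric(m), source = src)
      }))
      p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$amplitude,
                                            colour = .data$source)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::facet_wrap(~lead, scales = "free_y") +
        ggplot2::labs(x = sw, y = "Peak amplitude (raw units)") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(out_dir, paste0(report$experiment, "_", sw, ".png")),
                      p, width = 8, height = 6, dpi = 120)
    }
  } else if (report$experiment == "E3") {
    for (arm in names(report$km)) {
      km <- report$km[[arm]]
      df <- rbind(cbind(km$low, group = "low"), cbind(km$high, group = "high"))
      p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                            colour = .data$group, fill = .data$group)) +
        ggplot2::geom_step() +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             alpha = 0.2, colour = NA) +
        ggplot2::labs(x = "Follow-up (days)", y = "Survival probability",
                      title = paste("Arm:", arm)) +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(out_dir, paste0("E3_km_", arm, ".png")),
                      p, width = 6, height = 4, dpi = 120)
    }
  }
  invisible(NULL)
}
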