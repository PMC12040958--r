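# Survival components: Cox partial-likelihood loss on model risk scores,
# Harrell's concordance index, Kaplan-Meier estimation and median-risk
# stratification.

#' Construct survival records
#'
#' @param subject_id identifiers
#' @param time follow-up duration (days, > 0)
#' @param event 0 (censored) or 1 (CVD event)
#' @param subtype optional ICD-10 subtype labels
#' @return data.frame of class `survival_records`
#' @export
survival_records <- function(subject_id, time, event, subtype = NA_character_) {
  if (any(time <= 0) || !all(event %in% c(0, 1))) {
    abort_ecgvae("need time > 0 and event in {0,1}", "bad_input")
  }
  out <- data.frame(subject_id = as.character(subject_id), time = as.numeric(time),
                    event = as.integer(event), subtype = subtype,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_records", class(out))
  out
}

#' Cox partial-likelihood loss
#'
#' The negative of the scaled log partial likelihood
#' (1/N) sum_i delta_i (r_i - log sum_{j in R(t_i)} exp(r_j)), with risk set
#' R(t_i) = {j : t_j >= t_i}. The negation makes the loss something to
#' minimize, so it composes coherently with the reconstruction and KL terms.
#' Tied event times are handled in the Breslow manner: tied subjects share the
#' full risk set. Scores can be sigmoid risk scores or raw log-hazards; only
#' differences matter inside each term.
#'
#' @param risks numeric vector of model scores
#' @param records data.frame with `time` and `event` columns, same length
#' @return scalar loss (0 with a warning when the batch has no events)
#' @export
cox_loss <- function(risks, records) {
  n <- length(risks)
  stopifnot(n == nrow(records), n >= 2)
  delta <- records$event
  if (sum(delta) == 0) {
    warn_ecgvae("batch contains no events; Cox loss is 0", "degenerate_batch")
    return(0)
  }
  tt <- records$time
  # log sum_{j: t_j >= t_i} exp(r_j), computed over the reverse cumulative
  # sum of exp scores in time order (ties share the full risk set)
  ord <- order(tt)
  r_ord <- risks[ord]
  m <- max(r_ord)
  cs <- rev(cumsum(rev(exp(r_ord - m))))
  # collapse ties: every subject with the same time gets the risk-set sum
  # starting at the first occurrence of that time
  t_ord <- tt[ord]
  first_idx <- match(t_ord, t_ord)
  lse <- m + log(cs[first_idx])
  d_ord <- delta[ord]
  -(sum(d_ord * (r_ord - lse)) / n)
}

#' Gradient of [cox_loss()] with respect to the scores
#'
#' @param risks numeric score vector
#' @param records data.frame with `time` and `event`
#' @return numeric gradient vector
#' @export
cox_loss_grad <- function(risks, records) {
  n <- length(risks)
  delta <- records$event
  if (sum(delta) == 0) return(numeric(n))
  tt <- records$time
  er <- exp(risks - max(risks))
  g <- -delta
  for (i in which(delta == 1)) {
    at_risk <- tt >= tt[i]
    g[at_risk] <- g[at_risk] + er[at_risk] / sum(er[at_risk])
  }
  g / n
}

#' Total training loss
#'
#' Sum of the reconstruction, KL and survival terms with equal unit weights by
#' default.
#'
#' @param recon,kl,surv scalar loss terms
#' @param weights length-3 weights (default c(1, 1, 1))
#' @return scalar
#' @export
total_loss <- function(recon, kl, surv, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3, all(is.finite(c(recon, kl, surv))))
  weights[1] * recon + weights[2] * kl + weights[3] * surv
}

#' Harrell's concordance index
#'
#' Over all comparable pairs (i, j) with t_i < t_j and delta_i = 1, the
#' fraction in which the earlier-event subject carries the strictly higher
#' risk score; risk ties count one half. Returns 0.5 with a warning when no
#' pair is comparable.
#'
#' @param risks numeric risk scores (higher = riskier)
#' @param records data.frame with `time` and `event`
#' @return scalar in [0, 1]
#' @export
concordance_index <- function(risks, records) {
  n <- length(risks)
  stopifnot(n == nrow(records), n >= 2)
  tt <- records$time; delta <- records$event
  conc <- 0; comp <- 0
  for (i in which(delta == 1)) {
    later <- tt > tt[i]
    m <- sum(later)
    if (!m) next
    comp <- comp + m
    conc <- conc + sum(risks[i] > risks[later]) + 0.5 * sum(risks[i] == risks[later])
  }
  if (comp == 0) {
    warn_ecgvae("no comparable pairs; returning 0.5", "no_comparable_pairs")
    return(0.5)
  }
  conc / comp
}

#' Kaplan-Meier survival estimate with 95% confidence band
#'
#' Product-limit estimator with Greenwood variance and log-log transformed
#' confidence limits (via the survival package). A leading S(0) = 1 row is
#' included.
#'
#' @param records data.frame with `time` and `event`
#' @param conf_level confidence level (default 0.95)
#' @return data.frame: time, n_risk, n_event, surv, lower, upper
#' @export
kaplan_meier <- function(records, conf_level = 0.95) {
  stopifnot(nrow(records) >= 1)
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(nrow(records), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    surv = c(1, fit$surv),
                    lower = c(1, fit$lower),
                    upper = c(1, fit$upper))
  # no-event tail: survfit leaves CI at NA where S = 1
  out$lower[is.na(out$lower) & out$surv == 1] <- 1
  out$upper[is.na(out$upper) & out$surv == 1] <- 1
  out
}

#' Split subjects into low/high risk at the median risk score
#'
#' Subjects with risk <= median go to the low-risk group (ties at the median
#' are low risk), the rest to the high-risk group.
#'
#' @param risks numeric risk scores
#' @param records data.frame of the same length
#' @return list with `low` and `high` data.frames (records plus a `risk`
#'   column)
#' @export
stratify_by_median <- function(risks, records) {
  stopifnot(length(risks) == nrow(records), length(risks) >= 2)
  med <- stats::median(risks)
  records$risk <- risks
  list(low = records[risks <= med, , drop = FALSE],
       high = records[risks > med, , drop = FALSE])
}

#' Kaplan-Meier plot for risk strata
#'
#' @param groups list of data.frames with `time` and `event` (e.g. the output
#'   of [stratify_by_median()])
#' @param conf_level confidence level
#' @return a ggplot object
#' @export
km_plot <- function(groups, conf_level = 0.95) {
  dfs <- lapply(names(groups), function(nm) {
    km <- kaplan_meier(groups[[nm]], conf_level)
    km$group <- nm
    km
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group, fill = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::labs(x = "Follow-up time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Read a survival table from CSV
#'
#' Columns: subject_id, time_days (or time), event, subtype (optional).
#'
#' @param path CSV file
#' @return `survival_records`
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- if ("time_days" %in% names(df)) "time_days" else "time"
  survival_records(df$subject_id, df[[tcol]], df$event,
                   subtype = if ("subtype" %in% names(df)) df$subtype else NA)
}

#' Write a survival table to CSV
#'
#' @param records data.frame with subject_id, time, event (and optional
#'   subtype)
#' @param path output CSV file
#' @return `path`, invisibly
#' @export
write_survival_csv <- function(records, path) {
  out <- data.frame(subject_id = records$subject_id, time_days = records$time,
                    event = records$event,
                    subtype = if ("subtype" %in% names(records)) records$subtype else NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
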