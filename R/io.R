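# Dataset container I/O. Beat datasets bundle an N x 12 x 400 array with the
# condition matrix and its schema in a single RDS archive; tabular
# interchange (planes, electrodes, survival, demographics) is CSV.

#' Save a beats dataset
#'
#' @param beats N x 12 x 400 array
#' @param cond N x c condition matrix (may have 0 columns)
#' @param schema named condition block sizes
#' @param path output file (RDS)
#' @return `path`, invisibly
#' @export
save_beats <- function(beats, cond, schema, path) {
  stopifnot(length(dim(beats)) == 3)
  saveRDS(list(beats = beats, cond = cond, schema = schema), path)
  invisible(path)
}

#' Load a beats dataset
#'
#' @param path file written by [save_beats()]
#' @return list with `beats`, `cond`, `schema`
#' @export
load_beats <- function(path) readRDS(path)

#' Write a simulated cohort to a directory
#'
#' Emits beats.rds (beats + conditions + schema), planes.csv, electrodes.csv,
#' demographics.csv and survival.csv in the formats the other modules read.
#'
#' @param cohort output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_beats(cohort$beats, cohort$cond, cohort$schema, file.path(dir, "beats.rds"))
  planes <- lapply(cohort$subjects, function(s) planes_from_pose(s$pose))
  names(planes) <- vapply(cohort$subjects, function(s) s$subject_id, character(1))
  write_planes_csv(planes, file.path(dir, "planes.csv"))
  layouts <- lapply(cohort$subjects, function(s) s$layout)
  names(layouts) <- names(planes)
  write_electrodes_csv(layouts, file.path(dir, "electrodes.csv"))
  demo <- do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, age = s$demographics$age,
               sex = s$demographics$sex, bmi = s$demographics$bmi)
  }))
  utils::write.csv(demo, file.path(dir, "demographics.csv"), row.names = FALSE)
  write_survival_csv(cohort$survival, file.path(dir, "survival.csv"))
  invisible(dir)
}
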