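#' Cohort configuration
#'
#' Sampling design of the synthetic cohort: number of patients, high-grade
#' prevalence, grade effects on the clinical covariates, and the
#' train/validation split. The default prevalence 0.214 reflects a cohort
#' with roughly 110 high-grade cases out of 513; the default split is
#' 70/30. Clinical grade effects (male log-odds +0.5, age +6 years,
#' platelets +30 g/L in high grade) are calibration constants, not
#' estimates of any real cohort; nuisance covariates (hematuria, tumor
#' side) carry no grade effect so that univariate screening has true
#' negatives.
#'
#' @param n_patients Number of patients.
#' @param high_grade_prevalence Probability of high grade; default 0.214.
#' @param clinical_effects Named list of grade effects:
#'   `sex_log_odds`, `age_shift`, `platelet_shift`.
#' @param split_fractions Named numeric `c(train =, validation =)`, each in
#'   (0, 1), summing to at most 1; any remainder becomes a test split.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients,
                          high_grade_prevalence = 0.214,
                          clinical_effects = list(sex_log_odds = 0.5,
                                                  age_shift = 6,
                                                  platelet_shift = 30),
                          split_fractions = c(train = 0.7, validation = 0.3),
                          seed = 1) {
  if (high_grade_prevalence <= 0 || high_grade_prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1")
  }
  if (any(split_fractions <= 0) || any(split_fractions >= 1) ||
      sum(split_fractions) > 1 + 1e-9) {
    stop("split fractions must be in (0,1) and sum to at most 1")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         high_grade_prevalence = high_grade_prevalence,
         clinical_effects = clinical_effects,
         split_fractions = split_fractions, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort
#'
#' Draws grades at the configured prevalence, samples clinical covariates
#' with the configured grade effects, assigns train/validation(/test)
#' splits, and (optionally) generates the full multi-phase phantom for each
#' patient. With `volumes = FALSE` only the clinical table is produced,
#' which is convenient for covariate-screening studies at large n.
#'
#' @param config A `cohort_config`.
#' @param phantom A `phantom_config` used as the template for every patient
#'   (per-patient seeds and a mild tumor-radius jitter are derived from the
#'   cohort seed).
#' @param volumes Generate image volumes (`TRUE`) or clinical data only.
#' @return A `synthetic_cohort`: list with `patients` (list of
#'   `synthetic_patient`, empty when `volumes = FALSE`) and `table`, a
#'   tibble with columns `patient_id`, `split`, `grade`, `sex`, `age`,
#'   `platelets`, `hematuria`, `tumor_side`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 20, seed = 7),
#'                        volumes = FALSE)
#' dplyr::count(coh$table, grade)
#' @export
generate_cohort <- function(config, phantom = phantom_config(),
                            volumes = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  if (n == 0) {
    return(structure(list(patients = list(), table = empty_cohort_table()),
                     class = "synthetic_cohort"))
  }
  eff <- config$clinical_effects
  with_seed(config$seed, {
    grade <- rbinom(n, 1, config$high_grade_prevalence)
    if (length(unique(grade)) == 1) {
      warning("cohort contains a single grade class at this n/prevalence")
    }
    sex <- rbinom(n, 1, stats::plogis(qlogis_safe(0.6) + eff$sex_log_odds * grade))
    age <- rnorm(n, 55 + eff$age_shift * grade, 12)
    platelets <- rnorm(n, 250 + eff$platelet_shift * grade, 60)
    hematuria <- rbinom(n, 1, 0.3)
    tumor_side <- rbinom(n, 1, 0.5)

    fr <- config$split_fractions
    n_train <- round(fr[["train"]] * n)
    n_val <- round(fr[["validation"]] * n)
    n_val <- min(n_val, n - n_train)
    split <- c(rep("train", n_train), rep("validation", n_val),
               rep("test", n - n_train - n_val))
    split <- sample(split)

    ids <- sprintf("P%04d", seq_len(n))
    tab <- tibble::tibble(
      patient_id = ids, split = split,
      grade = ifelse(grade == 1, "high", "low"),
      sex = ifelse(sex == 1, "male", "female"),
      age = age, platelets = platelets,
      hematuria = hematuria, tumor_side = tumor_side
    )

    patients <- list()
    if (volumes) {
      seeds <- sample.int(.Machine$integer.max - 100000L, n)
      jitter <- runif(n, 0.85, 1.15)
      for (i in seq_len(n)) {
        cfg_i <- phantom
        cfg_i$seed <- seeds[i]
        cfg_i$tumor_radius_mm <- phantom$tumor_radius_mm * jitter[i]
        patients[[ids[i]]] <- generate_phantom(cfg_i, grade = grade[i],
                                               patient_id = ids[i])
      }
    }
    structure(list(patients = patients, table = tab),
              class = "synthetic_cohort")
  })
}

qlogis_safe <- function(p) log(p / (1 - p))

empty_cohort_table <- function() {
  tibble::tibble(patient_id = character(), split = character(),
                 grade = character(), sex = character(), age = numeric(),
                 platelets = numeric(), hematuria = integer(),
                 tumor_side = integer())
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (%d with volumes), %d high-grade\n",
              nrow(x$table), length(x$patients), sum(x$table$grade == "high")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes per-patient NIfTI volumes and masks, the cohort CSV, and a JSON
#' manifest recording the seeds and configuration.
#'
#' @param cohort A `synthetic_cohort` with volumes.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    pd <- file.path(dir, p$patient_id)
    dir.create(pd, showWarnings = FALSE)
    for (ph in names(p$phases)) {
      write_volume(p$phases[[ph]], file.path(pd, paste0(ph, ".nii.gz")))
    }
    write_volume(p$tumor_mask_reader1, file.path(pd, "mask_reader1.nii.gz"))
    write_volume(p$tumor_mask_reader2, file.path(pd, "mask_reader2.nii.gz"))
  }
  utils::write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  manifest <- list(n_patients = nrow(cohort$table),
                   patients = names(cohort$patients),
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
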