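# Cohort data contracts, readers/writers, class summaries ---------------------

.VISIT_COLUMNS <- c("subject_id", "time", "outcome", "test_version")
.BASELINE_COLUMNS <- c("subject_id", "arm", "age", "sex", "education",
                       "apoe4", "ptau217", "amyloid", "hipp_atrophy")

#' Read a cohort from CSV files
#'
#' Reads and validates the visit-level and baseline tables. Rows whose
#' numeric fields fail to parse are dropped and reported with their line
#' numbers; duplicated (subject, time) pairs are an error; subjects lacking a
#' baseline (time 0) visit are rejected with a count.
#'
#' @param visits_path,baseline_path CSV file paths (comma-delimited, UTF-8,
#'   header row).
#' @param require_baseline_visit Reject subjects without a time-0 visit.
#' @return A list with `visits` and `baseline` tibbles and a `report` of
#'   rejected rows/subjects.
#' @export
read_cohort <- function(visits_path, baseline_path,
                        require_baseline_visit = TRUE) {
  for (p in c(visits_path, baseline_path)) {
    if (!file.exists(p)) abort(sprintf("read_cohort(): file not found: %s", p))
  }
  vis_raw <- utils::read.csv(visits_path, colClasses = "character",
                             check.names = FALSE, fileEncoding = "UTF-8")
  bl_raw <- utils::read.csv(baseline_path, colClasses = "character",
                            check.names = FALSE, fileEncoding = "UTF-8")
  miss_v <- setdiff(.VISIT_COLUMNS, names(vis_raw))
  miss_b <- setdiff(.BASELINE_COLUMNS, names(bl_raw))
  if (length(miss_v) || length(miss_b)) {
    abort(sprintf("read_cohort(): missing required column(s): %s",
                  paste(c(miss_v, miss_b), collapse = ", ")))
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  visits <- tibble::tibble(
    subject_id = vis_raw$subject_id,
    time = num(vis_raw$time),
    outcome = num(vis_raw$outcome),
    test_version = vis_raw$test_version
  )
  if ("cdr_global" %in% names(vis_raw)) visits$cdr_global <- num(vis_raw$cdr_global)
  bad_rows <- which(!stats::complete.cases(visits[c("subject_id", "time", "outcome")]) |
                      visits$time < 0)
  if (length(bad_rows)) {
    warn(sprintf("read_cohort(): %d malformed visit row(s) dropped (lines %s).",
                 length(bad_rows),
                 paste(head(bad_rows + 1L, 10L), collapse = ", ")))
    visits <- visits[-bad_rows, ]
  }
  dup <- duplicated(visits[c("subject_id", "time")])
  if (any(dup)) {
    d1 <- visits[which(dup)[1L], ]
    abort(sprintf("read_cohort(): duplicated (subject, time) pair: (%s, %g).",
                  d1$subject_id, d1$time))
  }
  visits <- dplyr::arrange(visits, .data$subject_id, .data$time)

  baseline <- tibble::tibble(
    subject_id = bl_raw$subject_id,
    arm = bl_raw$arm,
    age = num(bl_raw$age),
    sex = bl_raw$sex,
    education = num(bl_raw$education),
    apoe4 = as.integer(num(bl_raw$apoe4)),
    ptau217 = num(bl_raw$ptau217),
    amyloid = num(bl_raw$amyloid),
    hipp_atrophy = num(bl_raw$hipp_atrophy)
  )
  if ("tau_pet" %in% names(bl_raw)) baseline$tau_pet <- num(bl_raw$tau_pet)
  bad_bl <- which(!stats::complete.cases(
    baseline[c("subject_id", "arm", "age", "education")]
  ))
  if (length(bad_bl)) {
    warn(sprintf("read_cohort(): %d malformed baseline row(s) dropped (lines %s).",
                 length(bad_bl),
                 paste(head(bad_bl + 1L, 10L), collapse = ", ")))
    baseline <- baseline[-bad_bl, ]
  }

  n_no_bl <- 0L
  if (require_baseline_visit) {
    has0 <- visits$subject_id[visits$time == 0]
    drop_ids <- setdiff(unique(visits$subject_id), has0)
    n_no_bl <- length(drop_ids)
    if (n_no_bl) {
      warn(sprintf("read_cohort(): %d subject(s) without a baseline visit rejected.",
                   n_no_bl))
      visits <- visits[!visits$subject_id %in% drop_ids, ]
      baseline <- baseline[!baseline$subject_id %in% drop_ids, ]
    }
  }
  list(
    visits = visits, baseline = baseline,
    report = list(bad_visit_rows = bad_rows, bad_baseline_rows = bad_bl,
                  subjects_without_baseline = n_no_bl)
  )
}

#' Write a cohort to CSV files
#'
#' @param cohort A `cohort_sim` (or any list with `visits` and `baseline`).
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; writes `<stem>_visits.csv`,
#'   `<stem>_baseline.csv` and a `<stem>_meta.yaml` with the seed and column
#'   schema.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, stem = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    visits = file.path(dir, paste0(stem, "_visits.csv")),
    baseline = file.path(dir, paste0(stem, "_baseline.csv")),
    meta = file.path(dir, paste0(stem, "_meta.yaml"))
  )
  utils::write.csv(cohort$visits, paths["visits"], row.names = FALSE)
  utils::write.csv(cohort$baseline, paths["baseline"], row.names = FALSE)
  yaml::write_yaml(list(
    seed = if (!is.null(cohort$params)) cohort$params$seed else NA,
    package_version = as.character(utils::packageVersion("cogtraj")),
    visit_columns = names(cohort$visits),
    baseline_columns = names(cohort$baseline)
  ), paths["meta"])
  invisible(paths)
}

#' Label clinical progression from a CDR global sequence
#'
#' A subject is a progressor iff the Clinical Dementia Rating global score
#' exceeds zero at two consecutive visits, or at the last visit.
#'
#' @param cdr Time-ordered numeric vector of CDR global scores for one
#'   subject.
#' @return `TRUE`/`FALSE`, or `NA` for an empty sequence.
#' @export
#' @examples
#' label_cdr_progression(c(0, 0, 0.5, 0.5))  # TRUE (consecutive rule)
#' label_cdr_progression(c(0, 0.5, 0, 0))    # FALSE
label_cdr_progression <- function(cdr) {
  cdr <- cdr[!is.na(cdr)]
  if (!length(cdr)) return(NA)
  pos <- cdr > 0
  any(pos[-1] & pos[-length(pos)]) || pos[length(pos)]
}

#' Class-level summary of baseline characteristics
#'
#' Builds the per-class counts and summaries used to characterise latent
#' classes: arm counts, means (SD) of continuous covariates, sex/APOE
#' counts, and CDR-progressor counts (via [label_cdr_progression()] when the
#' visits carry `cdr_global`).
#'
#' @param baseline,visits Cohort tables.
#' @param assignments Tibble with `subject_id` and `class`.
#' @return A list with `counts` (one row per class: `n`, `n_negative`,
#'   `n_placebo`, `n_active`, `n_female`, `n_apoe4`, `n_cdr_progressor`),
#'   `continuous` (per class x variable mean/SD), and `shares` from
#'   [class_share_summary()].
#' @export
class_summary_table <- function(baseline, visits, assignments) {
  cls <- assignments$class[match(baseline$subject_id, assignments$subject_id)]
  if (anyNA(cls)) abort("class_summary_table(): assignments must cover all subjects.")
  d <- dplyr::mutate(baseline, class = cls)
  prog <- if ("cdr_global" %in% names(visits)) {
    visits |>
      dplyr::arrange(.data$subject_id, .data$time) |>
      dplyr::summarise(progressor = label_cdr_progression(.data$cdr_global),
                       .by = "subject_id")
  } else {
    tibble::tibble(subject_id = baseline$subject_id, progressor = NA)
  }
  d$progressor <- prog$progressor[match(d$subject_id, prog$subject_id)]

  counts <- d |>
    dplyr::summarise(
      n = dplyr::n(),
      n_negative = sum(.data$arm == "negative-observational"),
      n_placebo = sum(.data$arm == "placebo"),
      n_active = sum(.data$arm == "active"),
      n_female = sum(.data$sex == "female"),
      n_apoe4 = sum(.data$apoe4 == 1),
      n_cdr_progressor = sum(.data$progressor %in% TRUE),
      .by = "class"
    ) |>
    dplyr::arrange(.data$class)

  cont_vars <- intersect(c("age", "education", "ptau217", "amyloid",
                           "hipp_atrophy", "tau_pet"), names(baseline))
  continuous <- d |>
    tidyr::pivot_longer(dplyr::all_of(cont_vars), names_to = "variable") |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .by = c("class", "variable"))

  list(counts = counts, continuous = continuous,
       shares = class_share_summary(counts))
}

#' Derived class shares from a class-counts table
#'
#' Computes the headline shares from a per-class counts table (as produced by
#' [class_summary_table()], or read from a published table): the stable share
#' of the whole cohort, the stable share among positive-study (placebo +
#' active) subjects, the decliner share among the negative-observational arm,
#' and the CDR-progressor share within each class.
#'
#' @param counts Tibble with columns `class`, `n`, `n_negative`, `n_placebo`,
#'   `n_active` and optionally `n_cdr_progressor`. The first row (or the row
#'   labelled `stable`) is the stable class.
#' @return A tibble (`share`, `numerator`, `denominator`, `percent`).
#' @export
class_share_summary <- function(counts) {
  cl <- as.character(counts$class)
  stable_i <- if ("stable" %in% cl) which(cl == "stable") else 1L
  dec_i <- setdiff(seq_len(nrow(counts)), stable_i)
  pos <- counts$n_placebo + counts$n_active
  out <- tibble::tibble(
    share = c("stable_overall", "stable_among_positive", "decliner_among_negative"),
    numerator = c(counts$n[stable_i], pos[stable_i], sum(counts$n_negative[dec_i])),
    denominator = c(sum(counts$n), sum(pos), sum(counts$n_negative))
  )
  if ("n_cdr_progressor" %in% names(counts)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      share = paste0("cdr_progressor_", cl),
      numerator = counts$n_cdr_progressor,
      denominator = counts$n
    ))
  }
  out$percent <- 100 * out$numerator / out$denominator
  out
}

#' Published class-level counts bundled with the package
#'
#' Loads the class-level counts of the reference study cohort (1629 subjects
#' in three trajectory classes) shipped as a plain-text fixture, for use with
#' [class_share_summary()].
#'
#' @return A tibble of per-class counts.
#' @export
published_class_counts <- function() {
  path <- system.file("extdata", "published_class_counts.csv", package = "cogtraj")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
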