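#' Read a longitudinal stroke clinical table
#'
#' Parses a wide per-patient TSV with columns `patient_id`, `age`, and
#' per-session triples `day_k`, `mi_k`, `nihss_k` (k = 1..n_sessions):
#' days post-stroke of each scan, Motricity Index (MI, 0-200; higher =
#' better motor function) and NIHSS (global stroke severity; lower =
#' better). Missing sessions are encoded as `-`, an en-dash, or an empty
#' cell and are kept as `NA` — never imputed. The packaged fixture
#' `system.file("extdata", "table1_clinical.tsv", package = "fcdlong")`
#' holds the study cohort of eight subcortical-stroke patients scanned at
#' up to five time points over one year.
#'
#' @param path path to the TSV file.
#' @param n_sessions planned number of sessions (columns expected per
#'   triple); default 5.
#' @return a `stroke_cohort`: a long tibble with one row per patient and
#'   planned session — columns `patient_id`, `age`, `session`, `day`,
#'   `mi`, `nihss` — plus attributes `n_sessions` and a per-patient scan
#'   count accessible via [cohort_demographics()].
#' @export
read_clinical_table <- function(path, n_sessions = 5L) {
  if (!file.exists(path)) abort(paste0("clinical table not found: ", path))
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (nrow(raw) == 0) abort("clinical table is empty")
  need <- c("patient_id", "age",
            paste0("day_", seq_len(n_sessions)),
            paste0("mi_", seq_len(n_sessions)),
            paste0("nihss_", seq_len(n_sessions)))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("clinical table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  num <- function(x, row) {
    x <- trimws(x)
    x[x %in% c("-", "–", "—", "", "NA")] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort(paste0("malformed value '", x[bad[1]], "' in row ", row[bad[1]]))
    }
    out
  }
  rows <- seq_len(nrow(raw))
  long <- tidyr::expand_grid(row = rows, session = seq_len(n_sessions))
  long <- dplyr::mutate(
    long,
    patient_id = raw$patient_id[.data$row],
    age = num(raw$age, rows)[.data$row],
    day = num(raw[cbind(.data$row, match(paste0("day_", .data$session), names(raw)))], .data$row),
    mi = num(raw[cbind(.data$row, match(paste0("mi_", .data$session), names(raw)))], .data$row),
    nihss = num(raw[cbind(.data$row, match(paste0("nihss_", .data$session), names(raw)))], .data$row)
  )
  long <- dplyr::select(long, "patient_id", "age", "session", "day", "mi", "nihss")
  new_stroke_cohort(long, n_sessions)
}

new_stroke_cohort <- function(tbl, n_sessions) {
  tbl <- tibble::as_tibble(tbl)
  validate_cohort(tbl, n_sessions)
  structure(tbl, n_sessions = as.integer(n_sessions),
            class = c("stroke_cohort", class(tbl)))
}

validate_cohort <- function(tbl, n_sessions) {
  if (nrow(tbl) == 0) abort("cohort has no records")
  for (pid in unique(tbl$patient_id)) {
    d <- tbl$day[tbl$patient_id == pid]
    d <- d[!is.na(d)]
    if (length(d) > 1 && any(diff(d) <= 0)) {
      abort(paste0("scan days not strictly increasing for patient ", pid))
    }
  }
  if (any(tbl$mi < 0 | tbl$mi > 200, na.rm = TRUE)) {
    abort("MI outside the 0-200 range")
  }
  if (any(tbl$nihss < 0, na.rm = TRUE)) abort("negative NIHSS")
  if (any(!tbl$session %in% seq_len(n_sessions))) {
    abort("session index outside the planned range")
  }
  invisible(tbl)
}

#' Build a stroke cohort from a long tibble
#'
#' @param tbl tibble with columns `patient_id`, `age`, `session`, `day`,
#'   `mi`, `nihss` (missing sessions as `NA`).
#' @param n_sessions planned number of sessions.
#' @return a `stroke_cohort` tibble.
#' @export
as_stroke_cohort <- function(tbl, n_sessions = max(tbl$session)) {
  new_stroke_cohort(tbl, n_sessions)
}

#' Scan-timing statistics per session
#'
#' Mean, sample standard deviation (n-1 denominator) and count of the
#' non-missing days post-stroke at each session.
#'
#' @param cohort a `stroke_cohort`.
#' @param session optional single session index; default all sessions.
#' @return tibble with columns `session`, `mean_day`, `sd_day`, `n`.
#' @export
session_interval_stats <- function(cohort, session = NULL) {
  n_sessions <- attr(cohort, "n_sessions")
  if (!is.null(session)) {
    if (!session %in% seq_len(n_sessions)) {
      abort(paste0("session ", session, " out of range 1..", n_sessions))
    }
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), session = .data$session),
    mean_day = mean(.data$day, na.rm = TRUE),
    sd_day = sd(.data$day, na.rm = TRUE),
    n = sum(!is.na(.data$day)),
    .groups = "drop"
  )
  if (!is.null(session)) {
    out <- out[out$session == session, ]
    if (out$n < 2) abort("fewer than two attended scans at this session")
  } else if (any(out$n < 2)) {
    abort("fewer than two attended scans at some session")
  }
  out
}

#' Cohort demographics and attendance
#'
#' @param cohort a `stroke_cohort`.
#' @return one-row tibble: `mean_age`, `age_min`, `age_max`, `n_patients`,
#'   `n_complete` (patients attending every planned session).
#' @export
cohort_demographics <- function(cohort) {
  n_sessions <- attr(cohort, "n_sessions")
  per <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), .data$patient_id),
    age = .data$age[1],
    n_scans = sum(!is.na(.data$day)),
    .groups = "drop"
  )
  if (any(is.na(per$age))) abort("missing age in cohort")
  tibble::tibble(
    mean_age = mean(per$age),
    age_min = min(per$age),
    age_max = max(per$age),
    n_patients = nrow(per),
    n_complete = sum(per$n_scans == n_sessions)
  )
}

#' Per-patient scan counts
#'
#' @param cohort a `stroke_cohort`.
#' @return tibble with `patient_id`, `n_scans`.
#' @export
scan_counts <- function(cohort) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), .data$patient_id),
    n_scans = sum(!is.na(.data$day)), .groups = "drop"
  )
}

#' Centre scores within a patient
#'
#' Subtracts the non-missing mean from a vector of per-session scores, the
#' normalisation used when a clinical score enters the longitudinal model
#' as predictor. Missing entries stay missing.
#'
#' @param x numeric vector of per-session scores (NA allowed).
#' @return centred vector summing to zero over non-missing entries.
#' @export
center_scores <- function(x) {
  if (all(is.na(x))) abort("all scores missing; cannot centre")
  x - mean(x, na.rm = TRUE)
}

#' Subject-centred clinical scores for association models
#'
#' Adds a `score_centered` column: the chosen score minus its
#' subject-specific mean over attended sessions.
#'
#' @param cohort a `stroke_cohort`.
#' @param which `"mi"` or `"nihss"`.
#' @return the cohort tibble with columns `score` and `score_centered`.
#' @export
normalize_scores <- function(cohort, which = c("mi", "nihss")) {
  which <- match.arg(which)
  tbl <- tibble::as_tibble(cohort)
  tbl$score <- tbl[[which]]
  out <- dplyr::mutate(
    dplyr::group_by(tbl, .data$patient_id),
    score_centered = center_scores(.data$score)
  )
  dplyr::ungroup(out)
}

#' Paired test of clinical recovery
#'
#' Compares each patient's first versus last attended session score with
#' both a paired t-test and an exact paired Wilcoxon signed-rank test.
#' Recovery is an increase for MI and a decrease for NIHSS; `direction`
#' is +1 when the mean change points the recovery way.
#'
#' @param cohort a `stroke_cohort`.
#' @param which `"mi"` or `"nihss"`.
#' @return tibble with rows per method: `method`, `statistic`, `p_value`,
#'   `direction`, `n`.
#' @export
recovery_test <- function(cohort, which = c("mi", "nihss")) {
  which <- match.arg(which)
  tbl <- tibble::as_tibble(cohort)
  per <- dplyr::summarise(
    dplyr::group_by(tbl, .data$patient_id),
    first = { s <- .data[[which]][!is.na(.data[[which]])]
              if (length(s) > 0) s[1] else NA_real_ },
    last = { s <- .data[[which]][!is.na(.data[[which]])]
             if (length(s) > 0) s[length(s)] else NA_real_ },
    .groups = "drop"
  )
  per <- per[!is.na(per$first) & !is.na(per$last), ]
  if (nrow(per) < 3) abort("need at least 3 patients with both endpoints")
  diffs <- per$last - per$first
  if (which == "nihss") diffs <- -diffs  # recovery = decrease
  direction <- sign(mean(diffs))
  if (all(diffs == 0)) {
    return(tibble::tibble(
      method = c("paired_t", "wilcoxon_signed_rank"),
      statistic = c(0, 0), p_value = c(1, 1),
      direction = 0, n = nrow(per)
    ))
  }
  if (sd(diffs) == 0) {
    # every patient changed by the identical nonzero amount: the paired t
    # is degenerate (infinite); report it as such
    tt <- list(statistic = c(t = Inf * sign(mean(diffs))),
               p.value = .Machine$double.xmin)
  } else {
    tt <- t.test(diffs)
  }
  wt <- suppressWarnings(wilcox.test(diffs, exact = NULL))
  tibble::tibble(
    method = c("paired_t", "wilcoxon_signed_rank"),
    statistic = c(unname(tt$statistic), unname(wt$statistic)),
    p_value = c(tt$p.value, wt$p.value),
    direction = direction,
    n = nrow(per)
  )
}
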