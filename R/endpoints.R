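## Exclusion cascade and endpoint construction.

#' Apply the missing-data exclusion cascade
#'
#' Removes the union of participants flagged by each exclusion criterion
#' (missing baseline BMI; missing outcome records) and returns both the
#' reduced cohort and a ledger with per-criterion counts, pairwise overlaps
#' and the final n. The ledger satisfies inclusion-exclusion exactly:
#' `final n = initial n - |union of excluded sets|`.
#'
#' @param cohort Cohort data frame with `bmi` and `obesity_event` columns.
#' @param extra Optional named list of additional logical exclusion flags
#'   (length `nrow(cohort)` each).
#' @return A list with elements `cohort` (rows kept) and `ledger`
#'   (class `exclusion_ledger`).
#' @export
apply_exclusions <- function(cohort, extra = NULL) {
  criteria <- list(missing_bmi = is.na(cohort$bmi),
                   missing_outcome = is.na(cohort$obesity_event))
  if (!is.null(extra)) {
    stopifnot(is.list(extra), !is.null(names(extra)))
    criteria <- c(criteria, extra)
  }
  flags <- vapply(criteria, function(f) as.logical(f), logical(nrow(cohort)))
  flags <- matrix(flags, nrow = nrow(cohort),
                  dimnames = list(NULL, names(criteria)))
  excluded <- rowSums(flags) > 0
  k <- ncol(flags)
  overlap <- crossprod(flags)  # pairwise (and self) intersection counts
  ledger <- structure(list(
    initial_n = nrow(cohort),
    counts = colSums(flags),
    overlap = overlap,
    union_n = sum(excluded),
    final_n = nrow(cohort) - sum(excluded)), class = "exclusion_ledger")
  list(cohort = cohort[!excluded, , drop = FALSE], ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("Exclusion cascade: %d -> %d (removed %d)\n",
              x$initial_n, x$final_n, x$union_n))
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  if (length(x$counts) > 1) {
    pairs <- utils::combn(names(x$counts), 2)
    for (i in seq_len(ncol(pairs)))
      cat(sprintf("  overlap %s & %s: %d\n", pairs[1, i], pairs[2, i],
                  x$overlap[pairs[1, i], pairs[2, i]]))
  }
  invisible(x)
}

#' Serialize an exclusion ledger to JSON
#' @param ledger An `exclusion_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(list(initial_n = ledger$initial_n,
                            counts = as.list(ledger$counts),
                            overlap = as.data.frame(as.table(ledger$overlap)),
                            union_n = ledger$union_n,
                            final_n = ledger$final_n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deterministic missingness-pattern fixture
#'
#' Builds a minimal cohort in which exactly `n_both` participants are missing
#' both BMI and outcome data, `n_missing_bmi - n_both` are missing BMI only
#' and `n_missing_outcome - n_both` outcome only, for exercising
#' [apply_exclusions()] against known flow counts.
#'
#' @param n Total participants.
#' @param n_missing_bmi,n_missing_outcome,n_both Pattern counts (each total
#'   includes the `n_both` overlap).
#' @return A data frame with `participant_id`, `bmi`, `obesity_event`,
#'   `obesity_time`.
#' @export
exclusion_fixture <- function(n, n_missing_bmi, n_missing_outcome, n_both) {
  stopifnot(n_both <= n_missing_bmi, n_both <= n_missing_outcome,
            n_missing_bmi + n_missing_outcome - n_both <= n)
  bmi <- rep(27, n)
  ev <- rep(0L, n)
  bmi[seq_len(n_missing_bmi)] <- NA_real_
  out_idx <- c(seq_len(n_both),
               n_missing_bmi + seq_len(n_missing_outcome - n_both))
  ev[out_idx] <- NA_integer_
  data.frame(participant_id = seq_len(n), bmi = bmi,
             obesity_event = ev, obesity_time = ifelse(is.na(ev), NA_real_, 10))
}

#' Prevalent obesity flag
#'
#' Boundary-inclusive: BMI of exactly 30 kg/m2 counts as obese.
#'
#' @param x A numeric BMI vector, or a cohort data frame with a `bmi` column.
#' @return Integer 0/1 flags (NA where BMI is missing).
#' @export
prevalent_obesity <- function(x) {
  bmi <- if (is.data.frame(x)) x$bmi else x
  if (is.null(bmi)) stop_gx("no bmi column found")
  as.integer(bmi >= 30)
}

#' Incident endpoint from per-source event times
#'
#' Resolves the earliest event record across sources, censors non-cases at
#' the earliest of death, loss to follow-up and the administrative horizon,
#' and flags events on or before enrollment (time <= 0) as prevalent rather
#' than incident (the follow-up interval is half-open: `(0, horizon]`).
#'
#' @param source_times Data frame / matrix of per-source event times in years
#'   from enrollment (NA = no record in that source), one row per participant.
#' @param horizon Administrative censoring horizon in years (> 0).
#' @param death_time,loss_time Optional per-participant censoring times.
#' @return Data frame with integer `event`, numeric `time` and integer
#'   `prevalent` columns; prevalent rows carry NA event/time.
#' @export
incident_endpoint <- function(source_times, horizon,
                              death_time = Inf, loss_time = Inf) {
  if (horizon <= 0) stop_gx("horizon must be > 0")
  st <- as.matrix(as.data.frame(source_times))
  earliest <- suppressWarnings(apply(st, 1, min, na.rm = TRUE))  # Inf if none
  censor <- pmin(death_time, loss_time, horizon)
  prevalent <- is.finite(earliest) & earliest <= 0
  event <- as.integer(!prevalent & earliest <= censor)
  time <- pmin(earliest, censor)
  event[prevalent] <- NA_integer_
  time[prevalent] <- NA_real_
  data.frame(event = event, time = time, prevalent = as.integer(prevalent))
}

#' BMI-threshold incident obesity from follow-up measurements
#'
#' Eligibility is explicit: baseline BMI below 30 and at least one follow-up
#' BMI measurement. A case is any eligible participant with a follow-up BMI
#' at or above 30 kg/m2.
#'
#' @param baseline_bmi Numeric baseline BMI.
#' @param followup_bmi Data frame / matrix of follow-up BMI measurements (NA
#'   where unmeasured), one row per participant.
#' @return Data frame with integer `eligible` and `case` columns (`case` is NA
#'   for ineligible rows).
#' @export
bmi_threshold_incidence <- function(baseline_bmi, followup_bmi) {
  fu <- as.matrix(as.data.frame(followup_bmi))
  has_fu <- rowSums(!is.na(fu)) > 0
  eligible <- !is.na(baseline_bmi) & baseline_bmi < 30 & has_fu
  case <- as.integer(apply(fu >= 30, 1, any, na.rm = TRUE))
  case[!eligible] <- NA_integer_
  data.frame(eligible = as.integer(eligible), case = case)
}

#' Long-format endpoint records
#'
#' Reshapes the wide per-endpoint event/time columns into the long layout
#' `(participant_id, endpoint, event, time)`.
#'
#' @param cohort Cohort with `*_event` / `*_time` column pairs.
#' @return Long data frame.
#' @export
endpoint_records <- function(cohort) {
  ev_cols <- grep("_event$", names(cohort), value = TRUE)
  out <- lapply(ev_cols, function(ec) {
    nm <- sub("_event$", "", ec)
    data.frame(participant_id = cohort$participant_id, endpoint = nm,
               event = cohort[[ec]], time = cohort[[paste0(nm, "_time")]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
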