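#' Apply cohort inclusion/exclusion rules
#'
#' Filters an encounter table through the exclusion cascade, in this fixed
#' order: (1) out-of-state residence, (2) endocrine neck surgery within the
#' prior six months, (3) low-volume facility -- a facility is excluded when
#' its mean annual volume over the study window falls below
#' \code{min_annual_volume} -- and, when \code{system_mode} is on,
#' (4) facilities with no health-system affiliation or belonging to a
#' single-facility system.  Each rule is a row-level predicate, so the final
#' cohort does not depend on the order; the order only attributes removals
#' in the log.  Facility volume is computed on the cohort remaining after
#' the patient-level exclusions, divided by the number of distinct discharge
#' years observed.
#'
#' @param encounters Encounter table carrying \code{out_of_state},
#'   \code{prior_neck_surgery_6mo}, \code{facility_id},
#'   \code{discharge_year}.
#' @param facilities Facility table (needed for system affiliation when
#'   \code{system_mode = TRUE}; may be omitted otherwise).
#' @param min_annual_volume Minimum mean cases/year for a facility to stay
#'   in the cohort (default 10).
#' @param system_mode Restrict to facilities in multi-facility health
#'   systems (the health-system reassignment analysis).
#' @return List with \code{cohort} (the filtered encounters) and
#'   \code{log}, an \code{exclusion_log} data frame of
#'   \code{(rule, n_removed, n_remaining)} with attribute \code{initial_n}.
#' @export
apply_exclusions <- function(encounters, facilities = NULL,
                             min_annual_volume = 10, system_mode = FALSE) {
  assert_columns(encounters,
                 c("out_of_state", "prior_neck_surgery_6mo", "facility_id",
                   "discharge_year"), "encounters")
  initial_n <- nrow(encounters)
  log <- data.frame(rule = character(), n_removed = integer(),
                    n_remaining = integer(), stringsAsFactors = FALSE)
  note <- function(rule, keep) {
    log <<- rbind(log, data.frame(
      rule = rule, n_removed = sum(!keep), n_remaining = sum(keep),
      stringsAsFactors = FALSE))
    encounters[keep, , drop = FALSE]
  }

  encounters <- note("out_of_state", !encounters$out_of_state)
  encounters <- note("prior_neck_surgery_6mo",
                     !encounters$prior_neck_surgery_6mo)

  n_years <- length(unique(encounters$discharge_year))
  vol <- table(encounters$facility_id) / max(n_years, 1)
  low <- names(vol)[vol < min_annual_volume]
  encounters <- note("low_volume_facility",
                     !(encounters$facility_id %in% low))

  if (system_mode) {
    if (is.null(facilities))
      stop_config("system_mode requires the facility table")
    assert_columns(facilities, c("facility_id", "system_id"), "facilities")
    sys_size <- table(facilities$system_id[!is.na(facilities$system_id)])
    multi <- names(sys_size)[sys_size >= 2]
    ok_fac <- facilities$facility_id[
      !is.na(facilities$system_id) & facilities$system_id %in% multi]
    encounters <- note("no_system_or_single_facility_system",
                       encounters$facility_id %in% ok_fac)
  }

  attr(log, "initial_n") <- initial_n
  class(log) <- c("exclusion_log", "data.frame")
  list(cohort = encounters, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("Exclusion cascade (initial n = %d)\n", attr(x, "initial_n")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Random 80/20 train/test split
#'
#' Simple random sampling without replacement at the patient level.  The
#' train size is \code{floor(train_fraction * n)}; the remainder goes to
#' the test cohort.  Membership depends only on the set of patient ids and
#' the seed, never on row order.
#'
#' @param cohort Encounter table with a \code{patient_id} column.
#' @param train_fraction Proportion assigned to training, in (0, 1);
#'   default 0.8.
#' @param split_seed Integer seed of the split.
#' @return List with \code{train} and \code{test} data frames,
#'   \code{train_ids}, \code{test_ids}, and the split parameters.
#' @export
split_train_test <- function(cohort, train_fraction = 0.8, split_seed = 1L) {
  if (!nrow(cohort)) stop_config("cohort is empty")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must lie strictly between 0 and 1")
  assert_columns(cohort, "patient_id", "cohort")
  ids <- sort(unique(cohort$patient_id))
  if (length(ids) != nrow(cohort))
    stop_config("patient_id must be unique (one encounter per patient)")
  n_train <- floor(train_fraction * length(ids))
  train_ids <- with_seed(split_seed, sample(ids, n_train))
  in_train <- cohort$patient_id %in% train_ids
  list(train = cohort[in_train, , drop = FALSE],
       test = cohort[!in_train, , drop = FALSE],
       train_ids = sort(train_ids),
       test_ids = setdiff(ids, train_ids),
       train_fraction = train_fraction,
       split_seed = split_seed)
}
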