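#' A small synthetic clinical code list
#'
#' Builds an illustrative include/exclude code list with balance-related
#' fall codes, non-balance fall codes (the excluded "other fall"
#' category), and non-fall codes across the ICD-10 (hospital) and Read v2
#' / v3 (primary-care) vocabularies. The codes are synthetic stand-ins
#' shaped like the real vocabularies, not a clinical resource.
#'
#' @return A `code_list` tibble with columns `vocabulary`, `code`,
#'   `category`, `description`.
#' @export
example_code_list <- function() {
  new_code_list(tibble(
    vocabulary = c(
      "ICD10", "ICD10", "ICD10", "ICD10", "ICD10", "ICD10",
      "READ2", "READ2", "READ2", "READ3", "READ3", "READ3"
    ),
    code = c(
      "W00", "W01", "W18", "W16", "I10", "J45",
      "TC00.", "TC01.", "H33..", "X70Aa", "X70Ab", "XE0Yd"
    ),
    category = c(
      "balance_fall", "balance_fall", "balance_fall", "other_fall",
      "non_fall", "non_fall",
      "balance_fall", "other_fall", "non_fall",
      "balance_fall", "other_fall", "non_fall"
    ),
    description = c(
      "Fall on same level due to slipping", "Fall involving tripping",
      "Other fall on same level", "Fall into water (diving)",
      "Essential hypertension", "Asthma",
      "Accidental fall on same level", "Fall into water",
      "Asthma review", "Fall on same level", "Fall from boat",
      "Hypertension monitoring"
    )
  ))
}

#' Simulate a coded clinical event log from a phenotyped cohort
#'
#' Emits, for every case, `fall_count` distinct fall dates, each carrying
#' one to three distinct balance-fall codes (possibly from different
#' vocabularies/sources), so the same-date deduplication rule is
#' exercised. Controls receive only non-fall codes. A configurable
#' fraction of persons is flagged "no records" and emits nothing,
#' exercising the exclusion rule. Hospital (HES/ICD-10) dates fall within
#' 1995-2021 and primary-care (GP/Read) dates within 1955-2017.
#'
#' @param cohort Cohort tibble (from [simulate_traits()]) with
#'   `person_id`, `fall_status`, `fall_count`.
#' @param code_list A `code_list` (e.g. [example_code_list()]) whose
#'   include set is the `balance_fall` category.
#' @param no_record_fraction Fraction of persons emitting zero rows.
#' @param seed Integer seed.
#' @return A list of class `"fallmr_event_log"` with `events` (tibble:
#'   `person_id`, `source`, `vocabulary`, `code`, `event_date`) and
#'   `no_record_persons` (character vector).
#' @export
simulate_event_log <- function(cohort, code_list = example_code_list(),
                               no_record_fraction = 0.02, seed = 1L) {
  assert_columns(cohort, c("person_id", "fall_status", "fall_count"),
                 "cohort")
  stopifnot(inherits(code_list, "code_list"))
  fall_codes <- dplyr::filter(code_list, category == "balance_fall")
  if (nrow(fall_codes) == 0) {
    config_error("code list has no balance_fall codes to draw from")
  }
  non_fall <- dplyr::filter(code_list, category == "non_fall")
  if (nrow(non_fall) == 0) {
    config_error("code list has no non_fall codes to draw from")
  }
  set.seed(seed + 4000L)

  n <- nrow(cohort)
  no_rec <- cohort$person_id[runif(n) < no_record_fraction]
  active <- dplyr::filter(cohort, !(person_id %in% no_rec))

  hes_dates <- seq(as.Date("1995-01-01"), as.Date("2021-12-31"), by = "day")
  gp_dates <- seq(as.Date("1955-01-01"), as.Date("2017-12-31"), by = "day")
  src_of <- function(vocab) if_else(vocab == "ICD10", "HES", "GP")
  date_pool <- function(vocab) {
    if (vocab == "ICD10") hes_dates else gp_dates
  }

  per_person <- function(pid, is_case, fc) {
    rows <- list()
    if (is_case && fc > 0) {
      # fall dates are drawn per source so vocabulary/date windows agree
      k_codes <- sample(1:3, fc, replace = TRUE)
      picks <- lapply(k_codes, function(k) {
        fall_codes[sample(nrow(fall_codes), min(k, nrow(fall_codes))), ]
      })
      used <- as.Date(character(0))
      for (i in seq_len(fc)) {
        pk <- picks[[i]]
        vocab0 <- pk$vocabulary[1]
        pool <- setdiff(date_pool(vocab0), used)
        d <- as.Date(sample(pool, 1), origin = "1970-01-01")
        used <- c(used, d)
        # same-date rows in HES and GP windows both only when the date fits
        ok <- vapply(pk$vocabulary, function(v) {
          d %in% date_pool(v)
        }, logical(1))
        pk <- pk[ok, , drop = FALSE]
        if (nrow(pk) == 0) pk <- fall_codes[match(vocab0, fall_codes$vocabulary), ]
        rows[[length(rows) + 1L]] <- tibble(
          person_id = pid,
          source = src_of(pk$vocabulary),
          vocabulary = pk$vocabulary,
          code = pk$code,
          event_date = d
        )
      }
    }
    # everyone active gets at least one benign record
    nf <- non_fall[sample(nrow(non_fall), 1), ]
    rows[[length(rows) + 1L]] <- tibble(
      person_id = pid,
      source = src_of(nf$vocabulary),
      vocabulary = nf$vocabulary,
      code = nf$code,
      event_date = as.Date(sample(date_pool(nf$vocabulary), 1),
                           origin = "1970-01-01")
    )
    dplyr::bind_rows(rows)
  }

  events <- dplyr::bind_rows(purrr::pmap(
    list(active$person_id, active$fall_status == "case", active$fall_count),
    per_person
  ))
  structure(
    list(events = events, no_record_persons = no_rec,
         code_list = code_list, seed = seed),
    class = "fallmr_event_log"
  )
}
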