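#' Construct and validate a clinical code list
#'
#' A code list assigns every (vocabulary, code) pair to one of three
#' categories: `balance_fall` (the case-defining include set),
#' `other_fall` (fall codes judged unrelated to balance, e.g. falls into
#' water, which disqualify a person from being a control without making
#' them a case) and `non_fall` (ordinary clinical activity).
#'
#' @param entries Data frame with columns `vocabulary`
#'   (`ICD10`/`READ2`/`READ3`), `code`, `category`
#'   (`balance_fall`/`other_fall`/`non_fall`) and optionally
#'   `description`.
#' @return The validated tibble with class `code_list`.
#' @export
new_code_list <- function(entries) {
  entries <- as_tibble(entries)
  assert_columns(entries, c("vocabulary", "code", "category"), "code list")
  if (!"description" %in% names(entries)) entries$description <- ""
  bad_vocab <- which(!entries$vocabulary %in% c("ICD10", "READ2", "READ3"))
  if (length(bad_vocab) > 0) {
    config_error(sprintf("unknown vocabulary in code-list row(s) %s",
                         paste(bad_vocab, collapse = ", ")))
  }
  bad_cat <- which(!entries$category %in%
                     c("balance_fall", "other_fall", "non_fall"))
  if (length(bad_cat) > 0) {
    config_error(sprintf("unknown category in code-list row(s) %s",
                         paste(bad_cat, collapse = ", ")))
  }
  dup <- duplicated(entries[, c("vocabulary", "code")])
  if (any(dup)) {
    config_error(sprintf("duplicated (vocabulary, code) in row(s) %s",
                         paste(which(dup), collapse = ", ")))
  }
  if (nrow(entries) == 0) {
    warn("code list is empty")
  }
  structure(entries[, c("vocabulary", "code", "category", "description")],
            class = c("code_list", class(tibble())))
}

#' Read a code list from CSV
#'
#' Expects columns `vocabulary`, `code`, `category`, `description`.
#'
#' @param path Path to a CSV file.
#' @return A validated [new_code_list()] tibble.
#' @export
read_code_list <- function(path) {
  if (!file.exists(path)) config_error(sprintf("no such file: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  new_code_list(raw)
}

# events joined to the code list; unlisted codes become "non_fall" records
# (any coded contact keeps a person in the denominator); rows whose
# vocabulary contradicts their source are dropped with a warning
classify_events <- function(events, code_list, sources) {
  assert_columns(events,
                 c("person_id", "source", "vocabulary", "code", "event_date"),
                 "event log")
  if (length(sources) == 0) config_error("source set must be non-empty")
  bad_src <- !events$source %in% c("HES", "GP")
  if (any(bad_src)) {
    config_error("event log contains sources other than HES/GP")
  }
  mismatch <- (events$source == "HES" & events$vocabulary != "ICD10") |
    (events$source == "GP" & !events$vocabulary %in% c("READ2", "READ3"))
  if (any(mismatch)) {
    warn(sprintf(
      "dropping %d event row(s) whose vocabulary contradicts the source",
      sum(mismatch)
    ))
    events <- events[!mismatch, , drop = FALSE]
  }
  events |>
    filter(source %in% sources) |>
    left_join(code_list[, c("vocabulary", "code", "category")],
              by = c("vocabulary", "code")) |>
    mutate(category = if_else(is.na(category), "non_fall", category))
}

#' Derive per-person fall case/control status from a coded event log
#'
#' Applies the record-based case/control rule: a person is a *case* if
#' they carry at least one balance-fall code in the selected sources; a
#' *control* if they have at least one record of any kind in the selected
#' sources and no fall code of any category (any fall code disqualifies a
#' control); and *excluded* otherwise — either no records in the selected
#' sources, or fall codes only of the non-balance (`other_fall`)
#' category, which make a person neither case nor control.
#'
#' @param events Event-log tibble with columns `person_id`, `source`
#'   (`HES`/`GP`), `vocabulary`, `code`, `event_date`.
#' @param code_list A [new_code_list()].
#' @param sources Subset of `c("HES", "GP")` defining the metric
#'   (combined, hospital-only, primary-care-only).
#' @param persons Optional character vector of the full person universe;
#'   persons absent from the (filtered) log are reported as `excluded`.
#' @return Tibble: `person_id`, `status`
#'   (`case`/`control`/`excluded`), `reason`, `fall_count` (distinct
#'   balance-fall dates; 0 for non-cases), `first_fall_date`.
#' @export
derive_fall_status <- function(events, code_list,
                               sources = c("HES", "GP"),
                               persons = NULL) {
  if (nrow(code_list) == 0) config_error("code list is empty")
  ev <- classify_events(events, code_list, sources)
  per <- ev |>
    group_by(person_id) |>
    summarise(
      n_records = n(),
      any_balance = any(category == "balance_fall"),
      any_other = any(category == "other_fall"),
      .groups = "drop"
    )
  counts <- ev |>
    filter(category == "balance_fall") |>
    distinct(person_id, event_date) |>
    group_by(person_id) |>
    summarise(fall_count = n(),
              first_fall_date = if (n() > 0) min(event_date) else as.Date(NA),
              .groups = "drop")
  out <- per |>
    left_join(counts, by = "person_id") |>
    mutate(
      fall_count = if_else(is.na(fall_count), 0L, as.integer(fall_count)),
      status = case_when(
        any_balance ~ "case",
        any_other ~ "excluded",
        n_records > 0 ~ "control",
        TRUE ~ "excluded"
      ),
      reason = case_when(
        any_balance ~ "balance_fall_code",
        any_other ~ "other_fall_only",
        n_records > 0 ~ "records_no_fall_codes",
        TRUE ~ "no_records"
      )
    ) |>
    select(person_id, status, reason, fall_count, first_fall_date)
  if (!is.null(persons)) {
    absent <- setdiff(persons, out$person_id)
    if (length(absent) > 0) {
      out <- bind_rows(out, tibble(
        person_id = absent, status = "excluded", reason = "no_records",
        fall_count = 0L, first_fall_date = as.Date(NA)
      ))
    }
    out <- out[match(persons, out$person_id), ]
  }
  out
}

#' Count falls as distinct balance-fall dates
#'
#' Multiple distinct fall codes recorded on the same calendar date count
#' as a single fall; the same code on different dates counts once per
#' date.
#'
#' @inheritParams derive_fall_status
#' @return Tibble `person_id`, `fall_count` for every person in the log
#'   (0 when no balance-fall dates).
#' @export
count_falls <- function(events, code_list, sources = c("HES", "GP")) {
  ev <- classify_events(events, code_list, sources)
  ev |>
    distinct(person_id) |>
    left_join(
      ev |>
        filter(category == "balance_fall") |>
        distinct(person_id, event_date) |>
        count(person_id, name = "fall_count"),
      by = "person_id"
    ) |>
    mutate(fall_count = if_else(is.na(fall_count), 0L,
                                as.integer(fall_count)))
}

#' Cross-tabulate record-derived fall status against self-report
#'
#' @param phenotype Output of [derive_fall_status()].
#' @param self_report Tibble `person_id`, `self_report` (logical).
#' @return Tibble with one row per status (`case`, `control`): `n`,
#'   `n_self_report`, `percent` (rounded to the nearest integer percent).
#' @export
cross_tabulate <- function(phenotype, self_report) {
  assert_columns(self_report, c("person_id", "self_report"), "self report")
  orphans <- symdiff_keys(phenotype$person_id, self_report$person_id)
  if (length(orphans) > 0) {
    config_error(sprintf(
      "person keys do not align; %d orphan id(s), e.g. %s",
      length(orphans), paste(head(orphans, 3), collapse = ", ")
    ))
  }
  phenotype |>
    inner_join(self_report, by = "person_id") |>
    filter(status %in% c("case", "control")) |>
    group_by(status) |>
    summarise(
      n = n(),
      n_self_report = sum(self_report),
      percent = round(100 * sum(self_report) / n()),
      .groups = "drop"
    )
}

symdiff_keys <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Demographics table with age-and-sex-adjusted group differences
#'
#' For each trait column, reports per-group mean (SD) for continuous
#' traits or count (percent of group, rounded to the nearest integer) for
#' binary traits, plus a p-value from a logistic regression of
#' case/control status on the trait adjusted for age and sex. Constant
#' traits get `NA` p-values.
#'
#' @param phenotype Output of [derive_fall_status()] (only `case` and
#'   `control` rows are used).
#' @param covariates Tibble keyed by `person_id` with `age`, `sex` and the
#'   trait columns.
#' @param traits Character vector of trait column names in `covariates`.
#' @return Tidy tibble: `trait`, `cases`, `controls` (formatted cells),
#'   `p`.
#' @export
summarize_cohort <- function(phenotype, covariates,
                             traits = setdiff(names(covariates),
                                              c("person_id", "age", "sex"))) {
  assert_columns(covariates, c("person_id", "age", "sex"), "covariates")
  dat <- phenotype |>
    filter(status %in% c("case", "control")) |>
    inner_join(covariates, by = "person_id") |>
    mutate(y = as.integer(status == "case"))
  cell <- function(x, grp) {
    x <- x[grp]
    if (is.logical(x) || all(x %in% c(0, 1, NA))) {
      sprintf("%d (%d%%)", sum(x, na.rm = TRUE),
              round(100 * mean(x, na.rm = TRUE)))
    } else {
      sprintf("%.3g (%.3g)", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
    }
  }
  one <- function(tr) {
    x <- dat[[tr]]
    if (is.logical(x)) x <- as.integer(x)
    p <- NA_real_
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 1) {
      fit <- glm(y ~ x + age + sex,
                 data = data.frame(y = dat$y, x = x, age = dat$age,
                                   sex = dat$sex),
                 family = binomial())
      p <- summary(fit)$coefficients["x", 4]
    }
    tibble(
      trait = tr,
      cases = cell(x, dat$y == 1L),
      controls = cell(x, dat$y == 0L),
      p = p
    )
  }
  map_dfr_safe(traits, one)
}

map_dfr_safe <- function(x, f) dplyr::bind_rows(lapply(x, f))
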