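#' Read a GWAS summary-statistics table from TSV
#'
#' Required columns: `variant_id`, `chrom`, `pos` (1-based),
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`;
#' optional `info`. Alleles are uppercased. Malformed rows (non-positive
#' SE, EAF outside (0,1), p outside [0,1]) are rejected with their line
#' numbers reported in a warning.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Typed tibble of the valid rows.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) config_error(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("variant_id", "chrom", "pos", "effect_allele",
                "other_allele", "eaf", "beta", "se", "pvalue", "n")
  assert_columns(raw, required, sprintf("summary-stats file %s", path))
  raw <- raw |>
    mutate(
      effect_allele = toupper(effect_allele),
      other_allele = toupper(other_allele)
    )
  bad <- is.na(raw$se) | raw$se <= 0 |
    is.na(raw$eaf) | raw$eaf <= 0 | raw$eaf >= 1 |
    is.na(raw$pvalue) | raw$pvalue < 0 | raw$pvalue > 1 |
    is.na(raw$beta)
  if (any(bad)) {
    warn(sprintf(
      "rejected %d malformed row(s) (file line%s %s)",
      sum(bad), if (sum(bad) > 1) "s" else "",
      paste(head(which(bad) + 1L, 10), collapse = ", ")
    ))
    raw <- raw[!bad, , drop = FALSE]
  }
  if (!"info" %in% names(raw)) raw$info <- NA_real_
  raw
}

#' Write a summary-statistics table as TSV
#'
#' @param sumstats Tibble in the [read_sumstats()] column contract.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  readr::write_tsv(sumstats, path, progress = FALSE)
  invisible(path)
}

#' Read a coded clinical event log from CSV
#'
#' Columns: `person_id`, `source` (HES/GP), `vocabulary`
#' (ICD10/READ2/READ3), `code`, `event_date` (ISO 8601).
#'
#' @param path Path to a CSV file.
#' @return Event-log tibble with `event_date` parsed as `Date`.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) config_error(sprintf("no such file: %s", path))
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          person_id = "c", source = "c", vocabulary = "c",
                          code = "c", event_date = readr::col_date()
                        ))
  assert_columns(ev, c("person_id", "source", "vocabulary", "code",
                       "event_date"), "event log")
  ev
}

#' Write an event log as CSV
#' @param events Event-log tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}
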