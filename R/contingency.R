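# Drug-event 2x2 contingency tables. For a target drug and each event term:
#   a = reports with drug and event, b = drug without event,
#   c = event without drug,         d = neither; N = a+b+c+d = store size.
# The comparator is all other reports in the store (full-database background).

#' Build 2x2 disproportionality tables for one drug
#'
#' One table per event term occurring in at least one drug-exposed report.
#' Exposure is report-level: the report lists the drug under one of the
#' requested role codes. Event occurrence is report-level presence of the
#' reaction PT (or, at SOC level, of at least one PT mapping to the SOC), so
#' a report counts once per event term however many times it repeats.
#'
#' @param store A deduplicated `report_store`.
#' @param drug Ingredient name (as produced by [normalize_drug_name()]).
#' @param roles Drug role codes defining exposure; default `"PS"` (primary
#'   suspect only).
#' @param level `"pt"` (preferred term) or `"soc"` (system organ class).
#' @param map A `meddra_map`; required when `level = "soc"`.
#' @return A tibble with columns `level`, `drug`, `event`, `a`, `b`, `c`,
#'   `d`, `n_total`. Empty (with a warning) if the drug is absent.
#' @export
build_contingency <- function(store, drug, roles = "PS",
                              level = c("pt", "soc"), map = NULL) {
  stopifnot(inherits(store, "report_store"), length(drug) == 1)
  level <- match.arg(level)
  if (!store$deduplicated) {
    warn("Store has not been deduplicated; counts will include case versions")
  }
  if (!all(roles %in% c("PS", "SS", "C", "I")) || length(roles) == 0) {
    abort("roles must be a non-empty subset of PS, SS, C, I",
          class = "faersignal_value_error")
  }
  empty <- tibble(level = character(), drug = character(), event = character(),
                  a = integer(), b = integer(), c = integer(), d = integer(),
                  n_total = integer())
  exposed <- store$drugs |>
    filter(.data$ingredient == drug, .data$role %in% roles) |>
    distinct(.data$primaryid)
  if (nrow(exposed) == 0) {
    warn(paste0("Drug ", drug, " not present in store under roles ",
                paste(roles, collapse = ",")))
    return(empty)
  }
  events <- store$reactions |> distinct(.data$primaryid, event = .data$pt)
  if (level == "soc") {
    if (is.null(map)) abort("A meddra_map is required at SOC level",
                            class = "faersignal_value_error")
    events <- events |>
      mutate(event = pt_to_soc(map, .data$event)$soc_name) |>
      distinct(.data$primaryid, .data$event)
  }
  n_total <- nrow(store$reports)
  n_exposed <- nrow(exposed)
  tot <- events |> count(.data$event, name = "n_event")
  events |>
    semi_join(exposed, by = "primaryid") |>
    count(.data$event, name = "a") |>
    left_join(tot, by = "event") |>
    transmute(level = level, drug = drug, event = .data$event,
              a = .data$a,
              b = n_exposed - .data$a,
              c = .data$n_event - .data$a,
              d = n_total - n_exposed - .data$n_event + .data$a,
              n_total = n_total) |>
    arrange(desc(.data$a), .data$event)
}

#' Contingency tables for every drug in a store
#'
#' The all-pairs counterpart of [build_contingency()]: one table per
#' (drug, event) pair with at least one co-occurrence report, computed in a
#' single pass. Used for database-wide screens such as false-positive
#' controls under a null simulation.
#'
#' @inheritParams build_contingency
#' @return A contingency-table tibble with one row per drug-event pair.
#' @export
build_contingency_all <- function(store, roles = "PS", level = c("pt", "soc"),
                                  map = NULL) {
  stopifnot(inherits(store, "report_store"))
  level <- match.arg(level)
  exposure <- store$drugs |>
    filter(.data$role %in% roles) |>
    distinct(.data$primaryid, .data$ingredient)
  events <- store$reactions |> distinct(.data$primaryid, event = .data$pt)
  if (level == "soc") {
    if (is.null(map)) abort("A meddra_map is required at SOC level",
                            class = "faersignal_value_error")
    events <- events |>
      mutate(event = pt_to_soc(map, .data$event)$soc_name) |>
      distinct(.data$primaryid, .data$event)
  }
  n_total <- nrow(store$reports)
  drug_margin <- count(exposure, .data$ingredient, name = "n_drug")
  event_margin <- count(events, .data$event, name = "n_event")
  inner_join(exposure, events, by = "primaryid",
             relationship = "many-to-many") |>
    count(.data$ingredient, .data$event, name = "a") |>
    left_join(drug_margin, by = "ingredient") |>
    left_join(event_margin, by = "event") |>
    transmute(level = level, drug = .data$ingredient, event = .data$event,
              a = .data$a, b = .data$n_drug - .data$a,
              c = .data$n_event - .data$a,
              d = n_total - .data$n_drug - .data$n_event + .data$a,
              n_total = n_total) |>
    arrange(.data$drug, desc(.data$a), .data$event)
}

#' Contingency tables from bare counts
#'
#' "Counts mode": wraps published or externally computed `(a, b, c, d)`
#' quadruples in the same table shape [build_contingency()] produces, so the
#' estimators can be run directly on printed counts.
#'
#' @param counts A data frame with columns `event`, `a`, `b`, `c`, `d`.
#' @param level `"pt"` or `"soc"` label for the rows.
#' @param drug Optional drug name to record.
#' @return A contingency-table tibble.
#' @examples
#' contingency_from_counts(tirzepatide_pt_counts())
#' @export
contingency_from_counts <- function(counts, level = c("pt", "soc"),
                                    drug = NA_character_) {
  level <- match.arg(level)
  miss <- setdiff(c("event", "a", "b", "c", "d"), names(counts))
  if (length(miss) > 0) {
    abort(paste0("Counts table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "faersignal_format_error")
  }
  cells <- c(counts$a, counts$b, counts$c, counts$d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != trunc(cells))) {
    abort("Cells a, b, c, d must be nonnegative integers",
          class = "faersignal_value_error")
  }
  counts |>
    transmute(level = level, drug = drug, event = as.character(.data$event),
              a = as.integer(.data$a), b = as.integer(.data$b),
              c = as.integer(.data$c), d = as.integer(.data$d),
              n_total = as.integer(.data$a + .data$b + .data$c + .data$d))
}

#' Minimum case-count filter
#'
#' Keeps tables with at least `n_min` co-occurrence reports (`a >= n_min`,
#' inclusive — the usual "N >= 3" screen).
#'
#' @param tables A contingency-table tibble.
#' @param n_min Nonnegative integer; `0` is the identity.
#' @return The filtered tibble.
#' @export
min_case_filter <- function(tables, n_min = 3) {
  if (length(n_min) != 1 || is.na(n_min) || n_min < 0) {
    abort("n_min must be a single nonnegative integer",
          class = "faersignal_value_error")
  }
  filter(tables, .data$a >= n_min)
}

#' Write contingency tables as TSV
#'
#' @param tables A contingency-table tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contingency_tsv <- function(tables, path) {
  readr::write_tsv(select(tables, "level", "event", "a", "b", "c", "d",
                          "n_total"),
                   path, progress = FALSE)
  invisible(path)
}
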