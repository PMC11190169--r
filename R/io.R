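# Ingestion of FAERS-dialect quarterly extracts: "$"-delimited ASCII tables
# DEMO / DRUG / REAC / OUTC / INDI, one header line, empty string = missing.

#' Parse a dollar-delimited FAERS-dialect table
#'
#' Reads one `$`-delimited ASCII file with a single header line into a tibble
#' of character columns. Empty fields become `NA`. Column order follows the
#' file header.
#'
#' @param path Path to the file.
#' @param expected_columns Optional character vector of columns that must be
#'   present; a missing one raises a format error naming it.
#' @return A tibble with one row per data line, all columns character.
#' @examples
#' f <- tempfile()
#' writeLines(c("primaryid$caseid$sex", "100$1$F"), f)
#' parse_dollar_table(f)
#' @export
parse_dollar_table <- function(path, expected_columns = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File does not exist: ", path),
          class = "faersignal_format_error")
  }
  x <- withCallingHandlers(
    readr::read_delim(path, delim = "$", quote = "",
                      col_types = readr::cols(.default = readr::col_character()),
                      na = "", trim_ws = TRUE, progress = FALSE),
    warning = function(w) invokeRestart("muffleWarning")
  )
  probs <- readr::problems(x)
  ragged <- probs[grepl("columns", probs$expected), , drop = FALSE]
  if (nrow(ragged) > 0) {
    abort(paste0("Ragged line ", ragged$row[1], " in ", path, ": expected ",
                 ragged$expected[1], ", got ", ragged$actual[1]),
          class = "faersignal_format_error")
  }
  if (!is.null(expected_columns)) {
    miss <- setdiff(expected_columns, names(x))
    if (length(miss) > 0) {
      abort(paste0("Missing mandatory column(s) in ", path, ": ",
                   paste(miss, collapse = ", ")),
            class = "faersignal_format_error")
    }
  }
  x
}

# Mandatory columns of each FAERS-dialect table.
faers_columns <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "sex", "age",
           "age_cod", "occr_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

#' Read all quarterly FAERS-dialect files under a directory
#'
#' Expects one subdirectory per quarter (named `"YYYYQn"`), each containing
#' the five tables as `demo.txt`, `drug.txt`, `reac.txt`, `outc.txt`,
#' `indi.txt` (case-insensitive prefixes). Rows from all quarters are stacked.
#'
#' @param dir Directory holding the quarter subdirectories.
#' @return A named list of tibbles: `demo`, `drug`, `reac`, `outc`, `indi`.
#' @seealso [assemble_reports()] to turn the tables into a report store,
#'   [write_faers_quarters()] which writes this layout.
#' @export
read_faers_quarters <- function(dir) {
  qdirs <- list.dirs(dir, recursive = FALSE)
  qdirs <- qdirs[grepl(quarter_rx, basename(qdirs))]
  if (length(qdirs) == 0) {
    abort(paste0("No quarter subdirectories (YYYYQn) found under ", dir),
          class = "faersignal_format_error")
  }
  read_one <- function(qdir, tab) {
    files <- list.files(qdir, full.names = TRUE)
    hit <- files[grepl(paste0("^", tab), basename(files), ignore.case = TRUE)]
    if (length(hit) == 0) {
      abort(paste0("Quarter directory ", qdir, " has no ", toupper(tab), " file"),
            class = "faersignal_format_error")
    }
    parse_dollar_table(hit[1], expected_columns = faers_columns[[tab]])
  }
  lapply(setNames(nm = names(faers_columns)), function(tab) {
    list_rbind(map(qdirs, read_one, tab = tab))
  })
}

#' Normalize a verbatim drug name to an ingredient
#'
#' Lowercases, strips punctuation, collapses whitespace, then applies the
#' synonym dictionary (verbatim variant to canonical ingredient, the
#' functional stand-in for a drug-vocabulary service). Names not in the
#' dictionary pass through in normalized form.
#'
#' @param verbatim Character vector of verbatim drug names.
#' @param synonyms Named character vector (lowercase variant -> ingredient),
#'   e.g. from [read_drug_synonyms()].
#' @return Character vector of ingredient names.
#' @examples
#' normalize_drug_name("MOUNJARO")
#' @export
normalize_drug_name <- function(verbatim, synonyms = read_drug_synonyms()) {
  x <- tolower(trimws(verbatim))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- stringr::str_squish(x)
  if (any(is.na(x) | x == "")) {
    abort("Empty drug name cannot be normalized",
          class = "faersignal_value_error")
  }
  hit <- synonyms[x]
  unname(dplyr::coalesce(hit, x))
}

new_report_store <- function(reports, drugs, reactions, outcomes, indications,
                             window = NULL, deduplicated = FALSE,
                             n_raw = nrow(reports)) {
  structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         outcomes = outcomes, indications = indications,
         window = window, deduplicated = deduplicated, n_raw = n_raw),
    class = "report_store"
  )
}

#' Number of reports in a store
#'
#' @param store A `report_store`.
#' @param raw If `TRUE`, the count of reports read at assembly time (before
#'   any deduplication or window filter); otherwise the current count. Both
#'   are exposed because spontaneous-report denominators are quoted under
#'   either convention.
#' @return Integer count.
#' @export
n_reports <- function(store, raw = FALSE) {
  stopifnot(inherits(store, "report_store"))
  if (raw) store$n_raw else nrow(store$reports)
}

#' @export
print.report_store <- function(x, ...) {
  win <- if (is.null(x$window)) "none" else paste(x$window, collapse = " to ")
  cat("<report_store>\n",
      "  reports:      ", nrow(x$reports),
      if (x$n_raw != nrow(x$reports)) paste0(" (", x$n_raw, " at assembly)") else "",
      "\n",
      "  distinct cases: ", dplyr::n_distinct(x$reports$caseid), "\n",
      "  deduplicated: ", x$deduplicated, "\n",
      "  window:       ", win, "\n", sep = "")
  invisible(x)
}

#' Assemble FAERS-dialect tables into a report store
#'
#' Joins the five quarterly tables on `primaryid` into a normalized store:
#' one row per report plus child tables for drugs, reactions, outcomes and
#' indications. Within a report, repeated reaction PTs collapse to one;
#' reports with no reaction rows are retained. Child rows whose `primaryid`
#' is absent from the DEMO table are dropped with a message (the count is
#' kept in the `orphans` attribute).
#'
#' @param demo,drug,reac,outc,indi Tibbles as returned by
#'   [parse_dollar_table()] / [read_faers_quarters()].
#' @param synonyms Drug-name synonym dictionary for [normalize_drug_name()].
#' @return A `report_store` (not yet deduplicated).
#' @export
assemble_reports <- function(demo, drug, reac, outc, indi,
                             synonyms = read_drug_synonyms()) {
  for (tab in names(faers_columns)) {
    x <- get(tab)
    miss <- setdiff(faers_columns[[tab]], names(x))
    if (length(miss) > 0) {
      abort(paste0(toupper(tab), " table is missing column(s): ",
                   paste(miss, collapse = ", ")),
            class = "faersignal_format_error")
    }
  }
  receipt <- as.Date(demo$fda_dt, format = "%Y%m%d")
  reports <- tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    case_version = dplyr::coalesce(suppressWarnings(as.integer(demo$caseversion)), 0L),
    receipt_date = receipt,
    quarter = quarter_label(receipt),
    sex = ifelse(demo$sex %in% c("M", "F"), demo$sex, "UNK"),
    age_years = age_in_years(demo$age, demo$age_cod),
    country = dplyr::coalesce(toupper(demo$occr_country), "UNK")
  ) |>
    mutate(continent = continent_of(.data$country))
  if (anyDuplicated(reports$primaryid) > 0) {
    abort("Duplicated primaryid in DEMO table",
          class = "faersignal_format_error")
  }

  orphans <- c(drug = 0L, reac = 0L, outc = 0L, indi = 0L)
  keep <- function(x, label) {
    orphan <- !(x$primaryid %in% reports$primaryid)
    if (any(orphan)) {
      inform(paste0("Dropping ", sum(orphan), " orphan ", label,
                    " row(s) with no matching DEMO report"))
    }
    orphans[tolower(label)] <<- sum(orphan)
    x[!orphan, , drop = FALSE]
  }

  role_ok <- drug$role_cod %in% c("PS", "SS", "C", "I")
  if (!all(role_ok)) {
    abort(paste0("Invalid drug role code(s): ",
                 paste(unique(drug$role_cod[!role_ok]), collapse = ", ")),
          class = "faersignal_format_error")
  }
  drug_kept <- keep(drug, "DRUG")
  drugs <- drug_kept |>
    transmute(primaryid = .data$primaryid, drug_seq = .data$drug_seq,
              verbatim_name = .data$drugname,
              ingredient = if (nrow(drug_kept) > 0)
                normalize_drug_name(.data$drugname, synonyms) else character(),
              role = .data$role_cod)
  reac_kept <- keep(reac, "REAC")
  reactions <- reac_kept |>
    transmute(primaryid = .data$primaryid, pt = trimws(.data$pt)) |>
    distinct()
  outc_ok <- outc$outc_cod %in% c("DE", "LT", "DS", "HO", "CA", "RI", "OT")
  if (!all(outc_ok)) {
    abort(paste0("Invalid outcome code(s): ",
                 paste(unique(outc$outc_cod[!outc_ok]), collapse = ", ")),
          class = "faersignal_format_error")
  }
  outc_kept <- keep(outc, "OUTC")
  outcomes <- outc_kept |>
    transmute(primaryid = .data$primaryid, outcome = .data$outc_cod) |>
    distinct()
  indi_kept <- keep(indi, "INDI")
  indications <- indi_kept |>
    transmute(primaryid = .data$primaryid, drug_seq = .data$indi_drug_seq,
              pt = trimws(.data$indi_pt)) |>
    distinct()

  store <- new_report_store(reports, drugs, reactions, outcomes, indications)
  attr(store, "orphans") <- orphans
  store
}

age_in_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  f <- dplyr::case_match(toupper(dplyr::coalesce(age_cod, "YR")),
                         "YR" ~ 1, "DEC" ~ 10, "MON" ~ 1 / 12,
                         "WK" ~ 7 / 365.25, "DY" ~ 1 / 365.25,
                         "HR" ~ 1 / (24 * 365.25), .default = 1)
  v * f
}

#' Deduplicate case versions
#'
#' FAERS cases are resubmitted as new versions under the same `caseid`. Keeps
#' one report per case: the greatest `(receipt_date, case_version,
#' primaryid)` in lexicographic order — the FDA-recommended "latest version
#' wins" rule. Output is sorted by `caseid`; child tables are filtered to the
#' surviving reports. Idempotent.
#'
#' @param store A `report_store`.
#' @return The deduplicated `report_store`.
#' @export
deduplicate_reports <- function(store) {
  stopifnot(inherits(store, "report_store"))
  rp <- store$reports
  ord <- order(rp$caseid, rp$receipt_date, rp$case_version, rp$primaryid)
  rp <- rp[ord, , drop = FALSE]
  survivors <- rp[!duplicated(rp$caseid, fromLast = TRUE), , drop = FALSE]
  keep <- function(x) filter(x, .data$primaryid %in% survivors$primaryid)
  new_report_store(survivors, keep(store$drugs), keep(store$reactions),
                   keep(store$outcomes), keep(store$indications),
                   window = store$window, deduplicated = TRUE,
                   n_raw = store$n_raw)
}

#' Restrict a store to a reporting window
#'
#' Keeps reports whose quarter lies in `[start, end]` (inclusive).
#'
#' @param store A `report_store`.
#' @param start,end Quarter labels `"YYYYQn"`.
#' @return The filtered `report_store`, with the window recorded.
#' @export
filter_window <- function(store, start, end) {
  stopifnot(inherits(store, "report_store"))
  lo <- quarter_index(start)
  hi <- quarter_index(end)
  if (lo > hi) abort("start quarter is after end quarter",
                     class = "faersignal_quarter_error")
  qi <- quarter_index(store$reports$quarter)
  survivors <- store$reports[!is.na(qi) & qi >= lo & qi <= hi, , drop = FALSE]
  keep <- function(x) filter(x, .data$primaryid %in% survivors$primaryid)
  new_report_store(survivors, keep(store$drugs), keep(store$reactions),
                   keep(store$outcomes), keep(store$indications),
                   window = c(start, end), deduplicated = store$deduplicated,
                   n_raw = store$n_raw)
}

#' Write / read a report store as a directory of TSV tables
#'
#' The store round-trips losslessly through five TSV files plus a small
#' metadata file.
#'
#' @param store A `report_store`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_report_store()` returns `dir` invisibly;
#'   `read_report_store()` returns the `report_store`.
#' @export
write_report_store <- function(store, dir) {
  stopifnot(inherits(store, "report_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in c("reports", "drugs", "reactions", "outcomes", "indications")) {
    readr::write_tsv(store[[tab]], file.path(dir, paste0(tab, ".tsv")),
                     progress = FALSE)
  }
  meta <- tibble(window_start = (store$window %||% c(NA, NA))[1],
                 window_end = (store$window %||% c(NA, NA))[2],
                 deduplicated = store$deduplicated, n_raw = store$n_raw)
  readr::write_tsv(meta, file.path(dir, "meta.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_report_store
#' @export
read_report_store <- function(dir) {
  rd <- function(name, types) {
    readr::read_tsv(file.path(dir, paste0(name, ".tsv")), col_types = types,
                    progress = FALSE)
  }
  reports <- rd("reports", readr::cols(
    primaryid = "c", caseid = "c", case_version = "i", receipt_date = "D",
    quarter = "c", sex = "c", age_years = "d", country = "c", continent = "c"))
  chr <- readr::cols(.default = "c")
  meta <- rd("meta", readr::cols(window_start = "c", window_end = "c",
                                 deduplicated = "l", n_raw = "i"))
  window <- if (is.na(meta$window_start)) NULL else
    c(meta$window_start, meta$window_end)
  new_report_store(reports, rd("drugs", chr), rd("reactions", chr),
                   rd("outcomes", chr), rd("indications", chr),
                   window = window, deduplicated = meta$deduplicated,
                   n_raw = meta$n_raw)
}

#' @method tidy report_store
#' @export
tidy.report_store <- function(x, ...) as_tibble(x$reports)

#' @method glance report_store
#' @export
glance.report_store <- function(x, ...) {
  tibble(n_reports = nrow(x$reports), n_raw = x$n_raw,
         n_cases = dplyr::n_distinct(x$reports$caseid),
         deduplicated = x$deduplicated,
         window_start = (x$window %||% c(NA, NA))[1],
         window_end = (x$window %||% c(NA, NA))[2])
}
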