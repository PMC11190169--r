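# PT -> primary SOC mapping. MedDRA itself is licensed, so the user supplies
# the mapping as a TSV; a small synthetic fixture covering the bundled
# tirzepatide tables ships with the package.

#' Read a PT-to-SOC mapping table
#'
#' Loads and validates a MedDRA-style mapping: every preferred term must have
#' exactly one primary system-organ-class assignment. Secondary SOC links may
#' be present (`primary_soc` false) but are not used in aggregation. PT
#' lookup is case-insensitive.
#'
#' @param path TSV with columns `pt_code`, `pt_name`, `soc_code`, `soc_name`,
#'   `primary_soc`.
#' @return A tibble of class `meddra_map`.
#' @seealso [example_meddra_map()], [pt_to_soc()]
#' @export
read_meddra_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  miss <- setdiff(c("pt_code", "pt_name", "soc_code", "soc_name", "primary_soc"),
                  names(x))
  if (length(miss) > 0) {
    abort(paste0("MedDRA map is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "faersignal_format_error")
  }
  x <- mutate(x, pt_code = as.integer(.data$pt_code),
              soc_code = as.integer(.data$soc_code),
              primary_soc = as.logical(.data$primary_soc))
  new_meddra_map(x)
}

new_meddra_map <- function(x) {
  n_primary <- x |>
    group_by(pt_key = tolower(.data$pt_name)) |>
    summarise(n = sum(.data$primary_soc), .groups = "drop")
  bad <- filter(n_primary, .data$n != 1L)
  if (nrow(bad) > 0) {
    abort(paste0("PT(s) without exactly one primary SOC: ",
                 paste(bad$pt_key, collapse = ", ")),
          class = "faersignal_meddra_error")
  }
  structure(as_tibble(x), class = c("meddra_map", class(as_tibble(x))))
}

#' Synthetic example PT-to-SOC map
#'
#' The small mapping fixture bundled with the package: the preferred terms of
#' the tirzepatide reference tables assigned to their published SOCs, plus a
#' few extra terms. SOC codes are the published ones; PT codes are synthetic
#' placeholders (9xxxxxxx) because real MedDRA codes are licensed.
#'
#' @return A `meddra_map`.
#' @export
example_meddra_map <- function() {
  read_meddra_map(system.file("extdata", "meddra_map_synthetic.tsv",
                              package = "faersignal", mustWork = TRUE))
}

#' Map preferred terms to their primary system organ class
#'
#' Total and deterministic: a PT absent from the map is assigned the
#' designated `"UNMAPPED"` SOC (with a warning) rather than erroring, so
#' aggregation never silently drops events.
#'
#' @param map A `meddra_map`.
#' @param pt_name Character vector of PT names (matched case-insensitively).
#' @return A tibble with columns `pt_name`, `soc_code`, `soc_name`.
#' @export
pt_to_soc <- function(map, pt_name) {
  stopifnot(inherits(map, "meddra_map"))
  primary <- filter(map, .data$primary_soc)
  idx <- match(tolower(pt_name), tolower(primary$pt_name))
  unmapped <- is.na(idx) & !is.na(pt_name)
  if (any(unmapped)) {
    warn(paste0(sum(unmapped), " PT(s) not in the map, assigned to UNMAPPED (e.g. ",
                paste(head(unique(pt_name[unmapped]), 3), collapse = ", "), ")"))
  }
  tibble(pt_name = pt_name,
         soc_code = ifelse(unmapped, NA_integer_, primary$soc_code[idx]),
         soc_name = ifelse(unmapped, "UNMAPPED", primary$soc_name[idx]))
}
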