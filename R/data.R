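# Bundled lookup tables and reference fixtures (all plain TSV under extdata).

#' Country to continent lookup
#'
#' Static ISO-3166 alpha-2 lookup covering the countries that dominate FAERS
#' reporting. Codes not listed map to `"UNK"`.
#'
#' @return A tibble with columns `country` and `continent`.
#' @export
country_continents <- function() {
  tibble(
    country = c("US", "CA", "MX", "PR",
                "BR", "AR", "CO", "CL", "PE",
                "GB", "DE", "FR", "IT", "ES", "NL", "SE", "CH", "PL", "BE",
                "IE", "DK", "NO", "FI", "AT", "PT", "GR",
                "JP", "CN", "KR", "IN", "SA", "AE", "IL", "TR", "TH", "PH",
                "AU", "NZ",
                "ZA", "NG", "EG", "KE"),
    continent = c(rep("North America", 4),
                  rep("South America", 5),
                  rep("Europe", 17),
                  rep("Asia", 10),
                  rep("Oceania", 2),
                  rep("Africa", 4))
  )
}

continent_of <- function(country) {
  lk <- country_continents()
  out <- lk$continent[match(country, lk$country)]
  dplyr::coalesce(out, "UNK")
}

#' Default drug-name synonym dictionary
#'
#' A small editable dictionary mapping brand/verbatim drug names to canonical
#' ingredient names (e.g. `mounjaro` and `zepbound` to `tirzepatide`). It
#' stands in for a full vocabulary service: unknown names simply pass through
#' [normalize_drug_name()] unchanged.
#'
#' @param path Optional path to a two-column TSV (`verbatim`, `ingredient`);
#'   defaults to the dictionary bundled with the package.
#' @return A named character vector: names are lowercase verbatim variants,
#'   values the canonical ingredient.
#' @export
read_drug_synonyms <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_synonyms.tsv",
                                package = "faersignal", mustWork = TRUE)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("verbatim", "ingredient")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("Synonym table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "faersignal_format_error")
  }
  setNames(tolower(x$ingredient), tolower(x$verbatim))
}

#' Published tirzepatide signal tables (reference fixtures)
#'
#' The 2x2 counts and printed disproportionality statistics for tirzepatide
#' (primary-suspect reports, FAERS 2022Q2--2023Q3 window, database denominator
#' 1,904,481) from a published pharmacovigilance analysis:
#' `tirzepatide_pt_counts()` returns the 46 preferred-term rows and
#' `tirzepatide_soc_counts()` the 8 system-organ-class rows. Counts columns
#' `a`, `b`, `c`, `d` are integers; the printed statistics (`ror`, `ror_low`,
#' `ror_high`, `prr`, `chi2`, `p_value`, `ic`, `ic025`, `ebgm`, `ebgm05`) are
#' kept as character strings so the number of printed decimals is preserved.
#'
#' These tables drive the counts-mode pipeline ([contingency_from_counts()])
#' and serve as reference values for the estimator implementations. Note that
#' several PT rows print a PRR that is not consistent with the PRR formula
#' given their own counts, and the printed IC025 values do not correspond to
#' the standard BCPNN closed-form credibility bound; see the package vignette.
#'
#' @return A tibble, one row per event term.
#' @export
tirzepatide_pt_counts <- function() {
  read_signal_fixture("tirzepatide_pt_signals.tsv", key = "pt")
}

#' @rdname tirzepatide_pt_counts
#' @export
tirzepatide_soc_counts <- function() {
  read_signal_fixture("tirzepatide_soc_signals.tsv", key = "soc")
}

read_signal_fixture <- function(file, key) {
  path <- system.file("extdata", file, package = "faersignal", mustWork = TRUE)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  mutate(x, across(c("a", "b", "c", "d"), as.integer),
         event = .data[[key]], .before = 1)
}
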