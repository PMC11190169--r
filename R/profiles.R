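# Clinical-characteristics profile of one drug's report set: counts and
# percentages by sex, age bin, continent, top-k countries, top-k indications,
# serious outcomes and reporting quarter. Percentages always use the number
# of drug reports as denominator, so multi-valued blocks (outcomes,
# indications) need not sum to 100%.

age_bin_levels <- c("<18", "18-29", "30-39", "40-49", "50-59", "60-69",
                    "70-79", "80-89", ">=90", "Unknown")

#' Bin an age in years
#'
#' Decade bins, lower edge inclusive: `<18`, `18-29`, ..., `80-89`, `>=90`;
#' missing ages map to `"Unknown"`.
#'
#' @param age_years Numeric vector of ages (missing allowed, negative is an
#'   error).
#' @return Factor with the full bin level set.
#' @examples
#' age_bin(c(55, 17.9, NA))
#' @export
age_bin <- function(age_years) {
  age_years <- as.numeric(age_years)
  if (any(!is.na(age_years) & age_years < 0)) {
    abort("Negative age", class = "faersignal_value_error")
  }
  cut_lab <- as.character(cut(age_years,
                              breaks = c(-Inf, 18, 30, 40, 50, 60, 70, 80, 90, Inf),
                              labels = age_bin_levels[1:9], right = FALSE))
  factor(dplyr::coalesce(cut_lab, "Unknown"), levels = age_bin_levels)
}

outcome_codes <- c("DE", "LT", "DS", "HO", "CA", "RI", "OT")

#' Profile the reports of one drug
#'
#' Report-level scan over the reports exposed to `drug` under the given
#' roles. Each block's percentages are computed against the number of drug
#' reports. A report with several serious-outcome codes counts once per code
#' (FAERS OUTC semantics), and indications are the target drug's own entries
#' only.
#'
#' @param store A deduplicated `report_store`.
#' @param drug Ingredient name.
#' @param roles Drug role codes defining exposure; default `"PS"`.
#' @param k_countries,k_indications How many top countries / indication PTs
#'   to keep.
#' @return A `faers_profile` tibble with columns `block`, `category`, `n`,
#'   `pct`, carrying the denominator as attribute `n_reports`.
#' @export
profile_reports <- function(store, drug, roles = "PS", k_countries = 5,
                            k_indications = 10) {
  stopifnot(inherits(store, "report_store"), length(drug) == 1)
  drug_rows <- store$drugs |>
    filter(.data$ingredient == drug, .data$role %in% roles)
  ids <- unique(drug_rows$primaryid)
  empty <- structure(tibble(block = character(), category = character(),
                            n = integer(), pct = numeric()),
                     class = c("faers_profile", class(tibble())),
                     drug = drug, n_reports = 0L)
  if (length(ids) == 0) {
    warn(paste0("Drug ", drug, " not present in store under roles ",
                paste(roles, collapse = ",")))
    return(empty)
  }
  rp <- filter(store$reports, .data$primaryid %in% ids)
  denom <- nrow(rp)

  block <- function(name, tab) {
    tibble(block = name, category = names(tab), n = as.integer(tab),
           pct = 100 * as.integer(tab) / denom)
  }
  top_block <- function(name, x, k) {
    tab <- sort(table(x), decreasing = TRUE)
    # ties broken by name for a deterministic ordering
    ord <- order(-as.integer(tab), names(tab))
    tab <- tab[ord]
    block(name, head(tab, k))
  }

  sex <- block("sex", table(factor(rp$sex, levels = c("M", "F", "UNK"))))
  age <- block("age", table(age_bin(rp$age_years)))
  continent <- top_block("continent", rp$continent, k = Inf)
  country <- top_block("country", rp$country, k = k_countries)
  indi <- store$indications |>
    semi_join(drug_rows, by = c("primaryid", "drug_seq"))
  indication <- top_block("indication", indi$pt, k = k_indications)
  outc <- filter(store$outcomes, .data$primaryid %in% ids)
  outcome <- block("outcome", table(factor(outc$outcome, levels = outcome_codes)))
  quarter <- block("quarter", table(rp$quarter))

  out <- bind_rows(sex, age, continent, country, indication, outcome, quarter)
  structure(out, class = c("faers_profile", class(out)),
            drug = drug, n_reports = denom)
}

#' @export
print.faers_profile <- function(x, ...) {
  cat("Clinical characteristics of reports: ", attr(x, "drug"),
      " (n = ", attr(x, "n_reports"), ")\n", sep = "")
  for (b in unique(x$block)) {
    cat("\n", b, "\n", sep = "")
    rows <- x[x$block == b, , drop = FALSE]
    cat(sprintf("  %-45s %8d  %6.2f%%\n", rows$category, rows$n, rows$pct),
        sep = "")
  }
  invisible(x)
}

#' Write a profile as TSV
#'
#' @param profile A `faers_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path, progress = FALSE)
  invisible(path)
}

#' @method tidy faers_profile
#' @export
tidy.faers_profile <- function(x, ...) {
  class(x) <- setdiff(class(x), "faers_profile")
  as_tibble(x)
}

#' @method glance faers_profile
#' @export
glance.faers_profile <- function(x, ...) {
  tibble(drug = attr(x, "drug"), n_reports = attr(x, "n_reports"),
         n_blocks = dplyr::n_distinct(x$block))
}
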