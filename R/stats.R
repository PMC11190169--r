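# The four disproportionality estimators on a 2x2 table (a, b, c, d),
# N = a + b + c + d:
#   ROR  = ad / bc, log-normal 95% CI exp(ln ROR +/- 1.96 * se),
#          se = sqrt(1/a + 1/b + 1/c + 1/d)
#   PRR  = [a / (a+b)] / [c / (c+d)], with the Pearson chi-square
#          (ad - bc)^2 N / [(a+b)(a+c)(b+d)(c+d)], no Yates correction
#   IC   = log2[ a N / ((a+b)(a+c)) ]  (BCPNN information component);
#          IC025 from the closed-form Bayesian approximation (Bate 1998)
#   EBGM = a N / ((a+b)(a+c)) = 2^IC; EBGM05 = exp(ln EBGM - 1.96 * se)
# All arithmetic is in double precision: FAERS-scale cells overflow 32-bit
# integers in the cross products.

check_cells <- function(..., positive = TRUE) {
  cells <- list(...)
  lens <- lengths(cells)
  if (length(unique(lens[lens != 1])) > 1) {
    abort("Cell vectors must have equal length", class = "faersignal_value_error")
  }
  cells <- lapply(cells, as.numeric)
  bad <- Reduce(`|`, lapply(cells, function(x) is.na(x) | x < 0))
  if (any(bad)) abort("Cells must be nonnegative and non-missing",
                      class = "faersignal_value_error")
  if (positive && any(Reduce(`|`, lapply(cells, function(x) x == 0)))) {
    abort(paste0("Statistic undefined with a zero cell; apply the ",
                 "continuity correction upstream (see signal_stats)"),
          class = "faersignal_zero_cell_error")
  }
  cells
}

log_se <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/bc`; bounds `exp(ln ROR -/+ 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' All cells must be positive (apply [signal_stats()]'s zero-cell correction
#' first for rare events).
#'
#' @param a,b,c,d Cell counts (vectorized).
#' @return A tibble with columns `ror`, `ror_low`, `ror_high`.
#' @examples
#' ror_ci(5752, 14291, 18587, 1865851)
#' @export
ror_ci <- function(a, b, c, d) {
  cl <- check_cells(a = a, b = b, c = c, d = d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  ror <- (a * d) / (b * c)
  half <- 1.96 * log_se(a, b, c, d)
  tibble(ror = ror, ror_low = exp(log(ror) - half),
         ror_high = exp(log(ror) + half))
}

#' Proportional reporting ratio with Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square statistic is the Pearson
#' test of independence on the 2x2 table without Yates continuity
#' correction, with its upper-tail p-value at one degree of freedom
#' (p below 1e-300 is clamped to 0 for display).
#'
#' @inheritParams ror_ci
#' @return A tibble with columns `prr`, `chi2`, `p_value`.
#' @export
prr_chi2 <- function(a, b, c, d) {
  cl <- check_cells(a = a, b = b, c = c, d = d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  n <- a + b + c + d
  prr <- (a * (c + d)) / (c * (a + b))
  chi2 <- (a * d - b * c)^2 * n / ((a + b) * (a + c) * (b + d) * (c + d))
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble(prr = prr, chi2 = chi2, p_value = ifelse(p < 1e-300, 0, p))
}

#' BCPNN information component with lower credibility bound
#'
#' The point estimate is the observed-to-expected log-ratio
#' `IC = log2[a N / ((a+b)(a+c))]` (identically `log2(EBGM)`). The lower
#' bound `IC025 = E(IC) - 2 sqrt(V(IC))` uses the closed-form Bayesian
#' approximation of the BCPNN with the standard priors
#' (gamma11 = alpha1 = beta1 = 1, alpha = beta = 2).
#'
#' @inheritParams ror_ci
#' @return A tibble with columns `ic`, `ic_low`.
#' @export
bcpnn_ic <- function(a, b, c, d) {
  cl <- check_cells(a = a, b = b, c = c, d = d, positive = FALSE)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  if (any(a == 0)) abort("IC undefined for a = 0; correct zero cells upstream",
                         class = "faersignal_zero_cell_error")
  n <- a + b + c + d
  ic <- log2(a * n / ((a + b) * (a + c)))
  # Bate et al. (1998) closed form; priors gamma11 = alpha1 = beta1 = 1,
  # alpha = beta = 2.
  g11 <- 1; a1 <- 1; b1 <- 1; al <- 2; be <- 2
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (n + al) * (n + be) /
                 ((n + gam) * (a + b + a1) * (a + c + b1)))
  v_ic <- ((n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
             (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
             (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be))) / log(2)^2
  tibble(ic = ic, ic_low = e_ic - 2 * sqrt(v_ic))
}

#' Empirical Bayes geometric mean with lower 95% bound
#'
#' The closed-form relative reporting ratio `EBGM = a N / ((a+b)(a+c))` with
#' `EBGM05 = exp(ln EBGM - 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. (This is the
#' simple closed form, not the full gamma-Poisson shrinkage of MGPS.)
#'
#' @inheritParams ror_ci
#' @return A tibble with columns `ebgm`, `ebgm_low`.
#' @export
ebgm_ci <- function(a, b, c, d) {
  cl <- check_cells(a = a, b = b, c = c, d = d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  n <- a + b + c + d
  ebgm <- a * n / ((a + b) * (a + c))
  tibble(ebgm = ebgm,
         ebgm_low = exp(log(ebgm) - 1.96 * log_se(a, b, c, d)))
}

#' Compute all four disproportionality statistics
#'
#' Adds the ROR, PRR + chi-square, IC and EBGM columns (with their bounds) to
#' a contingency-table tibble. Tables with a zero cell receive the
#' Haldane-Anscombe continuity correction (+0.5 to every cell) before the
#' statistics are computed and are flagged `corrected`; tables with all cells
#' positive are computed on the raw counts. The count columns `a, b, c, d`
#' always remain the raw counts.
#'
#' @param tables A contingency-table tibble (see [build_contingency()] or
#'   [contingency_from_counts()]).
#' @param zero_correction Apply the +0.5 correction to zero-cell tables
#'   (default). If `FALSE`, a zero cell raises an error.
#' @return The input tibble with columns `ror`, `ror_low`, `ror_high`, `prr`,
#'   `chi2`, `p_value`, `ic`, `ic_low`, `ebgm`, `ebgm_low`, `corrected`.
#' @export
signal_stats <- function(tables, zero_correction = TRUE) {
  if (nrow(tables) == 0) {
    return(mutate(tables, ror = numeric(), ror_low = numeric(),
                  ror_high = numeric(), prr = numeric(), chi2 = numeric(),
                  p_value = numeric(), ic = numeric(), ic_low = numeric(),
                  ebgm = numeric(), ebgm_low = numeric(), corrected = logical()))
  }
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c <- as.numeric(tables$c); d <- as.numeric(tables$d)
  corrected <- (a == 0 | b == 0 | c == 0 | d == 0)
  if (any(corrected) && !zero_correction) {
    abort("Zero cell(s) present and zero_correction = FALSE",
          class = "faersignal_zero_cell_error")
  }
  shift <- ifelse(corrected, 0.5, 0)
  a <- a + shift; b <- b + shift; c <- c + shift; d <- d + shift
  bind_cols(tables,
            ror_ci(a, b, c, d),
            prr_chi2(a, b, c, d),
            bcpnn_ic(a, b, c, d),
            ebgm_ci(a, b, c, d),
            tibble(corrected = corrected))
}

#' Apply the positive-signal criteria
#'
#' The four standard criteria, with the inequalities exactly as
#' conventionally stated:
#' * ROR: lower 95% bound > 1 and a >= 3;
#' * PRR: PRR >= 2, chi-square >= 4, a >= 3 and p < 0.05;
#' * BCPNN: IC025 > 0;
#' * EBGM: EBGM05 > 2.
#' `all_four` is their conjunction — the stringent rule requiring agreement
#' of all four algorithms. The case-count screen uses the raw `a`.
#'
#' @param stats A tibble from [signal_stats()].
#' @return The tibble with logical columns `ror_positive`, `prr_positive`,
#'   `bcpnn_positive`, `ebgm_positive`, `all_four`.
#' @export
evaluate_criteria <- function(stats) {
  mutate(stats,
         ror_positive = .data$ror_low > 1 & .data$a >= 3,
         prr_positive = .data$prr >= 2 & .data$chi2 >= 4 & .data$a >= 3 &
           .data$p_value < 0.05,
         bcpnn_positive = .data$ic_low > 0,
         ebgm_positive = .data$ebgm_low > 2,
         all_four = .data$ror_positive & .data$prr_positive &
           .data$bcpnn_positive & .data$ebgm_positive)
}

#' Detect and rank positive signals
#'
#' Computes all statistics and criteria for every table, keeps the rows
#' positive under `rule`, and ranks by `ebgm_low` (EBGM05) descending, ties
#' broken by `a` descending then event name.
#'
#' @param tables A contingency-table tibble (one store, one level).
#' @param rule `"all_four"` (conjunction of the four criteria), `"any"`
#'   (at least one), or a character subset of
#'   `c("ror", "prr", "bcpnn", "ebgm")` whose named criteria must all hold.
#' @param zero_correction Passed to [signal_stats()].
#' @return A `faers_signals` tibble of the retained rows with all statistics
#'   and criteria columns.
#' @examples
#' detect_signals(contingency_from_counts(tirzepatide_soc_counts(), "soc"))
#' @export
detect_signals <- function(tables, rule = "all_four", zero_correction = TRUE) {
  stats <- evaluate_criteria(signal_stats(tables, zero_correction))
  keep <- signal_rule_mask(stats, rule)
  out <- stats[keep, , drop = FALSE] |>
    arrange(desc(.data$ebgm_low), desc(.data$a), .data$event)
  structure(out, class = c("faers_signals", class(out)),
            rule = rule, n_tables = nrow(tables))
}

signal_rule_mask <- function(stats, rule) {
  if (identical(rule, "all_four")) return(stats$all_four)
  flags <- c(ror = "ror_positive", prr = "prr_positive",
             bcpnn = "bcpnn_positive", ebgm = "ebgm_positive")
  if (identical(rule, "any")) {
    return(Reduce(`|`, lapply(flags, function(f) stats[[f]])))
  }
  if (!all(rule %in% names(flags)) || length(rule) == 0) {
    abort("rule must be \"all_four\", \"any\", or a subset of ror/prr/bcpnn/ebgm",
          class = "faersignal_value_error")
  }
  Reduce(`&`, lapply(flags[rule], function(f) stats[[f]]))
}

#' Write a signal table as TSV
#'
#' @param signals A `faers_signals` tibble (or any [signal_stats()] output).
#' @param path Output file.
#' @param digits Decimal places for the statistic columns (counts are never
#'   rounded); default 2.
#' @return `path`, invisibly.
#' @export
write_signals_tsv <- function(signals, path, digits = 2) {
  statcols <- intersect(c("ror", "ror_low", "ror_high", "prr", "chi2", "ic",
                          "ic_low", "ebgm", "ebgm_low"), names(signals))
  out <- as_tibble(signals) |>
    mutate(across(all_of(statcols), ~ round(.x, digits)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @method tidy faers_signals
#' @export
tidy.faers_signals <- function(x, ...) {
  class(x) <- setdiff(class(x), "faers_signals")
  as_tibble(x)
}

#' @method glance faers_signals
#' @export
glance.faers_signals <- function(x, ...) {
  tibble(n_tables = attr(x, "n_tables") %||% NA_integer_,
         n_signals = nrow(x),
         rule = paste(attr(x, "rule") %||% NA_character_, collapse = "+"))
}

#' @export
print.faers_signals <- function(x, ...) {
  cat("<faers_signals> ", nrow(x), " signal(s) of ",
      attr(x, "n_tables") %||% NA, " table(s), rule = ",
      paste(attr(x, "rule"), collapse = "+"), "\n", sep = "")
  NextMethod()
}
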