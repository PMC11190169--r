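# Reference values for the estimator checks were verified against the
# published tirzepatide tables (the formulas reproduce the printed numbers
# at printed precision; see test-acceptance.R for the full-table check).

test_that("estimators reproduce reference values on published counts", {
  # Incorrect dose administered: a very strong signal at PT level
  s <- signal_stats(contingency_from_counts(
    tibble::tibble(event = "ida", a = 5752, b = 14291, c = 18587, d = 1865851)))
  expect_equal(s$ror, 40.4040, tolerance = 1e-5)
  expect_equal(s$ror_low, 39.0594, tolerance = 1e-5)
  expect_equal(s$ror_high, 41.7948, tolerance = 1e-5)
  expect_equal(s$prr, 29.0957, tolerance = 1e-5)
  expect_equal(s$chi2, 120715.2756, tolerance = 1e-8)
  expect_equal(s$p_value, 0)
  expect_equal(s$ic, 4.4890, tolerance = 1e-4)
  expect_equal(s$ebgm, 22.4559, tolerance = 1e-5)
  expect_equal(s$ebgm_low, 21.7086, tolerance = 1e-5)
  expect_false(s$corrected)

  # Gastrooesophageal reflux disease: top of the EBGM05 ranking
  g <- signal_stats(contingency_from_counts(
    tibble::tibble(event = "gerd", a = 207, b = 19836, c = 488, d = 1883950)))
  expect_equal(g$ror, 40.2871, tolerance = 1e-5)
  expect_equal(g$ic, 4.8228, tolerance = 1e-4)
  expect_equal(g$ebgm, 28.3008, tolerance = 1e-5)
  expect_equal(g$ebgm_low, 24.0399, tolerance = 1e-5)

  # Endocrine disorders SOC row
  e <- signal_stats(contingency_from_counts(
    tibble::tibble(event = "endo", a = 69, b = 19974, c = 1518, d = 1882920),
    level = "soc"))
  expect_equal(e$ror, 4.2849, tolerance = 1e-4)
  expect_equal(c(e$ror_low, e$ror_high), c(3.3651, 5.4563), tolerance = 1e-4)
  expect_equal(e$prr, 4.2736, tolerance = 1e-4)
  expect_equal(e$chi2, 165.6409, tolerance = 1e-6)
  expect_equal(e$ebgm, 4.1313, tolerance = 1e-4)
  expect_equal(e$ebgm_low, 3.2444, tolerance = 1e-4)
})

test_that("independence tables give null statistics", {
  s <- signal_stats(contingency_from_counts(
    tibble::tibble(event = "null", a = 10, b = 90, c = 100, d = 900)))
  expect_equal(s$ror, 1)
  expect_equal(s$prr, 1)
  expect_equal(s$chi2, 0)
  expect_equal(s$p_value, 1)
  expect_equal(s$ic, 0)
  expect_equal(s$ebgm, 1)
  expect_true(s$ror_low < 1 && s$ror_high > 1)
})

test_that("zero cells are corrected by +0.5 on all cells, or error when disabled", {
  tb <- contingency_from_counts(
    tibble::tibble(event = "rare", a = 3, b = 0, c = 5, d = 992))
  s <- signal_stats(tb)
  expect_true(s$corrected)
  # hand evaluation of the corrected cross product:
  # (3.5 * 992.5) / (0.5 * 5.5) = 1263.1818...
  expect_equal(s$ror, 3.5 * 992.5 / (0.5 * 5.5), tolerance = 1e-12)
  expect_equal(s$ror, 1263.18, tolerance = 1e-5)
  expect_equal(s[, c("a", "b", "c", "d")], tb[, c("a", "b", "c", "d")]) # raw kept
  expect_error(signal_stats(tb, zero_correction = FALSE),
               class = "faersignal_zero_cell_error")
  expect_error(ror_ci(3, 0, 5, 992), class = "faersignal_zero_cell_error")
  expect_error(bcpnn_ic(0, 10, 10, 100), class = "faersignal_zero_cell_error")
})

test_that("chi-square agrees with the expected-counts oracle on random tables", {
  tabs <- random_tables(1000)
  got <- prr_chi2(tabs$a, tabs$b, tabs$c, tabs$d)$chi2
  want <- mapply(chi2_oracle, tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(abs(got - want) <= 1e-9 * pmax(want, 1)))
})

test_that("IC equals log2(EBGM) identically", {
  tabs <- random_tables(1000, seed = 55)
  ic <- bcpnn_ic(tabs$a, tabs$b, tabs$c, tabs$d)$ic
  ebgm <- ebgm_ci(tabs$a, tabs$b, tabs$c, tabs$d)$ebgm
  expect_true(all(abs(ic - log2(ebgm)) < 1e-9))
})

test_that("IC025 matches an independent evaluation of the closed form and sits below IC", {
  cases <- rbind(c(207, 19836, 488, 1883950),
                 c(5752, 14291, 18587, 1865851),
                 c(10, 90, 100, 900),
                 c(3, 1, 1, 995))
  for (i in seq_len(nrow(cases))) {
    v <- as.numeric(cases[i, ])
    got <- bcpnn_ic(v[1], v[2], v[3], v[4])
    expect_equal(got$ic_low, ic025_oracle(v[1], v[2], v[3], v[4]),
                 tolerance = 1e-12)
    expect_lt(got$ic_low, got$ic)
  }
  tabs <- random_tables(200, seed = 77)
  got <- bcpnn_ic(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(got$ic_low < got$ic))
})

test_that("ROR is symmetric under b/c transposition and PRR is not", {
  expect_equal(ror_ci(30, 70, 40, 860)$ror, ror_ci(30, 40, 70, 860)$ror)
  expect_false(isTRUE(all.equal(prr_chi2(30, 70, 40, 860)$prr,
                                prr_chi2(30, 40, 70, 860)$prr)))
})

test_that("with margins fixed, increasing a increases every point estimate", {
  base <- c(a = 20, b = 80, c = 50, d = 850)
  shift <- function(delta) {
    c(base["a"] + delta, base["b"] - delta, base["c"] - delta, base["d"] + delta)
  }
  prev <- NULL
  for (delta in c(0, 5, 10, 15)) {
    v <- shift(delta)
    cur <- c(ror_ci(v[1], v[2], v[3], v[4])$ror,
             prr_chi2(v[1], v[2], v[3], v[4])$prr,
             bcpnn_ic(v[1], v[2], v[3], v[4])$ic,
             ebgm_ci(v[1], v[2], v[3], v[4])$ebgm)
    if (!is.null(prev)) expect_true(all(cur > prev))
    prev <- cur
  }
})

test_that("the positive-signal criteria apply strict inequalities exactly", {
  row <- function(a = 10, ror_low = 2, prr = 3, chi2 = 10, p_value = 1e-4,
                  ic_low = 0.5, ebgm_low = 3) {
    tibble::tibble(a = a, ror_low = ror_low, prr = prr, chi2 = chi2,
                   p_value = p_value, ic_low = ic_low, ebgm_low = ebgm_low)
  }
  expect_true(evaluate_criteria(row())$all_four)
  expect_false(evaluate_criteria(row(a = 2))$ror_positive)      # N >= 3 fails
  expect_false(evaluate_criteria(row(a = 2))$prr_positive)
  expect_true(evaluate_criteria(row(a = 3))$ror_positive)       # inclusive
  expect_false(evaluate_criteria(row(ror_low = 1))$ror_positive)    # strict >
  expect_true(evaluate_criteria(row(prr = 2))$prr_positive)         # >= 2
  expect_true(evaluate_criteria(row(chi2 = 4))$prr_positive)        # >= 4
  expect_false(evaluate_criteria(row(p_value = 0.05))$prr_positive) # strict <
  expect_false(evaluate_criteria(row(ic_low = 0))$bcpnn_positive)   # strict >
  expect_false(evaluate_criteria(row(ebgm_low = 2))$ebgm_positive)  # strict >
  expect_false(evaluate_criteria(row(ebgm_low = 2))$all_four)
})

test_that("signal detection ranks by EBGM05 then case count then name", {
  tb <- contingency_from_counts(tibble::tibble(
    event = c("weak", "strong", "tie_small", "tie_big"),
    a = c(5, 500, 40, 80),
    b = c(995, 500, 460, 920),
    c = c(100, 100, 200, 178),
    d = c(98900, 98900, 99300, 98822)))
  out <- detect_signals(tb, rule = "any")
  expect_s3_class(out, "faers_signals")
  expect_equal(out$event[1], "strong")
  # rule relaxation is monotone
  expect_gte(nrow(detect_signals(tb, rule = "any")),
             nrow(detect_signals(tb, rule = "all_four")))
  expect_gte(nrow(detect_signals(tb, rule = "ebgm")),
             nrow(detect_signals(tb, rule = c("ebgm", "ror"))))
  # empty input gives an empty, well-formed result
  empty <- detect_signals(tb[0, ], rule = "all_four")
  expect_equal(nrow(empty), 0)
  expect_true(all(c("ror", "ebgm_low", "all_four") %in% names(empty)))
  expect_error(detect_signals(tb, rule = "bogus"),
               class = "faersignal_value_error")
  expect_equal(glance(out)$n_tables, 4)
})

test_that("signal tables write with configurable rounding", {
  tb <- contingency_from_counts(tirzepatide_soc_counts(), "soc")
  out <- detect_signals(tb)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signals_tsv(out, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(out))
  expect_equal(back$ror, round(out$ror, 2))
})
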