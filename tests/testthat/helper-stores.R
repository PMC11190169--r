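# Fixtures built in code: in-memory FAERS-dialect tables and small stores.

library(dplyr)

# Synonym dictionary used by all test stores (keeps tests independent of the
# bundled dictionary file).
test_synonyms <- c(mounjaro = "tirzepatide", zepbound = "tirzepatide")

# Minimal demo row constructor.
demo_row <- function(primaryid, caseid = primaryid, caseversion = "1",
                     fda_dt = "20230215", sex = "F", age = "55",
                     age_cod = "YR", occr_country = "US") {
  tibble::tibble(primaryid = primaryid, caseid = caseid,
                 caseversion = caseversion, fda_dt = fda_dt, sex = sex,
                 age = age, age_cod = age_cod, occr_country = occr_country)
}

empty_drug <- tibble::tibble(primaryid = character(), drug_seq = character(),
                             role_cod = character(), drugname = character())
empty_reac <- tibble::tibble(primaryid = character(), pt = character())
empty_outc <- tibble::tibble(primaryid = character(), outc_cod = character())
empty_indi <- tibble::tibble(primaryid = character(), indi_drug_seq = character(),
                             indi_pt = character())

drug_rows <- function(primaryid, drugname, role = "PS",
                      drug_seq = as.character(seq_along(drugname))) {
  tibble::tibble(primaryid = primaryid, drug_seq = drug_seq,
                 role_cod = role, drugname = drugname)
}
reac_rows <- function(primaryid, pt) tibble::tibble(primaryid = primaryid, pt = pt)
outc_rows <- function(primaryid, outc_cod) {
  tibble::tibble(primaryid = primaryid, outc_cod = outc_cod)
}

# Four-report store in which the pair (tirzepatide, Nausea) has the 2x2 table
# (a, b, c, d) = (1, 1, 1, 1): r1 drug+event, r2 drug only, r3 event only,
# r4 neither.
toy_store <- function() {
  demo <- bind_rows(demo_row("1"), demo_row("2", sex = "M"),
                    demo_row("3", sex = ""), demo_row("4"))
  drug <- bind_rows(drug_rows("1", "MOUNJARO"), drug_rows("2", "MOUNJARO"),
                    drug_rows("3", "aspirin"), drug_rows("4", "aspirin"))
  reac <- bind_rows(reac_rows("1", "Nausea"), reac_rows("2", "Headache"),
                    reac_rows("3", "Nausea"), reac_rows("4", "Headache"))
  suppressMessages(
    assemble_reports(demo, drug, reac, empty_outc, empty_indi,
                     synonyms = test_synonyms)
  ) |> deduplicate_reports()
}

# Brute-force 2x2 oracle: naive double loop over reports.
oracle_table <- function(store, drug, event, roles = "PS") {
  ids <- store$reports$primaryid
  exposed <- vapply(ids, function(i) {
    any(store$drugs$primaryid == i & store$drugs$ingredient == drug &
          store$drugs$role %in% roles)
  }, logical(1))
  has_event <- vapply(ids, function(i) {
    any(store$reactions$primaryid == i & store$reactions$pt == event)
  }, logical(1))
  c(a = sum(exposed & has_event), b = sum(exposed & !has_event),
    c = sum(!exposed & has_event), d = sum(!exposed & !has_event))
}

# Independent Pearson chi-square oracle: expected-counts formulation.
chi2_oracle <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / n
  sum((o - e)^2 / e)
}

# Independent evaluation of the BCPNN closed-form lower bound, coded from the
# prior-parameter definitions rather than shared with the implementation.
ic025_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  c1 <- a + b + 1   # row margin + alpha1
  c2 <- a + c + 1   # column margin + beta1
  gamma_ <- (n + 2) * (n + 2) / (c1 * c2)
  e_ic <- log((a + 1) * (n + 2) * (n + 2) / ((n + gamma_) * c1 * c2)) / log(2)
  v_ic <- ((n - a + gamma_ - 1) / ((a + 1) * (1 + n + gamma_)) +
             (n - a - b + 1) / (c1 * (1 + n + 2)) +
             (n - a - c + 1) / (c2 * (1 + n + 2))) / log(2)^2
  e_ic - 2 * sqrt(v_ic)
}

# Random strictly positive 2x2 tables for property tests.
random_tables <- function(n, seed = 101, max_cell = 5000) {
  set.seed(seed)
  tibble::tibble(
    event = sprintf("ev%04d", seq_len(n)),
    a = sample(5:max_cell, n, replace = TRUE),
    b = sample(5:max_cell, n, replace = TRUE),
    c = sample(5:max_cell, n, replace = TRUE),
    d = sample(5:max_cell, n, replace = TRUE)
  )
}

# Printed-precision comparator: printed values are strings; agreement means
# matching at the printed number of decimals, allowing for the rounding
# direction of the last digit at half-way boundaries.
expect_printed <- function(computed, printed, label) {
  nd <- ifelse(grepl("\\.", printed), nchar(sub(".*\\.", "", printed)), 0)
  tol <- 0.55 * 10^(-nd) + 1e-9
  expect_true(all(abs(computed - as.numeric(printed)) <= tol),
              label = paste0(label, ": max deviation ",
                             signif(max(abs(computed - as.numeric(printed))), 3)))
}
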