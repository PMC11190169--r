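# Synthetic FAERS-style report generator. Emulates the structure of a
# quarterly extract — multi-drug multi-event reports with role codes,
# duplicate case versions, heavy demographic missingness, serious-outcome
# codes — with known ground truth, so every pipeline stage is testable
# without any database download. Planted drug-event associations multiply the
# event's baseline per-report probability by a rate ratio among exposed
# reports; that ratio is exactly what the disproportionality estimators
# should recover when the background is rare.

#' Declare a planted drug-event association
#'
#' @param drug Drug name (the study drug or a vocabulary drug).
#' @param event Event PT name (must belong to the event vocabulary).
#' @param rate_ratio Reporting-rate ratio `lambda >= 1` multiplying the
#'   event's baseline probability among reports exposed to `drug`
#'   (`lambda = 1` plants a null pair).
#' @param baseline Optional override of the event's baseline per-report
#'   probability.
#' @return A `planted_signal` list.
#' @export
planted_signal <- function(drug, event, rate_ratio, baseline = NULL) {
  if (rate_ratio < 1) abort("rate_ratio must be >= 1",
                            class = "faersignal_config_error")
  structure(list(drug = drug, event = event, rate_ratio = rate_ratio,
                 baseline = baseline), class = "planted_signal")
}

#' Configure the synthetic report generator
#'
#' Defaults emulate a spontaneous-reporting extract: Zipf-distributed drug
#' and event vocabularies, about two drugs and two reaction PTs per report, a
#' rarely-reported study drug, duplicate case versions, and the heavy
#' missingness of FAERS demographics (most ages unknown).
#'
#' @param n_reports Number of distinct cases to simulate.
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   configuration.
#' @param drug_vocab_size,event_vocab_size Sizes of the background drug and
#'   event vocabularies.
#' @param zipf_exponent Exponent of the Zipf frequency decay for both
#'   vocabularies.
#' @param mean_drugs_per_report Mean drug count per report; counts follow a
#'   truncated geometric with minimum 1.
#' @param mean_events_per_report Expected reaction PTs per report; sets the
#'   scale of the per-PT baseline probabilities.
#' @param study_drug Name of the study drug.
#' @param p_study_drug Marginal probability a report is exposed to the study
#'   drug.
#' @param planted List of [planted_signal()] objects.
#' @param p_duplicate Probability a case emits a second version.
#' @param missingness Named list of missing-data probabilities for `sex`,
#'   `age`, `country`.
#' @param quarters Quarter labels to spread reports over (reporting volume
#'   grows linearly across them).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reports = 50000, seed = 1,
                       drug_vocab_size = 50, event_vocab_size = 100,
                       zipf_exponent = 1,
                       mean_drugs_per_report = 2, mean_events_per_report = 2,
                       study_drug = "studydrug", p_study_drug = 0.01,
                       planted = list(), p_duplicate = 0.05,
                       missingness = list(sex = 0.15, age = 0.6, country = 0.01),
                       quarters = quarter_seq("2022Q2", "2023Q3")) {
  if (n_reports <= 0) abort("n_reports must be positive",
                            class = "faersignal_config_error")
  probs <- c(p_study_drug, p_duplicate, unlist(missingness))
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1]", class = "faersignal_config_error")
  }
  quarter_index(quarters)  # validates labels
  if (inherits(planted, "planted_signal")) planted <- list(planted)

  drugs <- sprintf("drug%03d", seq_len(drug_vocab_size))
  events <- sprintf("Synthetic event %03d", seq_len(event_vocab_size))
  zipf <- function(k) {
    w <- seq_len(k)^(-zipf_exponent)
    w / sum(w)
  }
  drug_freqs <- zipf(drug_vocab_size)
  event_freqs <- zipf(event_vocab_size)
  baselines <- pmin(event_freqs * mean_events_per_report, 0.95)
  names(baselines) <- events

  for (p in planted) {
    if (!(p$drug == study_drug || p$drug %in% drugs)) {
      abort(paste0("Planted drug not in vocabulary: ", p$drug),
            class = "faersignal_config_error")
    }
    if (!(p$event %in% events)) {
      abort(paste0("Planted event not in vocabulary: ", p$event),
            class = "faersignal_config_error")
    }
    if (!is.null(p$baseline)) baselines[p$event] <- p$baseline
  }
  for (p in planted) {
    if (p$rate_ratio * baselines[p$event] > 1) {
      abort(paste0("Infeasible planted signal: rate_ratio * baseline > 1 for ",
                   p$event), class = "faersignal_config_error")
    }
  }

  structure(list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    drug_vocab = drugs, event_vocab = events,
    drug_freqs = drug_freqs, event_baselines = baselines,
    mean_drugs_per_report = mean_drugs_per_report,
    study_drug = study_drug, p_study_drug = p_study_drug,
    planted = planted, p_duplicate = p_duplicate,
    missingness = missingness, quarters = quarters
  ), class = "sim_config")
}

#' Simulate a synthetic report store with ground truth
#'
#' Per report: the drug count is truncated geometric (minimum 1), drugs are
#' drawn without replacement from the Zipf vocabulary, the study drug is
#' added with its marginal exposure probability, and one drug is flagged PS
#' uniformly at random (others get SS/C/I). Each event PT occurs
#' independently with its baseline probability, multiplied by the planted
#' rate ratio in reports exposed to the planted drug. Duplicate case versions
#' (identical content, incremented `case_version`) are emitted with
#' probability `p_duplicate`. Deterministic given the config.
#'
#' @param cfg A [sim_config()].
#' @return A `faers_sim` list: `store` (a `report_store`, duplicates
#'   included, not yet deduplicated) and `truth` (exact tallies on the
#'   deduplicated cases: per-drug and per-event report counts, planted-pair
#'   co-occurrence counts, and the sex mix of study-drug reports).
#' @export
simulate_reports <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_reports
  d_voc <- length(cfg$drug_vocab)

  # -- drugs ---------------------------------------------------------------
  p_geom <- 1 / cfg$mean_drugs_per_report
  k <- pmin(1L + rgeom(n, p_geom), min(6L, d_voc))
  drug_sets <- lapply(seq_len(n), function(i) {
    sample.int(d_voc, k[i], prob = cfg$drug_freqs)
  })
  exposed_study <- runif(n) < cfg$p_study_drug
  drug_names <- map2(drug_sets, exposed_study, function(s, e) {
    c(cfg$drug_vocab[s], if (e) cfg$study_drug)
  })
  n_entries <- lengths(drug_names)
  report_of_entry <- rep.int(seq_len(n), n_entries)
  roles <- sample(c("SS", "C", "I"), sum(n_entries), replace = TRUE,
                  prob = c(0.5, 0.35, 0.15))
  offset <- cumsum(n_entries) - n_entries
  ps_at <- offset + floor(runif(n) * n_entries) + 1
  roles[ps_at] <- "PS"

  # -- events --------------------------------------------------------------
  has_drug <- function(name) {
    if (name == cfg$study_drug) return(exposed_study)
    idx <- match(name, cfg$drug_vocab)
    vapply(drug_sets, function(s) idx %in% s, logical(1))
  }
  planted_by_event <- split(cfg$planted,
                            vapply(cfg$planted, `[[`, "", "event"))
  event_hits <- lapply(seq_along(cfg$event_vocab), function(j) {
    ev <- cfg$event_vocab[j]
    p <- rep(cfg$event_baselines[[j]], n)
    for (pl in planted_by_event[[ev]]) {
      p <- ifelse(has_drug(pl$drug), pmin(p * pl$rate_ratio, 1), p)
    }
    which(runif(n) < p)
  })
  reactions0 <- tibble(
    report = unlist(event_hits, use.names = FALSE),
    pt = rep(cfg$event_vocab, lengths(event_hits))
  ) |> arrange(.data$report, .data$pt)

  # -- demographics --------------------------------------------------------
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.62, 0.38))
  sex[runif(n) < cfg$missingness$sex] <- "UNK"
  age <- pmin(pmax(round(rnorm(n, 50, 16)), 1), 99)
  age[runif(n) < cfg$missingness$age] <- NA
  country <- sample(c("US", "CA", "JP", "GB", "DE", "BR", "AE"), n,
                    replace = TRUE,
                    prob = c(0.88, 0.03, 0.03, 0.02, 0.02, 0.01, 0.01))
  country[runif(n) < cfg$missingness$country] <- "UNK"
  quarter <- sample(cfg$quarters, n, replace = TRUE,
                    prob = seq_along(cfg$quarters))
  bounds <- lapply(setNames(nm = cfg$quarters), quarter_bounds)
  q_first <- vapply(bounds, function(b) as.integer(b[1]), integer(1))
  q_ndays <- vapply(bounds, function(b) as.integer(b[2] - b[1]) + 1L, integer(1))
  receipt_date <- as.Date(q_first[quarter], origin = "1970-01-01") +
    floor(runif(n) * q_ndays[quarter])

  # -- ids and duplicates --------------------------------------------------
  caseid <- as.character(70000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")
  dup <- runif(n) < cfg$p_duplicate

  reports <- tibble(
    primaryid = primaryid, caseid = caseid, case_version = 1L,
    receipt_date = receipt_date, quarter = quarter, sex = sex,
    age_years = as.numeric(age), country = country,
    continent = continent_of(country)
  )
  drugs <- tibble(
    primaryid = primaryid[report_of_entry],
    drug_seq = as.character(sequence(n_entries)),
    verbatim_name = unlist(drug_names, use.names = FALSE),
    ingredient = unlist(drug_names, use.names = FALSE),
    role = roles
  )
  reactions <- tibble(primaryid = primaryid[reactions0$report],
                      pt = reactions0$pt)
  outc_p <- c(DE = 0.005, LT = 0.002, DS = 0.001, HO = 0.03, CA = 0.0005,
              RI = 0.001, OT = 0.04)
  outcomes <- list_rbind(map(names(outc_p), function(code) {
    hit <- which(runif(n) < outc_p[[code]])
    tibble(primaryid = primaryid[hit], outcome = code)
  })) |> arrange(.data$primaryid, .data$outcome)
  indi_pts <- c("Product used for unknown indication", "Type 2 diabetes mellitus",
                "Weight decreased", "Obesity")
  has_indi <- runif(nrow(drugs)) < 0.4
  indications <- tibble(
    primaryid = drugs$primaryid[has_indi],
    drug_seq = drugs$drug_seq[has_indi],
    pt = sample(indi_pts, sum(has_indi), replace = TRUE,
                prob = c(0.55, 0.25, 0.1, 0.1))
  )

  dup_ids <- primaryid[dup]
  dup_map <- setNames(paste0(caseid[dup], "2"), dup_ids)
  dup_child <- function(x) {
    y <- filter(x, .data$primaryid %in% dup_ids)
    y$primaryid <- unname(dup_map[y$primaryid])
    y
  }
  reports_all <- bind_rows(
    reports,
    reports[dup, , drop = FALSE] |>
      mutate(primaryid = unname(dup_map[.data$primaryid]), case_version = 2L)
  )
  store <- new_report_store(
    reports_all,
    bind_rows(drugs, dup_child(drugs)),
    bind_rows(reactions, dup_child(reactions)),
    bind_rows(outcomes, dup_child(outcomes)),
    bind_rows(indications, dup_child(indications)),
    n_raw = nrow(reports_all)
  )

  # -- ground truth (on the deduplicated cases; versions are identical) ----
  drug_counts <- drugs |>
    distinct(.data$primaryid, .data$ingredient, .keep_all = TRUE) |>
    count(.data$ingredient, name = "n_reports")
  ps_counts <- drugs |>
    filter(.data$role == "PS") |>
    distinct(.data$primaryid, .data$ingredient) |>
    count(.data$ingredient, name = "n_reports_ps")
  event_counts <- count(reactions, .data$pt, name = "n_reports")
  planted_truth <- list_rbind(map(cfg$planted, function(pl) {
    exp_i <- has_drug(pl$drug)
    ev_i <- seq_len(n) %in% reactions0$report[reactions0$pt == pl$event]
    tibble(drug = pl$drug, event = pl$event, rate_ratio = pl$rate_ratio,
           baseline = unname(cfg$event_baselines[pl$event]),
           n_exposed = sum(exp_i), n_event = sum(ev_i),
           n_both = sum(exp_i & ev_i), n_total = n)
  }))
  truth <- list(
    n_cases = n, n_raw = nrow(reports_all), n_duplicates = sum(dup),
    drug_counts = left_join(drug_counts, ps_counts, by = "ingredient") |>
      mutate(n_reports_ps = dplyr::coalesce(.data$n_reports_ps, 0L)),
    event_counts = event_counts,
    planted = planted_truth,
    study_sex = reports |>
      filter(.data$primaryid %in%
               drugs$primaryid[drugs$ingredient == cfg$study_drug]) |>
      count(.data$sex, name = "n")
  )
  structure(list(store = store, truth = truth, config = cfg),
            class = "faers_sim")
}

#' Synthetic PT-to-SOC map for the simulator vocabulary
#'
#' Assigns the simulated event vocabulary cyclically to eight synthetic
#' system organ classes, for SOC-level tests on simulated data.
#'
#' @param cfg A [sim_config()].
#' @return A `meddra_map`.
#' @export
synthetic_meddra_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  v <- length(cfg$event_vocab)
  soc <- (seq_len(v) - 1L) %% 8L + 1L
  new_meddra_map(tibble(
    pt_code = 98000000L + seq_len(v),
    pt_name = cfg$event_vocab,
    soc_code = 99000000L + soc,
    soc_name = sprintf("Synthetic SOC %d", soc),
    primary_soc = TRUE
  ))
}

#' Write a store as FAERS-dialect quarterly files
#'
#' Emits `demo.txt`, `drug.txt`, `reac.txt`, `outc.txt`, `indi.txt`
#' (dollar-delimited, one header line) in one subdirectory per quarter, the
#' layout [read_faers_quarters()] ingests. Missing values are written as
#' empty fields; `UNK` sex/country round-trip through empty fields.
#'
#' @param store A `report_store`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_faers_quarters <- function(store, dir) {
  stopifnot(inherits(store, "report_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dollar_line <- function(...) {
    cols <- lapply(list(...), function(x) dplyr::coalesce(as.character(x), ""))
    do.call(paste, c(cols, sep = "$"))
  }
  for (q in unique(store$reports$quarter)) {
    qdir <- file.path(dir, q)
    dir.create(qdir, showWarnings = FALSE)
    rp <- filter(store$reports, .data$quarter == q)
    sel <- function(x) filter(x, .data$primaryid %in% rp$primaryid)
    writeLines(c("primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$occr_country",
                 dollar_line(rp$primaryid, rp$caseid, rp$case_version,
                             format(rp$receipt_date, "%Y%m%d"),
                             ifelse(rp$sex == "UNK", NA, rp$sex),
                             rp$age_years,
                             ifelse(is.na(rp$age_years), NA, "YR"),
                             ifelse(rp$country == "UNK", NA, rp$country))),
               file.path(qdir, "demo.txt"))
    dg <- sel(store$drugs)
    writeLines(c("primaryid$drug_seq$role_cod$drugname",
                 dollar_line(dg$primaryid, dg$drug_seq, dg$role, dg$verbatim_name)),
               file.path(qdir, "drug.txt"))
    rc <- sel(store$reactions)
    writeLines(c("primaryid$pt", dollar_line(rc$primaryid, rc$pt)),
               file.path(qdir, "reac.txt"))
    oc <- sel(store$outcomes)
    writeLines(c("primaryid$outc_cod", dollar_line(oc$primaryid, oc$outcome)),
               file.path(qdir, "outc.txt"))
    id <- sel(store$indications)
    writeLines(c("primaryid$indi_drug_seq$indi_pt",
                 dollar_line(id$primaryid, id$drug_seq, id$pt)),
               file.path(qdir, "indi.txt"))
  }
  invisible(dir)
}

#' Compare estimated signals against the planted ground truth
#'
#' For each planted pair, reports the planted rate ratio next to the
#' estimated EBGM and ROR and the relative error of EBGM against the ratio.
#' A planted pair absent from the estimates (no co-occurrence reports) is
#' recorded as non-detected.
#'
#' @param sim A `faers_sim` from [simulate_reports()].
#' @param estimates A signal table covering the study data — typically
#'   `evaluate_criteria(signal_stats(tables))` over all tables, so that null
#'   pairs are present too.
#' @return A `faers_recovery` tibble with one row per planted pair.
#' @export
recovery_check <- function(sim, estimates) {
  stopifnot(inherits(sim, "faers_sim"))
  planted <- sim$truth$planted
  if (is.null(planted) || nrow(planted) == 0) {
    return(structure(tibble(drug = character(), event = character(),
                            rate_ratio = numeric(), a = integer(),
                            ebgm = numeric(), ror = numeric(),
                            ebgm_low = numeric(), rel_error_ebgm = numeric(),
                            detected_all_four = logical()),
                     class = c("faers_recovery", class(tibble()))))
  }
  est <- as_tibble(estimates)
  if (!"all_four" %in% names(est)) est$all_four <- NA
  out <- planted |>
    left_join(select(est, "event", "a", "ebgm", "ror", "ebgm_low", "all_four"),
              by = "event") |>
    mutate(rel_error_ebgm = abs(.data$ebgm - .data$rate_ratio) / .data$rate_ratio,
           detected_all_four = dplyr::coalesce(.data$all_four, FALSE)) |>
    select("drug", "event", "rate_ratio", "a", "ebgm", "ror", "ebgm_low",
           "rel_error_ebgm", "detected_all_four")
  structure(out, class = c("faers_recovery", class(out)),
            median_rel_error = stats::median(out$rel_error_ebgm, na.rm = TRUE))
}

#' @method glance faers_recovery
#' @export
glance.faers_recovery <- function(x, ...) {
  tibble(n_planted = nrow(x), n_detected = sum(x$detected_all_four),
         median_rel_error_ebgm = attr(x, "median_rel_error") %||% NA_real_)
}
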