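test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_reports = 100, seed = 1)
  a <- simulate_reports(cfg)
  b <- simulate_reports(cfg)
  for (tab in c("reports", "drugs", "reactions", "outcomes", "indications")) {
    expect_identical(a$store[[tab]], b$store[[tab]], label = tab)
  }
  expect_identical(a$truth, b$truth)
  # and a different seed changes the data
  c <- simulate_reports(sim_config(n_reports = 100, seed = 2))
  expect_false(identical(a$store$reports, c$store$reports))
})

test_that("duplicate emission respects p_duplicate", {
  none <- simulate_reports(sim_config(n_reports = 500, seed = 4, p_duplicate = 0))
  expect_equal(dplyr::n_distinct(none$store$reports$caseid), 500)
  expect_equal(nrow(none$store$reports), 500)
  some <- simulate_reports(sim_config(n_reports = 500, seed = 4, p_duplicate = 0.2))
  expect_equal(nrow(some$store$reports), 500 + some$truth$n_duplicates)
  expect_gt(some$truth$n_duplicates, 0)
})

test_that("infeasible planted signals are rejected at configuration time", {
  expect_error(sim_config(planted = planted_signal("studydrug",
                                                   "Synthetic event 001",
                                                   rate_ratio = 5,
                                                   baseline = 0.5)),
               class = "faersignal_config_error")
  expect_error(planted_signal("studydrug", "x", rate_ratio = 0.5),
               class = "faersignal_config_error")
  expect_error(sim_config(planted = planted_signal("nosuchdrug",
                                                   "Synthetic event 001", 2)),
               class = "faersignal_config_error")
  expect_error(sim_config(p_study_drug = 1.5), class = "faersignal_config_error")
})

test_that("ground-truth tallies equal a brute-force recount of the emitted reports", {
  cfg <- sim_config(n_reports = 400, seed = 8, p_study_drug = 0.1,
                    planted = planted_signal("studydrug", "Synthetic event 010",
                                             5, baseline = 0.02))
  sim <- simulate_reports(cfg)
  store <- deduplicate_reports(sim$store)
  ids <- store$reports$primaryid
  exposed <- ids %in% store$drugs$primaryid[store$drugs$ingredient == "studydrug"]
  has_ev <- ids %in%
    store$reactions$primaryid[store$reactions$pt == "Synthetic event 010"]
  tr <- sim$truth$planted
  expect_equal(tr$n_exposed, sum(exposed))
  expect_equal(tr$n_event, sum(has_ev))
  expect_equal(tr$n_both, sum(exposed & has_ev))
  expect_equal(tr$n_total, length(ids))
  # drug marginals
  dc <- sim$truth$drug_counts
  got <- store$drugs |> dplyr::distinct(primaryid, ingredient) |>
    dplyr::count(ingredient, name = "n_reports")
  expect_equal(as.data.frame(dplyr::arrange(dc[, c("ingredient", "n_reports")],
                                            ingredient)),
               as.data.frame(dplyr::arrange(got, ingredient)))
})

test_that("written quarters round-trip exactly through ingestion and dedup", {
  sim <- simulate_reports(sim_config(n_reports = 200, seed = 6,
                                     p_duplicate = 0.1))
  dir <- withr::local_tempdir()
  write_faers_quarters(sim$store, dir)
  expect_true(all(file.exists(file.path(
    dir, unique(sim$store$reports$quarter), "demo.txt"))))
  raw <- read_faers_quarters(dir)
  back <- deduplicate_reports(
    assemble_reports(raw$demo, raw$drug, raw$reac, raw$outc, raw$indi))
  orig <- deduplicate_reports(sim$store)
  expect_equal(n_reports(back), dplyr::n_distinct(sim$store$reports$caseid))
  for (tab in c("reports", "drugs", "reactions", "outcomes", "indications")) {
    x <- dplyr::arrange_all(tibble::as_tibble(orig[[tab]]))
    y <- dplyr::arrange_all(tibble::as_tibble(back[[tab]]))
    expect_equal(as.data.frame(x), as.data.frame(y), label = tab)
  }
})

test_that("contingency tables are identical before and after serialization", {
  sim <- simulate_reports(sim_config(n_reports = 1000, seed = 12,
                                     p_study_drug = 0.05, p_duplicate = 0.05))
  dir <- withr::local_tempdir()
  write_faers_quarters(sim$store, dir)
  raw <- read_faers_quarters(dir)
  back <- deduplicate_reports(
    assemble_reports(raw$demo, raw$drug, raw$reac, raw$outc, raw$indi))
  orig <- deduplicate_reports(sim$store)
  roles <- c("PS", "SS", "C", "I")
  expect_equal(as.data.frame(build_contingency(back, "studydrug", roles)),
               as.data.frame(build_contingency(orig, "studydrug", roles)))
})

test_that("recovery reporting joins planted pairs with estimates", {
  cfg <- sim_config(n_reports = 5000, seed = 14, p_study_drug = 0.05,
                    planted = planted_signal("studydrug", "Synthetic event 020",
                                             8, baseline = 0.02))
  sim <- simulate_reports(cfg)
  store <- deduplicate_reports(sim$store)
  est <- evaluate_criteria(signal_stats(
    build_contingency(store, "studydrug", roles = c("PS", "SS", "C", "I"))))
  rec <- recovery_check(sim, est)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$rate_ratio, 8)
  expect_true(is.finite(rec$ebgm))
  expect_equal(rec$rel_error_ebgm, abs(rec$ebgm - 8) / 8)
  # no planted pairs -> empty summary
  empty <- recovery_check(simulate_reports(sim_config(n_reports = 50, seed = 1)),
                          est)
  expect_equal(nrow(empty), 0)
})
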