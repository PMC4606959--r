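# ICD classification and multiple-cause tabulation.

test_that("default map includes cardiac anomalies and excludes peripheral ones", {
  map <- icd_code_map()
  expect_true(icd_classify("Q210", 10, map))    # VSD
  expect_true(icd_classify("Q26", 10, map))
  expect_false(icd_classify("Q271", 10, map))   # peripheral vascular
  expect_false(icd_classify("I219", 10, map))   # outside all ranges
  expect_true(icd_classify("7450", 9, map))
  expect_true(icd_classify("74749", 9, map))
  expect_false(icd_classify("7475", 9, map))    # excluded range
  expect_false(icd_classify("7479", 9, map))
  expect_true(icd_classify("746", 8, map))      # 3-digit code, no subcode
  expect_error(icd_classify("Q210", 11, map), "version")
})

test_that("code maps load from CSV map files", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(version = 10L, start = "Q20", end = "Q26ZZZ", action = "include"),
    path, row.names = FALSE
  )
  expect_error(icd_code_map(path), "include ranges for ICD-8")
  full <- as.data.frame(icd_code_map())
  utils::write.csv(full[, c("version", "start", "end", "action")], path,
                   row.names = FALSE)
  m <- icd_code_map(path)
  expect_true(icd_classify("Q210", 10, m))
  expect_false(icd_classify("7475", 9, m))
})

test_that("classification is idempotent and normalization strips dots", {
  codes <- normalize_icd(c("Q21.0", " q24.9", "745.0"))
  expect_equal(codes, c("Q210", "Q249", "7450"))
  once <- icd_classify(codes, 10, icd_code_map())
  expect_identical(icd_classify(codes, 10, icd_code_map()), once)
})

test_that("tabulation matches the hand count of the record fixture", {
  counts <- icd_tabulate(as_death_records(records_fixture()))
  # 7 records carry the condition as underlying cause, 3 as a mention only
  expect_equal(sum(counts$underlying), 7)
  expect_equal(sum(counts$any_mention), 10)
  expect_equal(share(sum(counts$underlying), sum(counts$any_mention)), 70.0)
  expect_true(all(counts$underlying <= counts$any_mention))
})

test_that("mention-only records count toward any_mention but not underlying", {
  rec <- tibble::tibble(
    age = 3L, sex = "male", year = 2001L, icd_version = 10L,
    underlying_cause = "I50.0", cause_2 = "Q21.0"
  )
  counts <- icd_tabulate(as_death_records(rec))
  expect_equal(counts$any_mention, 1L)
  expect_equal(counts$underlying, 0L)
})

test_that("degenerate records are excluded with notice, empty input allowed", {
  expect_equal(nrow(icd_tabulate(as_death_records(records_fixture())[0, ])), 0)
  rec <- as_death_records(tibble::tibble(
    age = c(1L, NA), sex = c("male", "female"), year = 2000L,
    icd_version = 10L, underlying_cause = "Q210", cause_2 = ""
  ))
  expect_message(out <- icd_tabulate(rec), "dropped")
  expect_equal(sum(out$any_mention), 1)
  expect_equal(attr(out, "n_missing_demo"), 1L)
  rec2 <- as_death_records(tibble::tibble(
    age = 1L, sex = "male", year = 2000L, icd_version = 10L,
    underlying_cause = "", cause_2 = ""
  ))
  expect_warning(out2 <- icd_tabulate(rec2), "empty cause")
  expect_equal(nrow(out2), 0)
})

test_that("records CSV round-trips and underlying joins the mention list", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(records_fixture(), path, row.names = FALSE)
  rec <- read_death_records(path)
  expect_equal(nrow(rec), 10)
  expect_true(all(mapply(function(u, m) u %in% m,
                         rec$underlying_cause, rec$mentions)))
})

test_that("aggregated cell counts conserve the number of classified records", {
  tr <- small_truth(seed = 2)
  d <- simulate_deaths(tr)
  # build one certificate per simulated death (capped for speed)
  d <- d[d$deaths > 0 & d$year %in% 2000:2001, ]
  rec <- tibble::tibble(
    age = rep(d$age, d$deaths), sex = rep(d$sex, d$deaths),
    year = rep(d$year, d$deaths), icd_version = 10L,
    underlying_cause = "Q24.9", cause_2 = ""
  )
  counts <- icd_tabulate(as_death_records(rec))
  expect_equal(sum(counts$any_mention), nrow(rec))
  expect_equal(sum(counts$underlying), nrow(rec))
})

test_that("rates divide counts by matching population and guard the join", {
  pop <- tibble::tibble(
    age = c(10L, 10L), sex = c("male", "female"),
    year = 2000L, population = c(1e5, 1e5)
  )
  counts <- tibble::tibble(
    age = 10L, sex = "male", year = 2000L, any_mention = 53L, underlying = 40L
  )
  obs <- rates_from_counts(counts, pop)
  expect_equal(obs$value, 53 / 1e5)      # 53 per 100,000 person-years
  expect_equal(obs$effective_n, 1e5)
  # zero deaths retained
  counts0 <- dplyr::mutate(counts, any_mention = 0L)
  expect_equal(rates_from_counts(counts0, pop)$value, 0)
  # missing cell is a named hard error
  expect_error(
    rates_from_counts(dplyr::mutate(counts, year = 2001L), pop),
    "age=10 sex=male year=2001"
  )
  expect_error(
    rates_from_counts(counts, dplyr::mutate(pop, population = 0)),
    "positive"
  )
})
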