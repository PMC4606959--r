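#' ICD code map for condition-associated deaths
#'
#' A code map is a table of lexicographic code intervals per ICD revision,
#' each flagged `include` or `exclude`. A normalized (dot-stripped,
#' upper-case) code is condition-associated when it falls inside at least one
#' include interval and inside no exclude interval of its revision.
#' Lexicographic interval matching is robust to the 3/4/5-character code
#' lengths used across revisions.
#'
#' The default map targets congenital anomalies of the heart and great
#' vessels and excludes anomalies of the peripheral circulatory system:
#' ICD-8/9 include 745.0-747.49 and exclude 747.5-747.9; ICD-10 includes
#' Q20-Q26 and excludes Q27-Q28. It is an editable approximation of the
#' cause list; supply your own table to override.
#'
#' @param map optional tibble with columns `version` (8, 9 or 10), `start`,
#'   `end` (code interval bounds, dots allowed), `action`
#'   (`"include"`/`"exclude"`), or the path of a CSV file with those
#'   columns (one range per row); defaults to the map above.
#' @return a tibble of class `icd_code_map`.
#' @export
icd_code_map <- function(map = NULL) {
  if (is.character(map) && length(map) == 1L) {
    map <- utils::read.csv(map)
  }
  if (is.null(map)) {
    map <- tibble::tribble(
      ~version, ~start,  ~end,      ~action,
      8L,       "745",   "747.49",  "include",
      8L,       "747.5", "747.9ZZ", "exclude",
      9L,       "745",   "747.49",  "include",
      9L,       "747.5", "747.9ZZ", "exclude",
      10L,      "Q20",   "Q26ZZZ",  "include",
      10L,      "Q27",   "Q28ZZZ",  "exclude"
    )
  }
  map <- tibble::as_tibble(map)
  req <- c("version", "start", "end", "action")
  if (!all(req %in% names(map))) {
    stop("code map needs columns ", paste(req, collapse = ", "))
  }
  if (!all(map$version %in% c(8L, 9L, 10L))) {
    stop("ICD versions must be 8, 9 or 10")
  }
  if (!all(map$action %in% c("include", "exclude"))) {
    stop("`action` must be 'include' or 'exclude'")
  }
  map$start <- normalize_icd(map$start)
  map$end <- normalize_icd(map$end)
  if (any(map$start == "" | map$start > map$end)) {
    stop("each range needs non-empty start <= end")
  }
  for (v in c(8L, 9L, 10L)) {
    if (!any(map$version == v & map$action == "include")) {
      stop("code map must define include ranges for ICD-", v)
    }
  }
  class(map) <- unique(c("icd_code_map", class(map)))
  map
}

#' Normalize ICD codes
#'
#' Strips dots and whitespace and upper-cases, the canonical form used for
#' lexicographic interval matching.
#'
#' @param code character vector of raw codes.
#' @return normalized codes.
#' @export
normalize_icd <- function(code) {
  toupper(gsub("[.[:space:]]", "", as.character(code)))
}

#' Classify ICD codes as condition-associated
#'
#' @param code character vector of normalized codes (use [normalize_icd()]).
#' @param version a single ICD revision (8, 9 or 10).
#' @param map an [icd_code_map()].
#' @return logical vector: inside an include range and no exclude range.
#' @export
icd_classify <- function(code, version, map = icd_code_map()) {
  map <- icd_code_map(map)
  if (length(version) != 1L || !version %in% c(8L, 9L, 10L)) {
    stop("unknown ICD version: ", paste(version, collapse = ","))
  }
  m <- map[map$version == as.integer(version), ]
  in_any <- function(action) {
    r <- m[m$action == action, ]
    if (nrow(r) == 0) return(rep(FALSE, length(code)))
    hit <- rep(FALSE, length(code))
    for (i in seq_len(nrow(r))) {
      hit <- hit | (code >= r$start[i] & code <= r$end[i])
    }
    hit
  }
  in_any("include") & !in_any("exclude")
}

#' Read death records from a multiple-cause CSV
#'
#' Expects columns `age`, `sex`, `year`, `icd_version`, `underlying_cause`
#' and any number of `cause_*` contributing-cause columns (blank-padded),
#' mirroring multiple-cause-of-death layouts at CSV fidelity. Codes are
#' normalized on load and the underlying cause is added to the mention list
#' when absent.
#'
#' @param path CSV file path.
#' @return tibble of death records with a `mentions` list-column.
#' @export
read_death_records <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  as_death_records(raw)
}

#' @rdname read_death_records
#' @param df a data frame in the same layout as the CSV.
#' @export
as_death_records <- function(df) {
  req <- c("age", "sex", "year", "icd_version", "underlying_cause")
  if (!all(req %in% names(df))) {
    stop("records need columns ", paste(req, collapse = ", "))
  }
  cause_cols <- grep("^cause_", names(df), value = TRUE)
  und <- normalize_icd(df$underlying_cause)
  mentions <- lapply(seq_len(nrow(df)), function(i) {
    m <- normalize_icd(unlist(df[i, cause_cols], use.names = FALSE))
    m <- m[!is.na(m) & m != ""]
    u <- und[i]
    if (!is.na(u) && u != "" && !(u %in% m)) m <- c(u, m)
    m
  })
  tibble::tibble(
    age = suppressWarnings(as.integer(df$age)),
    sex = as.character(df$sex),
    year = suppressWarnings(as.integer(df$year)),
    icd_version = suppressWarnings(as.integer(df$icd_version)),
    underlying_cause = und,
    mentions = mentions
  )
}

#' Tabulate condition-associated deaths by age, sex and year
#'
#' A record counts toward `any_mention` when at least one of its listed
#' causes is condition-associated under the map, and toward
#' `underlying` when its underlying cause is. Records with an empty cause
#' list are excluded with a warning; records missing age or sex are dropped
#' with a logged count. Underlying counts never exceed any-mention counts.
#'
#' @param records tibble from [read_death_records()] / [as_death_records()].
#' @param map an [icd_code_map()].
#' @return tibble `age`, `sex`, `year`, `any_mention`, `underlying`, with
#'   attributes `n_empty_cause` and `n_missing_demo` recording exclusions.
#' @export
icd_tabulate <- function(records, map = icd_code_map()) {
  map <- icd_code_map(map)
  if (nrow(records) == 0) {
    return(tibble::tibble(
      age = integer(), sex = character(), year = integer(),
      any_mention = integer(), underlying = integer()
    ))
  }
  empty <- lengths(records$mentions) == 0
  if (any(empty)) {
    warning(sum(empty), " record(s) with empty cause list excluded")
    records <- records[!empty, , drop = FALSE]
  }
  missing_demo <- is.na(records$age) | is.na(records$sex) | records$sex == "" |
    is.na(records$year)
  n_missing <- sum(missing_demo)
  if (n_missing > 0) {
    message(n_missing, " record(s) missing age/sex/year dropped")
    records <- records[!missing_demo, , drop = FALSE]
  }
  any_hit <- vapply(seq_len(nrow(records)), function(i) {
    any(icd_classify(records$mentions[[i]], records$icd_version[i], map))
  }, logical(1))
  und_hit <- vapply(seq_len(nrow(records)), function(i) {
    icd_classify(records$underlying_cause[i], records$icd_version[i], map)
  }, logical(1))
  out <- tibble::tibble(
    age = records$age, sex = records$sex, year = records$year,
    any_mention = as.integer(any_hit), underlying = as.integer(und_hit & any_hit)
  ) %>%
    dplyr::group_by(.data$age, .data$sex, .data$year) %>%
    dplyr::summarise(
      any_mention = sum(.data$any_mention),
      underlying = sum(.data$underlying),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$year, .data$sex, .data$age)
  attr(out, "n_empty_cause") <- sum(empty)
  attr(out, "n_missing_demo") <- n_missing
  out
}

#' Convert death counts to mortality-rate observations
#'
#' Divides condition-associated death counts by the midyear population of the
#' matching age/sex/year cell, carrying the population as the effective
#' sample size (person-years) for likelihood weighting. Zero-death cells are
#' retained with rate 0.
#'
#' @param counts tibble with `age`, `sex`, `year` and a death-count column
#'   (`deaths`, `any_mention`, or one named via `count_col`).
#' @param population tibble `age`, `sex`, `year`, `population`.
#' @param count_col which column of `counts` holds the death counts; by
#'   default `deaths` if present, else `any_mention`.
#' @return CSMR observations (see [observations()]).
#' @export
rates_from_counts <- function(counts, population, count_col = NULL) {
  if (is.null(count_col)) {
    count_col <- if ("deaths" %in% names(counts)) "deaths" else "any_mention"
  }
  if (!count_col %in% names(counts)) stop("no count column '", count_col, "'")
  merged <- dplyr::left_join(
    counts, population[, c("age", "sex", "year", "population")],
    by = c("age", "sex", "year"), suffix = c("", ".pop")
  )
  popcol <- if ("population.pop" %in% names(merged)) "population.pop" else "population"
  miss <- is.na(merged[[popcol]])
  if (any(miss)) {
    i <- which(miss)[1]
    stop(sprintf(
      "no population for cell age=%d sex=%s year=%d (and %d more)",
      merged$age[i], merged$sex[i], merged$year[i], sum(miss) - 1L
    ))
  }
  if (any(merged[[popcol]] <= 0)) stop("population must be positive in every cell")
  observations(
    measure = "csmr",
    age_lo = merged$age, age_hi = merged$age,
    sex = merged$sex, year = merged$year,
    value = merged[[count_col]] / merged[[popcol]],
    effective_n = merged[[popcol]]
  )
}
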