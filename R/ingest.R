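#' Parse and validate raw occurrence records
#'
#' Reads a table of opportunistic occurrence records (one row per record of a
#' species on a date at a 1 km grid-cell site), applies the study window,
#' restricts to a declared species register, and collapses duplicate records.
#' Records are detection/non-detection only: sub-daily duplicates and repeated
#' records of the same species on the same visit carry no extra information
#' and are dropped silently, with counts kept in the ingest log.
#'
#' Dates must be fully resolved (`YYYY-MM-DD`). Records supplied with only
#' year or year-month precision are rejected (counted in the log), because a
#' visit is defined by an exact date. Any other unparseable date is treated as
#' a data error and aborts with the offending row numbers.
#'
#' @param records A data frame (or path to a CSV file) with columns
#'   `species`, `date`, `site`. `date` may be `Date` or `YYYY-MM-DD` strings.
#' @param start_year,end_year Inclusive study window in calendar years.
#' @param species Optional character vector: the declared species register.
#'   Records of species outside the register are dropped and counted. When
#'   `NULL`, every species present is accepted.
#' @return A tibble with columns `species`, `date` (`Date`), `site`, one row
#'   per unique (species, date, site) record, carrying an `"ingest_log"`
#'   attribute (see [ingest_log()]).
#' @seealso [build_visits()], [filter_sites()]
#' @examples
#' raw <- tibble::tibble(
#'   species = c("a", "a", "b"),
#'   date = c("1995-06-01", "1995-06-01", "1979-05-01"),
#'   site = "SU1234"
#' )
#' parse_records(raw, 1980, 2012)
#' @export
parse_records <- function(records, start_year = 1980, end_year = 2012,
                          species = NULL) {
  if (is.character(records) && length(records) == 1) {
    records <- readr::read_csv(records, col_types = readr::cols(.default = "c"),
                               progress = FALSE)
  }
  records <- as_tibble(records)
  need <- c("species", "date", "site")
  if (!all(need %in% names(records))) {
    abort(paste0("`records` must have columns ",
                 paste(need, collapse = ", "), "."))
  }
  if (start_year > end_year) abort("`start_year` must not exceed `end_year`.")
  n_in <- nrow(records)
  if (n_in == 0) abort("No records supplied.")
  if (any(records$species == "" | is.na(records$species)) ||
      any(records$site == "" | is.na(records$site))) {
    abort("Empty species or site identifiers are not allowed.")
  }

  if (inherits(records$date, "Date")) {
    parsed <- records$date
    partial <- rep(FALSE, n_in)
  } else {
    raw <- as.character(records$date)
    full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", raw)
    # year or year-month precision: rejected with a count, not an error
    partial <- !full & grepl("^\\d{4}(-\\d{1,2})?$", raw)
    bad <- !full & !partial
    if (any(bad)) {
      abort(paste0("Unparseable date(s) at row(s): ",
                   paste(head(which(bad), 5), collapse = ", "),
                   if (sum(bad) > 5) " ..." else "", "."))
    }
    parsed <- as.Date(rep(NA_character_, n_in))
    parsed[full] <- as.Date(raw[full], format = "%Y-%m-%d")
    if (any(full & is.na(parsed))) {
      bad <- which(full & is.na(parsed))
      abort(paste0("Invalid calendar date(s) at row(s): ",
                   paste(head(bad, 5), collapse = ", "), "."))
    }
  }
  out <- tibble(species = as.character(records$species),
                date = parsed, site = as.character(records$site))
  n_partial <- sum(partial)
  out <- out[!partial, ]

  yr <- as.integer(format(out$date, "%Y"))
  in_window <- yr >= start_year & yr <= end_year
  n_window <- sum(!in_window)
  out <- out[in_window, ]

  n_unknown <- 0L
  if (!is.null(species)) {
    known <- out$species %in% species
    n_unknown <- sum(!known)
    out <- out[known, ]
  }

  n_before <- nrow(out)
  out <- distinct(out, .data$species, .data$date, .data$site)
  n_dup <- n_before - nrow(out)

  if (nrow(out) == 0) {
    abort(paste0("No records remain after filtering (window ", start_year,
                 "-", end_year, ")."))
  }
  log <- tibble(
    step = c("records_in", "dropped_partial_date", "dropped_outside_window",
             "dropped_unknown_species", "dropped_duplicate", "records_kept"),
    n = c(n_in, n_partial, n_window, n_unknown, n_dup, nrow(out))
  )
  attr(out, "ingest_log") <- log
  out
}

#' Retrieve the ingest log of a record set
#'
#' @param records A record tibble produced by [parse_records()].
#' @return A tibble of per-step record counts.
#' @export
ingest_log <- function(records) {
  log <- attr(records, "ingest_log")
  if (is.null(log)) abort("`records` carries no ingest log.")
  log
}

#' Assemble visits and detection histories from records
#'
#' A visit is a unique combination of site (1 km grid cell) and date. Each
#' visit records the set of species detected and its list length `L`, the
#' number of species on the visit's list -- the effort proxy used by the
#' detection sub-model of [fit_occupancy()].
#'
#' @param records A tibble with columns `species`, `date`, `site`
#'   (typically from [parse_records()]).
#' @return A tibble of class `visit_table` with columns `visit_id`, `site`,
#'   `date`, `year`, `list_length` and a list-column `species_list` (sorted
#'   character vector of species detected on the visit).
#' @examples
#' recs <- tibble::tibble(
#'   species = c("a", "b", "a"),
#'   date = as.Date(c("2000-06-01", "2000-06-01", "2000-06-02")),
#'   site = "SU1234"
#' )
#' build_visits(recs)
#' @export
build_visits <- function(records) {
  if (nrow(records) == 0) abort("Cannot build visits from an empty record set.")
  visits <- records %>%
    mutate(date = as.Date(.data$date)) %>%
    group_by(.data$site, .data$date) %>%
    summarise(species_list = list(sort(unique(.data$species))),
              .groups = "drop") %>%
    mutate(
      year = as.integer(format(.data$date, "%Y")),
      list_length = lengths(.data$species_list),
      visit_id = paste(.data$site, format(.data$date, "%Y-%m-%d"), sep = "_")
    ) %>%
    select("visit_id", "site", "date", "year", "list_length", "species_list") %>%
    arrange(.data$site, .data$date)
  class(visits) <- c("visit_table", class(visits))
  visits
}

#' Keep only well-sampled sites
#'
#' Opportunistic recording leaves many sites with a single casual visit;
#' occupancy trends are only estimable where sites are revisited. This keeps
#' the visits of sites with at least `min_years` distinct calendar years of
#' visits and drops the rest.
#'
#' @param visits A `visit_table` from [build_visits()].
#' @param min_years Minimum number of distinct years with at least one visit
#'   a site needs to be retained (default 3).
#' @return The filtered `visit_table`; idempotent for a fixed `min_years`.
#' @export
filter_sites <- function(visits, min_years = 3) {
  if (min_years < 1) abort("`min_years` must be >= 1.")
  keep <- visits %>%
    group_by(.data$site) %>%
    summarise(n_years = n_distinct(.data$year), .groups = "drop") %>%
    filter(.data$n_years >= min_years) %>%
    pull(.data$site)
  out <- visits[visits$site %in% keep, ]
  if (nrow(out) == 0) {
    abort(paste0("No sites have data in at least ", min_years,
                 " distinct years; nothing retained."))
  }
  out
}

#' Per-site year coverage and dataset counts
#'
#' @param visits A `visit_table`.
#' @return A tibble with one row per site (`site`, `n_years`, `years`
#'   list-column of sorted years) carrying attributes `n_sites`, `n_visits`
#'   and `n_site_years`; see also [visit_counts()].
#' @export
site_year_index <- function(visits) {
  idx <- visits %>%
    group_by(.data$site) %>%
    summarise(years = list(sort(unique(.data$year))), .groups = "drop") %>%
    mutate(n_years = lengths(.data$years)) %>%
    select("site", "n_years", "years")
  attr(idx, "n_sites") <- nrow(idx)
  attr(idx, "n_visits") <- nrow(visits)
  attr(idx, "n_site_years") <- sum(idx$n_years)
  idx
}

#' Summary counts for a visit table
#'
#' Mirrors the record -> visit -> site -> site-year accounting used when
#' auditing opportunistic datasets.
#'
#' @param visits A `visit_table`.
#' @return A one-row tibble: `n_visits`, `n_sites`, `n_site_years`,
#'   `n_detections` (total species-visit detections, i.e. the number of
#'   records the visits represent).
#' @export
visit_counts <- function(visits) {
  tibble(
    n_visits = nrow(visits),
    n_sites = n_distinct(visits$site),
    n_site_years = nrow(distinct(as_tibble(visits)[c("site", "year")])),
    n_detections = sum(visits$list_length)
  )
}

#' Detection history of one species across visits
#'
#' @param visits A `visit_table`.
#' @param species Focal species identifier.
#' @return An integer vector along the rows of `visits`: 1 where the species
#'   is on the visit's list, 0 otherwise.
#' @export
detection_history <- function(visits, species) {
  as.integer(map_lgl(visits$species_list, ~ species %in% .x))
}
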