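test_that("parse_records applies the window, register and deduplication", {
  raw <- tibble::tibble(
    species = c("a", "a", "b"),
    date = c("1979-05-01", "1995-06-01", "1995-06-01"),
    site = "s1"
  )
  rs <- parse_records(raw, 1980, 2012)
  expect_equal(nrow(rs), 2)
  log <- ingest_log(rs)
  expect_equal(log$n[log$step == "dropped_outside_window"], 1)
  expect_s3_class(rs$date, "Date")

  # window boundaries are inclusive
  edge <- tibble::tibble(species = "a", site = "s",
                         date = c("1980-01-01", "2012-12-31"))
  expect_equal(nrow(parse_records(edge, 1980, 2012)), 2)

  # exact duplicates collapse to one row
  dup <- tibble::tibble(species = "speciesA", date = "2000-06-01",
                        site = "siteX")[c(1, 1), ]
  rs2 <- parse_records(dup, 1980, 2012)
  expect_equal(nrow(rs2), 1)
  expect_equal(ingest_log(rs2)$n[ingest_log(rs2)$step == "dropped_duplicate"], 1)

  # unknown species are dropped and counted when a register is given
  rs3 <- parse_records(
    tibble::tibble(species = c("a", "zz"), date = "2000-06-01", site = "s"),
    1980, 2012, species = "a")
  expect_equal(nrow(rs3), 1)
  expect_equal(ingest_log(rs3)$n[ingest_log(rs3)$step == "dropped_unknown_species"], 1)
})

test_that("parse_records rejects partial dates with a count, errors on garbage", {
  raw <- tibble::tibble(species = "a", site = "s",
                        date = c("1995-06", "1995", "1995-06-15"))
  rs <- parse_records(raw, 1980, 2012)
  expect_equal(nrow(rs), 1)
  expect_equal(ingest_log(rs)$n[ingest_log(rs)$step == "dropped_partial_date"], 2)

  bad <- tibble::tibble(species = "a", site = "s",
                        date = c("1995-06-15", "15/06/1995"))
  expect_error(parse_records(bad, 1980, 2012), "row")
  expect_error(parse_records(
    tibble::tibble(species = "a", site = "s", date = "1995-02-31"),
    1980, 2012), "Invalid calendar")
  # everything filtered away is a hard error
  expect_error(parse_records(
    tibble::tibble(species = "a", site = "s", date = "1970-01-01"),
    1980, 2012), "No records remain")
  expect_error(parse_records(
    tibble::tibble(species = "", site = "s", date = "1995-06-15"),
    1980, 2012), "Empty species")
})

test_that("parse_records matches a line-by-line filter oracle on 1,000 rows", {
  set.seed(101)
  n <- 1000
  raw <- tibble::tibble(
    species = sample(c(sprintf("sp%02d", 1:8), "unknown_sp"), n, replace = TRUE),
    date = sample(c(
      format(as.Date("1975-01-01") + sample.int(15000, 600, replace = TRUE)),
      rep("1990-07", 50),
      format(as.Date("1990-01-01") + sample.int(4000, 350, replace = TRUE))
    ), n, replace = TRUE),
    site = sample(sprintf("site%03d", 1:40), n, replace = TRUE)
  )
  register <- sprintf("sp%02d", 1:8)
  got <- parse_records(raw, 1980, 2012, species = register)
  want <- oracle_filter_records(raw, 1980, 2012, species = register)
  ord <- function(d) d[order(d$species, d$site, d$date), ]
  expect_equal(ord(as.data.frame(got))$species, ord(want)$species)
  expect_equal(ord(as.data.frame(got))$date, ord(want)$date)
  expect_equal(ord(as.data.frame(got))$site, ord(want)$site)
})

test_that("build_visits groups records into site-date visits with list length", {
  recs <- tibble::tibble(
    species = c("A", "B", "A"),
    date = as.Date(c("2001-06-01", "2001-06-01", "2001-06-02")),
    site = "s1"
  )
  v <- build_visits(recs)
  expect_equal(nrow(v), 2)
  v1 <- v[v$date == as.Date("2001-06-01"), ]
  expect_equal(v1$list_length, 2)
  expect_setequal(v1$species_list[[1]], c("A", "B"))
  expect_equal(v$list_length[v$date == as.Date("2001-06-02")], 1)
  expect_equal(unique(v$year), 2001L)
  expect_true(all(v$list_length == lengths(v$species_list)))

  single <- build_visits(recs[1, ])
  expect_equal(nrow(single), 1)
  expect_equal(single$list_length, 1)

  expect_equal(detection_history(v, "B"), c(1L, 0L))
})

test_that("build_visits equals brute-force grouping on simulated records", {
  sim <- simulate_records(
    n_species = 4, n_sites = 60, years = 2000:2009,
    psi_start = 0.5, psi_end = 0.5,
    effort = list(visits_per_site_year = 2, list_mean_start = 3,
                  list_mean_end = 5, n_background = 40),
    seed = 7)
  recs <- parse_records(sim$records, 2000, 2009)
  v <- build_visits(recs)
  want <- oracle_visits(recs)
  expect_equal(nrow(v), length(want))
  key <- paste(v$site, format(v$date, "%Y-%m-%d"), sep = "|")
  expect_setequal(key, names(want))
  for (i in seq_len(nrow(v))) {
    expect_identical(v$species_list[[i]], want[[key[i]]]$species)
  }
  # conservation of detections: per-species visit detections = distinct
  # (date, site) pairs in the record set
  for (s in sim$species) {
    n_pairs <- nrow(unique(recs[recs$species == s, c("date", "site")]))
    expect_equal(sum(detection_history(v, s)), n_pairs)
  }
  # list-length distribution is invariant to record row order
  perm <- recs[sample.int(nrow(recs)), ]
  v2 <- build_visits(perm)
  expect_equal(sort(v$list_length), sort(v2$list_length))
  expect_equal(nrow(v2), nrow(v))
})

test_that("filter_sites keeps sites with enough distinct years, idempotently", {
  recs <- tibble::tibble(
    species = "A",
    date = as.Date(c("1990-06-01", "1991-06-01",       # 2 years at s1
                     "1990-06-01", "1991-06-01", "1992-06-01")), # 3 at s2
    site = c("s1", "s1", "s2", "s2", "s2")
  )
  v <- build_visits(recs)
  kept <- filter_sites(v, min_years = 3)
  expect_setequal(unique(kept$site), "s2")
  # min_years = 1 keeps everything
  expect_equal(nrow(filter_sites(v, 1)), nrow(v))
  # removing every site is a hard error naming the threshold
  expect_error(filter_sites(v, 10), "10")
  # idempotence
  expect_identical(filter_sites(kept, 3), kept)
})

test_that("filter_sites equals an independent recount on a simulated table", {
  sim <- simulate_records(
    n_species = 3, n_sites = 200, years = 2000:2007,
    psi_start = 0.4, psi_end = 0.4,
    effort = list(visits_per_site_year = 0.8, list_mean_start = 2,
                  list_mean_end = 2, n_background = 25),
    seed = 21)
  v <- build_visits(parse_records(sim$records, 2000, 2007))
  got <- filter_sites(v, 3)
  want <- oracle_filter_sites(v, 3)
  expect_equal(got$visit_id, want$visit_id)
  expect_identical(filter_sites(got, 3), got)
})

test_that("site_year_index and visit_counts agree with direct recounts", {
  sim <- simulate_records(n_species = 2, n_sites = 30, years = 2000:2004,
                          seed = 3)
  v <- build_visits(parse_records(sim$records, 2000, 2004))
  idx <- site_year_index(v)
  expect_equal(attr(idx, "n_sites"), length(unique(v$site)))
  expect_equal(attr(idx, "n_visits"), nrow(v))
  expect_equal(attr(idx, "n_site_years"),
               nrow(unique(as.data.frame(v)[c("site", "year")])))
  cnt <- visit_counts(v)
  expect_equal(cnt$n_visits, nrow(v))
  expect_equal(cnt$n_detections, sum(lengths(v$species_list)))
})
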