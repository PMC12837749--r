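make_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("site_id,species,timestamp", lines), f)
  f
}

test_that("read_detections parses well-formed files and preserves order", {
  f <- make_csv(c("S1,elephant,2022-06-01 10:00",
                  "S2,sambar,2022-06-01 11:30",
                  "S1,elephant,2022-06-02 09:15"))
  rec <- read_detections(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$site_id, c("S1", "S2", "S1"))
  expect_s3_class(rec$timestamp, "POSIXct")
  expect_equal(format(rec$timestamp[2], "%H:%M"), "11:30")

  empty <- make_csv(character(0))
  expect_equal(nrow(read_detections(empty)), 0)
})

test_that("read_detections reports malformed rows with line numbers", {
  f <- make_csv(c("S1,elephant,2022-06-01 10:00",
                  "S1,elephant,2022-13-01 00:00",   # invalid month
                  "S1,elephant,2022-06-03 10:00"))
  expect_error(read_detections(f), "line 3")
  expect_warning(rec <- read_detections(f, skip_bad = TRUE), "line 3")
  expect_equal(nrow(rec), 2)

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,when", "S1,2022-06-01 10:00"), g)
  expect_error(read_detections(g), "missing required column")
  expect_error(read_detections("no/such/file.csv"), "not found")
})

test_that("species names are canonicalised by trimming and case folding", {
  f <- make_csv(c("S1, Sus Scrofa ,2022-06-01 10:00",
                  "S1,sus scrofa,2022-06-01 12:00"))
  rec <- read_detections(f)
  expect_equal(unique(rec$species), "sus scrofa")
})

test_that("the 30-min rule merges records within the event-start window", {
  ts <- as.POSIXct(c("2022-06-01 00:00", "2022-06-01 00:10",
                     "2022-06-01 00:40"), tz = "UTC")
  rec <- data.frame(site_id = "S1", species = "elephant", timestamp = ts)
  ev <- filter_independent(rec)
  expect_equal(nrow(ev), 2)
  expect_equal(format(ev$event_start, "%H:%M"), c("00:00", "00:40"))
  expect_equal(ev$n_records, c(2L, 1L))

  # same times, two species: groups are independent
  rec2 <- rec
  rec2$species <- c("elephant", "sambar", "elephant")
  expect_equal(nrow(filter_independent(rec2)), 3)

  # single record
  ev1 <- filter_independent(rec[1, ])
  expect_equal(ev1$n_records, 1L)

  # half-open window: exactly 30 min after the event start opens a new event
  rec3 <- data.frame(site_id = "S1", species = "elephant",
                     timestamp = ts[1] + c(0, 29, 30) * 60)
  expect_equal(nrow(filter_independent(rec3)), 2)
})

test_that("independence filtering matches a brute-force scan and is idempotent", {
  set.seed(42)
  for (i in 1:25) {
    rec <- random_records(sample(1:20, 1))
    ev <- filter_independent(rec)
    oracle <- brute_force_events(rec)
    expect_equal(ev$event_start, oracle$event_start)
    expect_equal(ev$n_records, oracle$n_records)
    # conservation
    expect_equal(sum(ev$n_records), nrow(rec))
    # idempotence: event starts re-filtered reproduce the same events
    again <- filter_independent(data.frame(site_id = ev$site_id,
                                           species = ev$species,
                                           timestamp = ev$event_start))
    expect_equal(again$event_start, ev$event_start)
  }
})

test_that("widening the window never increases the number of events", {
  set.seed(7)
  for (i in 1:10) {
    rec <- random_records(40)
    n_ev <- vapply(c(5, 15, 30, 60, 120),
                   function(w) nrow(filter_independent(rec, w)), numeric(1))
    expect_true(all(diff(n_ev) <= 0))
  }
})

test_that("build_matrix tabulates events with deterministic ordering", {
  ev <- data.frame(site_id = c("X", "X", "Y"),
                   species = c("a", "a", "b"),
                   stringsAsFactors = FALSE)
  m <- build_matrix(ev)
  expect_equal(unname(m$counts), matrix(c(2L, 0L, 0L, 1L), 2))
  expect_equal(rownames(m$counts), c("X", "Y"))
  expect_identical(m$presence, m$counts > 0)
  expect_error(build_matrix(ev[0, ]), "no detection events")

  set.seed(1)
  ev2 <- random_records(100)[, c("site_id", "species")]
  m2 <- build_matrix(ev2)
  expect_equal(as.vector(colSums(m2$counts)),
               as.vector(table(ev2$species)[colnames(m2$counts)]))
  expect_equal(sum(m2$counts), nrow(ev2))
})

test_that("matrix occupancy matches the reference community occupancies", {
  # synthesise one event per (species, site) according to the published
  # per-species occupancies, then check the presence column sums
  tab <- community_table()
  ev <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(site_id = sprintf("S%02d", seq_len(tab$occupancy[i])),
               species = tab$species[i], stringsAsFactors = FALSE)
  }))
  m <- build_matrix(ev, sites = sprintf("S%02d", 1:67))
  occ <- colSums(m$presence)
  expect_equal(unname(occ["Rusa unicolor"]), 61)
  expect_equal(unname(occ["Elephas maximus"]), 50)
  expect_equal(unname(occ[tab$species]), tab$occupancy)
})

test_that("events and matrix round-trip through their CSV writers", {
  set.seed(3)
  rec <- random_records(30)
  ev <- filter_independent(rec)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(ev))
  m <- build_matrix(ev)
  g <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, g)
  back2 <- utils::read.csv(g, check.names = FALSE)
  expect_equal(as.matrix(back2[, -1]),
               matrix(as.numeric(m$counts), nrow(m$counts),
                      dimnames = list(NULL, colnames(m$counts))))
})
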