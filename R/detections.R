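#' Read raw camera-trap detection records
#'
#' Parses a CSV of raw captures with columns `site_id`, `species` and
#' `timestamp` (ISO 8601, `"YYYY-MM-DD HH:MM"`, seconds optional). An optional
#' `media_id` column is carried through untouched. Species names are trimmed
#' and case-folded so that `" Sus Scrofa "` and `"sus scrofa"` refer to the
#' same species; no taxonomic resolution is attempted.
#'
#' @param path Path to the detections CSV.
#' @param skip_bad If `TRUE`, rows with unparseable timestamps or empty
#'   site/species fields are dropped with a warning naming the offending line
#'   numbers; if `FALSE` (default) such rows abort the run.
#' @return A data frame of detection records (`site_id`, `species`,
#'   `timestamp` as `POSIXct`, plus `media_id` when present), in file order.
#' @export
read_detections <- function(path, skip_bad = FALSE) {
  if (!file.exists(path)) {
    stop("detections file not found: ", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("site_id", "species", "timestamp")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("detections CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(data.frame(site_id = character(), species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE))
  }
  ts <- parse_timestamp(raw$timestamp)
  site <- trimws(raw$site_id)
  sp <- canonical_species(raw$species)
  bad <- which(is.na(ts) | site == "" | sp == "")
  if (length(bad) > 0) {
    # +1 for the header line so numbers match the file as the user sees it
    msg <- paste0("malformed detection row(s) at line ",
                  paste(bad + 1L, collapse = ", "))
    if (!skip_bad) stop(msg, " (use skip_bad = TRUE to drop them)")
    warning(msg, " - dropped")
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  out <- data.frame(site_id = site[keep], species = sp[keep],
                    timestamp = ts[keep], stringsAsFactors = FALSE)
  if ("media_id" %in% names(raw)) out$media_id <- raw$media_id[keep]
  out
}

# Naive local clock time, stored as UTC so no DST arithmetic can intervene.
parse_timestamp <- function(x) {
  x <- trimws(x)
  ts <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  short <- is.na(ts)
  ts[short] <- as.POSIXct(x[short], tz = "UTC", format = "%Y-%m-%d %H:%M")
  ts
}

canonical_species <- function(x) tolower(trimws(x))

#' Collapse raw detections into independent detection events
#'
#' Within each (site, species) group, the first record opens an event; each
#' later record opens a new event if and only if it falls at or beyond
#' `window_minutes` after the *start* of the current event, otherwise it is
#' merged into that event. The window is half-open: a record exactly
#' `window_minutes` after the event start opens a new event.
#'
#' @param records Data frame as returned by [read_detections()].
#' @param window_minutes Independence window in minutes (default 30).
#' @return A data frame of events with columns `site_id`, `species`,
#'   `event_start` (`POSIXct` of the initial photograph) and `n_records`
#'   (raw records merged into the event), sorted by site, species, time.
#' @export
filter_independent <- function(records, window_minutes = 30) {
  stopifnot(is.numeric(window_minutes), length(window_minutes) == 1,
            window_minutes > 0)
  cols <- c("site_id", "species", "timestamp")
  if (!all(cols %in% names(records))) {
    stop("records must have columns site_id, species, timestamp")
  }
  if (nrow(records) == 0) {
    return(data.frame(site_id = character(), species = character(),
                      event_start = as.POSIXct(character(), tz = "UTC"),
                      n_records = integer(), stringsAsFactors = FALSE))
  }
  if (any(is.na(records$timestamp))) stop("records contain NA timestamps")
  ord <- order(records$site_id, records$species, records$timestamp)
  rec <- records[ord, cols]
  key <- paste(rec$site_id, rec$species, sep = "\r")
  win <- window_minutes * 60
  out <- lapply(split(seq_len(nrow(rec)), key), function(idx) {
    t <- as.numeric(rec$timestamp[idx])
    starts <- integer(0)
    n_rec <- integer(0)
    cur_start <- -Inf
    for (i in seq_along(t)) {
      if (t[i] - cur_start >= win) {
        cur_start <- t[i]
        starts <- c(starts, idx[i])
        n_rec <- c(n_rec, 1L)
      } else {
        n_rec[length(n_rec)] <- n_rec[length(n_rec)] + 1L
      }
    }
    data.frame(site_id = rec$site_id[starts], species = rec$species[starts],
               event_start = rec$timestamp[starts], n_records = n_rec,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$site_id, out$species, out$event_start), , drop = FALSE]
}

#' Build a site-by-species matrix of independent event counts
#'
#' @param events Data frame of events from [filter_independent()] (or any data
#'   frame with `site_id` and `species` columns, one row per event).
#' @param sites,species Optional character vectors fixing the site/species
#'   universe and order (useful when some sites detected nothing); defaults to
#'   the lexicographically sorted values present in `events`.
#' @return An object of class `site_species_matrix`: a list with `counts`
#'   (sites x species integer matrix) and `presence` (`counts > 0`).
#' @export
build_matrix <- function(events, sites = NULL, species = NULL) {
  if (nrow(events) == 0) {
    stop("no detection events: cannot build a site-by-species matrix ",
         "(check the independence filter input)")
  }
  if (is.null(sites)) sites <- sort(unique(events$site_id))
  if (is.null(species)) species <- sort(unique(events$species))
  if (anyDuplicated(sites) || anyDuplicated(species)) {
    stop("site and species labels must be unique")
  }
  extra_s <- setdiff(unique(events$site_id), sites)
  extra_p <- setdiff(unique(events$species), species)
  if (length(extra_s) || length(extra_p)) {
    stop("events contain labels outside the supplied universe: ",
         paste(c(extra_s, extra_p), collapse = ", "))
  }
  counts <- table(factor(events$site_id, levels = sites),
                  factor(events$species, levels = species))
  counts <- matrix(as.integer(counts), nrow = length(sites),
                   dimnames = list(site = sites, species = species))
  structure(list(counts = counts, presence = counts > 0),
            class = "site_species_matrix")
}

#' @export
print.site_species_matrix <- function(x, ...) {
  cat("site_species_matrix:", nrow(x$counts), "sites x",
      ncol(x$counts), "species,", sum(x$counts), "independent events\n")
  invisible(x)
}

#' Per-site species richness of a presence matrix
#' @param m A `site_species_matrix` or logical matrix.
#' @return Integer vector, one entry per site.
#' @export
site_richness <- function(m) {
  p <- if (inherits(m, "site_species_matrix")) m$presence else m
  rowSums(p)
}

#' Write events and matrix outputs
#'
#' @param events Events data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events
  out$event_start <- format(out$event_start, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param m A `site_species_matrix`.
#' @export
write_matrix <- function(m, path) {
  utils::write.csv(data.frame(site_id = rownames(m$counts), m$counts,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
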