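#' Specify a synthetic camera-trap community
#'
#' Defines the generating model for a simulated deployment: `n_sites` cameras
#' run for `n_days`; each species has an occupancy probability `psi`, a mean
#' number of independent events per occupied site `mu` with negative-binomial
#' overdispersion `k`, and a diel activity profile given as a von Mises
#' mixture (weights, mean hour, concentration). Pairwise presence
#' associations are specified as *target phi coefficients*; the generator
#' calibrates the latent Gaussian copula correlation so the realised phi of
#' the thresholded presences converges to the target as the number of sites
#' grows.
#'
#' @param n_sites Number of camera sites.
#' @param species Data frame with columns `name`, `psi` (occupancy in
#'   `(0, 1]`), `mu` (> 0), `k` (> 0).
#' @param activity Named list (by species) of mixture components; each a
#'   data frame / list with `weight`, `mean_h` (hour of day) and `kappa`.
#'   Species without an entry are cathemeral (uniform).
#' @param associations Data frame with columns `a`, `b`, `phi` giving target
#'   pairwise phi values; unlisted pairs are independent.
#' @param start_date First day of the study window (`"YYYY-MM-DD"`).
#' @param n_days Study length in days.
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(n_sites, species, activity = list(),
                           associations = NULL,
                           start_date = "2022-06-01", n_days = 365) {
  stopifnot(n_sites >= 2, n_days >= 1)
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  req <- c("name", "psi", "mu", "k")
  if (!all(req %in% names(species))) {
    stop("species table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(species$name)) stop("duplicate species names")
  if (any(species$psi <= 0 | species$psi > 1)) stop("psi must be in (0, 1]")
  if (any(species$mu <= 0) || any(species$k <= 0)) stop("mu and k must be > 0")
  for (nm in names(activity)) {
    comp <- as.data.frame(activity[[nm]])
    if (abs(sum(comp$weight) - 1) > 1e-8) {
      stop("activity mixture weights for ", nm, " must sum to 1")
    }
    activity[[nm]] <- comp
  }
  if (!is.null(associations)) {
    associations <- as.data.frame(associations, stringsAsFactors = FALSE)
    bad <- setdiff(c(associations$a, associations$b), species$name)
    if (length(bad)) stop("association targets name unknown species: ",
                          paste(bad, collapse = ", "))
    if (any(abs(associations$phi) >= 1)) stop("target phi must be in (-1, 1)")
  }
  structure(list(n_sites = as.integer(n_sites), species = species,
                 activity = activity, associations = associations,
                 start_date = start_date, n_days = as.integer(n_days)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("community_spec: %d sites x %d species, %d days from %s, %d association target(s)\n",
              x$n_sites, nrow(x$species), x$n_days, x$start_date,
              if (is.null(x$associations)) 0L else nrow(x$associations)))
  invisible(x)
}

#' Load a shipped community preset
#'
#' Presets live as YAML under `inst/extdata/presets/`: `paper_like` (67
#' sites, 12 species spanning occupancy 0.05-0.9, one strong positive pair,
#' one asymmetric commensal pair, a bimodal crepuscular focal species),
#' `null_community` (11 fully independent species at psi = 0.5, the
#' calibration baseline) and `strong_pairs` (200 sites with one positive and
#' one negative planted pair).
#'
#' @param name Preset name or a path to a YAML spec.
#' @return A `community_spec`.
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "camassoc")
  if (path == "" || !file.exists(path)) stop("unknown preset: ", name)
  y <- yaml::read_yaml(path)
  species <- do.call(rbind, lapply(y$species, function(s) {
    data.frame(name = s$name, psi = s$psi, mu = s$mu, k = s$k,
               stringsAsFactors = FALSE)
  }))
  activity <- list()
  for (s in y$species) {
    if (!is.null(s$activity)) {
      activity[[s$name]] <- do.call(rbind, lapply(s$activity, as.data.frame))
    }
  }
  associations <- if (!is.null(y$associations)) {
    do.call(rbind, lapply(y$associations, as.data.frame))
  }
  community_spec(y$n_sites, species, activity, associations,
                 start_date = y$start_date, n_days = y$n_days)
}

# P(Z1 > qnorm(1-psi1), Z2 > qnorm(1-psi2)) under latent correlation rho
joint_exceed <- function(rho, psi1, psi2) {
  a <- stats::qnorm(1 - psi1)
  b <- stats::qnorm(1 - psi2)
  if (abs(rho) < 1e-12) return(psi1 * psi2)
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((b - rho * z) / s, lower.tail = FALSE)
  }, a, Inf, rel.tol = 1e-10)$value
}

#' Latent Gaussian correlation achieving a target presence phi
#'
#' Inverts the tetrachoric relation: given marginal occupancies and a target
#' phi for the thresholded Bernoulli pair, solves for the latent normal
#' correlation by root finding on the joint exceedance probability.
#'
#' @param phi Target phi coefficient.
#' @param psi1,psi2 Occupancy probabilities of the two species.
#' @return Latent correlation in `(-1, 1)`.
#' @export
phi_to_latent <- function(phi, psi1, psi2) {
  if (phi == 0) return(0)
  sd12 <- sqrt(psi1 * (1 - psi1) * psi2 * (1 - psi2))
  if (sd12 == 0) stop("degenerate margins: target phi unreachable")
  p11 <- phi * sd12 + psi1 * psi2
  lo <- max(0, psi1 + psi2 - 1)
  hi <- min(psi1, psi2)
  if (p11 <= lo || p11 >= hi) {
    stop(sprintf("target phi = %.3f infeasible for occupancies %.2f / %.2f",
                 phi, psi1, psi2))
  }
  stats::uniroot(function(rho) joint_exceed(rho, psi1, psi2) - p11,
                 lower = -0.9999, upper = 0.9999, tol = 1e-9)$root
}

latent_correlation <- function(spec) {
  sp <- spec$species$name
  S <- length(sp)
  R <- diag(1, S)
  dimnames(R) <- list(sp, sp)
  if (!is.null(spec$associations)) {
    for (i in seq_len(nrow(spec$associations))) {
      row <- spec$associations[i, ]
      rho <- phi_to_latent(row$phi, spec$species$psi[sp == row$a],
                           spec$species$psi[sp == row$b])
      R[row$a, row$b] <- R[row$b, row$a] <- rho
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("association targets jointly infeasible; applying nearest-PSD repair")
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("correlation matrix not PSD after repair")
  }
  R
}

#' Simulate correlated presence/absence across sites
#'
#' Draws one latent multivariate normal vector per site with the calibrated
#' correlation matrix and thresholds component i at `qnorm(1 - psi_i)`, so
#' column means converge to the occupancies and pairwise phi to the targets.
#'
#' @param spec A `community_spec`.
#' @param seed Integer RNG seed.
#' @return Logical `n_sites` x S matrix with site/species dimnames.
#' @export
simulate_presence <- function(spec, seed = 1) {
  R <- latent_correlation(spec)
  S <- nrow(spec$species)
  r <- spec$n_sites
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  # jitter the diagonal if chol still objects to a numerically semi-definite R
  U <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-8, S)))
  Z <- matrix(stats::rnorm(r * S), nrow = r) %*% U
  thr <- stats::qnorm(1 - spec$species$psi)
  pres <- sweep(Z, 2, thr, ">")
  dimnames(pres) <- list(site_labels(r), spec$species$name)
  pres
}

site_labels <- function(r) sprintf(paste0("S%0", nchar(r), "d"), seq_len(r))

sample_mixture <- function(n, comps) {
  if (is.null(comps) || n == 0) return(stats::runif(n, 0, 2 * pi))
  idx <- sample.int(nrow(comps), n, replace = TRUE, prob = comps$weight)
  vapply(idx, function(i) {
    rvonmises(1, comps$mean_h[i] / 24 * 2 * pi, comps$kappa[i])
  }, numeric(1))
}

# zero-truncated negative binomial draw (occupied sites have >= 1 event)
rztnbinom <- function(n, mu, size) {
  p0 <- stats::pnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, p0, 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' Simulate raw detection records from a presence matrix
#'
#' Per occupied (site, species) cell the number of independent events is
#' zero-truncated negative binomial(`mu`, `k`). Each event gets a calendar
#' day uniform over the study window and a time of day from the species'
#' von Mises mixture, rounded to the minute. Event starts within a cell are
#' forced at least 30 minutes apart (later events are pushed forward when
#' needed) so the independence filter recovers the planted events exactly.
#' Each event then contributes `1 + Poisson(0.7)` raw records, the extras at
#' 1-29 minutes after the event start.
#'
#' @param presence Logical matrix from [simulate_presence()].
#' @param spec The `community_spec` used to generate it.
#' @param seed Integer RNG seed.
#' @return Data frame of detection records (`site_id`, `species`,
#'   `timestamp`), sorted by site, species, time.
#' @export
simulate_detections <- function(presence, spec, seed = 1) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  t0 <- as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC")
  rows <- list()
  for (i in seq_len(ncol(presence))) {
    sp <- colnames(presence)[i]
    occ <- which(presence[, i])
    if (length(occ) == 0) next
    mu <- spec$species$mu[spec$species$name == sp]
    k <- spec$species$k[spec$species$name == sp]
    counts <- rztnbinom(length(occ), mu, k)
    comps <- spec$activity[[sp]]
    for (jj in seq_along(occ)) {
      cnt <- counts[jj]
      day <- sample.int(spec$n_days, cnt, replace = TRUE) - 1L
      theta <- sample_mixture(cnt, comps)
      minute <- floor(theta / (2 * pi) * 1440)
      ev <- sort(day * 1440 + minute)
      if (cnt > 1) {
        for (e in 2:cnt) {
          if (ev[e] < ev[e - 1] + 30) ev[e] <- ev[e - 1] + 30
        }
      }
      n_extra <- stats::rpois(cnt, 0.7)
      offs <- lapply(n_extra, function(m) {
        if (m == 0) integer(0) else sort(sample.int(29, m, replace = TRUE))
      })
      all_min <- unlist(mapply(function(start, o) c(start, start + o), ev,
                               offs, SIMPLIFY = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        site_id = rownames(presence)[occ[jj]], species = sp,
        timestamp = t0 + all_min * 60, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(site_id = character(), species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$site_id, out$species, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-call community simulation
#' @inheritParams simulate_detections
#' @param spec A `community_spec` or preset name.
#' @param seed Integer RNG seed (presence uses `seed`, detections
#'   `seed + 1`).
#' @return List `presence`, `records`.
#' @export
simulate_community <- function(spec, seed = 1) {
  if (is.character(spec)) spec <- load_preset(spec)
  pres <- simulate_presence(spec, seed = seed)
  rec <- simulate_detections(pres, spec, seed = seed + 1L)
  list(presence = pres, records = rec, spec = spec, seed = seed)
}

#' Write a simulated dataset as a detections fixture
#'
#' Produces a CSV schema-identical to [read_detections()] input plus a JSON
#' sidecar recording the generating spec and seed. Same seed, same bytes.
#'
#' @param records Records from [simulate_detections()].
#' @param path Output CSV path (sidecar gets `.meta.json` appended).
#' @param spec,seed Provenance recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(records, path, spec = NULL, seed = NULL) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(generator = "camassoc::simulate_detections", seed = seed,
               n_records = nrow(records))
  if (!is.null(spec)) {
    meta$spec <- list(n_sites = spec$n_sites, n_days = spec$n_days,
                      start_date = spec$start_date,
                      species = spec$species,
                      associations = spec$associations)
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
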