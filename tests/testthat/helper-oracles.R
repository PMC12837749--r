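# Independent reference implementations used to cross-check the package.

# Literal scan of the independence rule: walk each (site, species) group in
# time order, opening a new event whenever >= `window` minutes have elapsed
# since the current event's first record.
brute_force_events <- function(records, window = 30) {
  out <- list()
  for (s in unique(records$site_id)) {
    for (sp in unique(records$species)) {
      grp <- records[records$site_id == s & records$species == sp, ]
      if (nrow(grp) == 0) next
      grp <- grp[order(grp$timestamp), ]
      start <- NULL
      n <- 0
      for (i in seq_len(nrow(grp))) {
        t <- grp$timestamp[i]
        if (is.null(start) ||
            as.numeric(difftime(t, start, units = "mins")) >= window) {
          if (!is.null(start)) {
            out[[length(out) + 1]] <- data.frame(site_id = s, species = sp,
                                                 event_start = start,
                                                 n_records = n)
          }
          start <- t
          n <- 1
        } else {
          n <- n + 1
        }
      }
      out[[length(out) + 1]] <- data.frame(site_id = s, species = sp,
                                           event_start = start, n_records = n)
    }
  }
  out <- do.call(rbind, out)
  out[order(out$site_id, out$species, out$event_start), ]
}

# random detection records over a handful of sites/species
random_records <- function(n, n_sites = 2, n_species = 2, span_h = 6) {
  data.frame(
    site_id = sample(paste0("X", seq_len(n_sites)), n, replace = TRUE),
    species = sample(letters[seq_len(n_species)], n, replace = TRUE),
    timestamp = as.POSIXct("2022-06-01", tz = "UTC") +
      60 * sample.int(span_h * 60, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# random 2x2 table with all margins positive
random_table <- function(n_max = 80) {
  repeat {
    cells <- as.vector(stats::rmultinom(1, sample(20:n_max, 1),
                                        prob = stats::runif(4, 0.05, 1)))
    t <- list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
              n = sum(cells))
    if (all(c(t$a + t$b, t$a + t$c, t$b + t$d, t$c + t$d) > 0)) return(t)
  }
}

# rebuild the two presence vectors a 2x2 table came from
table_to_vectors <- function(t) {
  x <- rep(c(1, 1, 0, 0), times = c(t$a, t$b, t$c, t$d))
  y <- rep(c(1, 0, 1, 0), times = c(t$a, t$b, t$c, t$d))
  list(x = x, y = y)
}

# two-pass literal transcription of Schluter's variance ratio
literal_vr <- function(pres) {
  pres <- pres * 1
  N <- nrow(pres)
  pi <- numeric(ncol(pres))
  for (i in seq_len(ncol(pres))) pi[i] <- sum(pres[, i]) / N
  Tj <- numeric(N)
  for (j in seq_len(N)) Tj[j] <- sum(pres[j, ])
  t_bar <- sum(Tj) / N
  num <- 0
  for (j in seq_len(N)) num <- num + (Tj[j] - t_bar)^2
  num <- num / N
  den <- 0
  for (i in seq_len(ncol(pres))) den <- den + pi[i] * (1 - pi[i])
  num / den
}

# proportional-reduction-in-error lambda by explicit modal prediction
brute_force_lambda <- function(t, direction = "ab") {
  v <- table_to_vectors(t)
  pred_from <- if (direction == "ab") v$x else v$y
  target <- if (direction == "ab") v$y else v$x
  modal_err <- function(y) length(y) - max(table(factor(y, levels = 0:1)))
  e1 <- modal_err(target)
  e2 <- sum(vapply(split(target, pred_from), modal_err, numeric(1)))
  if (e1 == 0) return(NA_real_)
  (e1 - e2) / e1
}

# true overlap of two von Mises densities by fine quadrature
true_vm_overlap <- function(mu1, k1, mu2, k2, n_grid = 4096) {
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[1:n_grid]
  f1 <- exp(k1 * cos(grid - mu1)) / (2 * pi * besselI(k1, 0))
  f2 <- exp(k2 * cos(grid - mu2)) / (2 * pi * besselI(k2, 0))
  mean(pmin(f1, f2)) * 2 * pi
}

# minimal two-species community spec for association recovery checks
two_species_spec <- function(n_sites, phi, psi1 = 0.5, psi2 = 0.5) {
  community_spec(
    n_sites = n_sites,
    species = data.frame(name = c("A", "B"), psi = c(psi1, psi2),
                         mu = c(2, 2), k = c(1, 1)),
    associations = if (phi != 0) data.frame(a = "A", b = "B", phi = phi))
}
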