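#' Relative abundance index and the mean-threshold screen
#'
#' RAI_i = 100 * n_i / sum(n), the percentage of the community's independent
#' detections contributed by species i. A species is `selected` when its RAI
#' strictly exceeds the community mean (which is always `100 / S`); ties at
#' the mean are not selected.
#'
#' @param event_counts Named numeric vector of independent event counts per
#'   species, or a `site_species_matrix` (column sums are used).
#' @return Data frame with `species`, `n_events`, `rai`, `occupancy` (sites
#'   detected, `NA` when counts alone were supplied) and `selected`.
#' @export
rai <- function(event_counts) {
  occupancy <- NULL
  if (inherits(event_counts, "site_species_matrix")) {
    occupancy <- colSums(event_counts$presence)
    event_counts <- colSums(event_counts$counts)
  }
  if (is.null(names(event_counts))) {
    names(event_counts) <- paste0("sp", seq_along(event_counts))
  }
  if (any(event_counts < 0)) stop("event counts must be non-negative")
  total <- sum(event_counts)
  if (total <= 0) stop("all event counts are zero: RAI undefined")
  r <- 100 * event_counts / total
  mean_rai <- 100 / length(event_counts)
  data.frame(species = names(event_counts),
             n_events = as.vector(event_counts),
             rai = as.vector(r),
             occupancy = if (is.null(occupancy)) NA_integer_ else
               as.integer(occupancy),
             selected = as.vector(r > mean_rai),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Site-usage distribution of one species
#'
#' P_ij, the share of species i's independent events occurring at site j.
#'
#' @param counts Non-negative numeric vector of per-site event counts.
#' @return Numeric vector summing to 1, or an error for a zero-event species.
#' @export
usage_distribution <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("species has no events: usage distribution undefined")
  counts / total
}

#' Levins distributional breadth
#'
#' `B_L = 1 / sum(P_ij^2)`, the inverse Simpson concentration of a species'
#' site usage. Ranges from 1 (all events at one site) to `r` (perfectly even
#' use of all `r` sites).
#'
#' @param p Usage distribution (any non-negative vector; normalised
#'   internally).
#' @return Scalar breadth.
#' @export
levins_breadth <- function(p) {
  p <- usage_distribution(p)
  1 / sum(p^2)
}

#' Shannon distributional breadth
#'
#' `B_S = -sum(P_ij * log(P_ij))` with `0 * log(0) = 0`. Ranges from 0
#' (single site) to `log(r)` (uniform use).
#'
#' @inheritParams levins_breadth
#' @return Scalar breadth (natural log).
#' @export
shannon_breadth <- function(p) {
  p <- usage_distribution(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pianka spatial co-occurrence index for a species pair
#'
#' `O_ik = sum(P_ij P_kj) / sqrt(sum(P_ij^2) sum(P_kj^2))` - the cosine
#' similarity of the two site-usage vectors, so raw counts may be supplied;
#' rescaling either vector leaves the index unchanged. 0 means disjoint site
#' sets, 1 identical usage.
#'
#' @param u_i,u_k Usage distributions or raw count vectors over the same
#'   ordered site list.
#' @return Scalar in `[0, 1]`.
#' @export
pianka_overlap <- function(u_i, u_k) {
  if (length(u_i) != length(u_k)) stop("usage vectors differ in length")
  if (sum(u_i) <= 0 || sum(u_k) <= 0) {
    stop("species with zero events: overlap undefined")
  }
  sum(u_i * u_k) / sqrt(sum(u_i^2) * sum(u_k^2))
}

#' Breadth table and Pianka overlap matrix for a community
#'
#' @param m A `site_species_matrix`.
#' @return `niche_breadth()`: data frame `species`, `b_levins`, `b_shannon`.
#' @export
niche_breadth <- function(m) {
  counts <- m$counts
  data.frame(species = colnames(counts),
             b_levins = apply(counts, 2, levins_breadth),
             b_shannon = apply(counts, 2, shannon_breadth),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname niche_breadth
#' @return `pianka_matrix()`: symmetric S x S matrix with unit diagonal.
#' @export
pianka_matrix <- function(m) {
  counts <- m$counts
  S <- ncol(counts)
  O <- diag(1, S)
  dimnames(O) <- list(colnames(counts), colnames(counts))
  if (S < 2) return(O)
  for (i in seq_len(S - 1)) {
    for (k in (i + 1):S) {
      O[i, k] <- O[k, i] <- pianka_overlap(counts[, i], counts[, k])
    }
  }
  O
}

#' Long-format overlap pairs (for heatmap-style output)
#' @param O Symmetric overlap matrix from [pianka_matrix()].
#' @return Data frame `species_a`, `species_b`, `overlap` (upper triangle).
#' @export
overlap_pairs <- function(O) {
  idx <- which(upper.tri(O), arr.ind = TRUE)
  data.frame(species_a = rownames(O)[idx[, 1]],
             species_b = colnames(O)[idx[, 2]],
             overlap = O[idx], stringsAsFactors = FALSE)
}
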