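#' 2 x 2 presence contingency table for a species pair
#'
#' Cells follow the classical linked-distribution layout: `a` sites with both
#' species, `b` only the first, `c` only the second, `d` neither;
#' `a + b + c + d` equals the number of sites.
#'
#' @param presence_i,presence_k Logical site vectors of equal length.
#' @return Named list `a`, `b`, `c`, `d`, `n`.
#' @export
contingency <- function(presence_i, presence_k) {
  if (length(presence_i) != length(presence_k)) {
    stop("presence vectors differ in length")
  }
  presence_i <- as.logical(presence_i)
  presence_k <- as.logical(presence_k)
  # doubles, not integers: cell products in phi/chi-square overflow 32-bit
  # integers for site counts in the thousands
  list(a = as.numeric(sum(presence_i & presence_k)),
       b = as.numeric(sum(presence_i & !presence_k)),
       c = as.numeric(sum(!presence_i & presence_k)),
       d = as.numeric(sum(!presence_i & !presence_k)),
       n = as.numeric(length(presence_i)))
}

margins_positive <- function(t) {
  all(c(t$a + t$b, t$a + t$c, t$b + t$d, t$c + t$d) > 0)
}

#' Phi association coefficient of a 2 x 2 table
#'
#' `phi = (ad - bc) / sqrt((a+b)(a+c)(b+d)(c+d))`, in `[-1, 1]`; 0 means the
#' two species occur independently, the sign gives the association direction.
#' Undefined (returns `NA`) when any margin is zero, i.e. when either species
#' is present at all sites or at none.
#'
#' @param t Contingency table from [contingency()].
#' @return Scalar phi, or `NA_real_` with a warning for a zero margin.
#' @export
phi_coef <- function(t) {
  if (!margins_positive(t)) {
    warning("zero margin: phi undefined for this pair")
    return(NA_real_)
  }
  (t$a * t$d - t$b * t$c) /
    sqrt((t$a + t$b) * (t$a + t$c) * (t$b + t$d) * (t$c + t$d))
}

#' Yates continuity-corrected chi-square of a 2 x 2 table
#'
#' `n * (max(|ad - bc| - n/2, 0))^2 / ((a+b)(a+c)(b+d)(c+d))`. The numerator
#' is clamped at zero when `|ad - bc| <= n/2`, matching standard continuity
#' correction semantics (the statistic cannot grow for near-null tables).
#'
#' @inheritParams phi_coef
#' @return Scalar chi-square, or `NA_real_` for a zero margin.
#' @export
yates_chi2 <- function(t) {
  if (!margins_positive(t)) {
    warning("zero margin: chi-square undefined for this pair")
    return(NA_real_)
  }
  num <- max(abs(t$a * t$d - t$b * t$c) - t$n / 2, 0)
  t$n * num^2 / ((t$a + t$b) * (t$a + t$c) * (t$b + t$d) * (t$c + t$d))
}

#' Significance class of a pairwise chi-square
#'
#' Classes follow the df = 1 critical values: below 3.841 no significant
#' association (p > 0.05), between 3.841 and 6.635 significant
#' (0.01 < p < 0.05), above 6.635 highly significant (p < 0.01). Values
#' exactly at a threshold fall in the lower class.
#'
#' @param chi2 Non-negative chi-square value(s).
#' @return Character vector: `"none"`, `"significant"` or
#'   `"highly_significant"` (`NA` propagates).
#' @export
classify_association <- function(chi2) {
  cls <- ifelse(chi2 > 6.635, "highly_significant",
                ifelse(chi2 > 3.841, "significant", "none"))
  cls[is.na(chi2)] <- NA_character_
  cls
}

#' Pairwise Phi / chi-square association table for a community
#'
#' Runs [contingency()], [phi_coef()] and [yates_chi2()] over every unordered
#' species pair; the association sign is taken from `ad - bc`.
#'
#' @param m A `site_species_matrix`.
#' @param species Optional subset of species to analyse (default all).
#' @return Data frame with one row per pair: the four cells, `phi`, `chi2`,
#'   `sign` (`positive` / `negative` / `independent`) and `class`.
#' @export
pair_associations <- function(m, species = NULL) {
  pres <- m$presence
  if (!is.null(species)) {
    missing <- setdiff(species, colnames(pres))
    if (length(missing)) stop("unknown species: ", paste(missing, collapse = ", "))
    pres <- pres[, species, drop = FALSE]
  }
  sp <- colnames(pres)
  S <- length(sp)
  if (S < 2) stop("need at least two species for pairwise association")
  pairs <- utils::combn(S, 2)
  rows <- apply(pairs, 2, function(ik) {
    t <- contingency(pres[, ik[1]], pres[, ik[2]])
    det <- t$a * t$d - t$b * t$c
    phi <- suppressWarnings(phi_coef(t))
    chi2 <- suppressWarnings(yates_chi2(t))
    data.frame(species_a = sp[ik[1]], species_b = sp[ik[2]],
               a = t$a, b = t$b, c = t$c, d = t$d,
               phi = phi, chi2 = chi2,
               sign = if (det > 0) "positive" else if (det < 0) "negative"
                      else "independent",
               class = classify_association(chi2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Community-wide variance-ratio association test
#'
#' Schluter's variance ratio: with `T_j` the species richness at site j and
#' `p_i = n_i / N` the fraction of the `N` sites occupied by species i,
#' `VR = [(1/N) sum_j (T_j - mean(T))^2] / [sum_i p_i (1 - p_i)]`. Under
#' independence its expectation is 1; `VR > 1` indicates community-wide
#' positive association. The test statistic `W = VR * N` is compared with the
#' central chi-square band `(chi^2_{0.95}, chi^2_{0.05})` at `df` degrees of
#' freedom (default `N`): `W` inside the band means no significant overall
#' association.
#'
#' @param presence Logical sites x species matrix or `site_species_matrix`.
#' @param df Degrees of freedom for the chi-square band; defaults to the
#'   number of sites.
#' @return List of class `community_association`: `vr`, `w`, `df`,
#'   `band` (length-2 numeric), `verdict` (`significant_positive`,
#'   `significant_negative` or `not_significant`).
#' @export
variance_ratio <- function(presence, df = NULL) {
  p <- if (inherits(presence, "site_species_matrix")) presence$presence
       else presence
  p <- p * 1L
  N <- nrow(p)
  S <- ncol(p)
  if (N < 2 || S < 2) stop("need at least 2 sites and 2 species")
  pi <- colMeans(p)
  denom <- sum(pi * (1 - pi))
  if (denom == 0) {
    stop("every species is present at all sites or none: variance ratio undefined")
  }
  Tj <- rowSums(p)
  num <- mean((Tj - mean(Tj))^2)
  vr <- num / denom
  w <- vr * N
  if (is.null(df)) df <- N
  band <- stats::qchisq(c(0.05, 0.95), df = df)
  verdict <- if (w > band[1] && w < band[2]) "not_significant"
             else if (vr > 1) "significant_positive"
             else "significant_negative"
  structure(list(vr = vr, w = w, df = df, band = band, verdict = verdict,
                 n_sites = N, n_species = S),
            class = "community_association")
}

#' @export
print.community_association <- function(x, ...) {
  cat(sprintf("Variance ratio VR = %.3f, W = %.2f (df = %d, band %.2f-%.2f): %s\n",
              x$vr, x$w, x$df, x$band[1], x$band[2], x$verdict))
  invisible(x)
}

gk_lambda_point <- function(t, direction = c("ab", "ba")) {
  direction <- match.arg(direction)
  # rows = predictor states, cols = predicted states
  if (direction == "ab") {
    tab <- rbind(c(t$a, t$b), c(t$c, t$d))
  } else {
    tab <- rbind(c(t$a, t$c), c(t$b, t$d))
  }
  colmax <- max(colSums(tab))
  if (t$n - colmax == 0) return(NA_real_)
  (sum(apply(tab, 1, max)) - colmax) / (t$n - colmax)
}

#' Goodman-Kruskal asymmetric lambda for a species pair
#'
#' Proportional reduction in error when the predicted species' presence state
#' at a site is guessed from the predictor species' state instead of from the
#' overall mode. Asymmetric: predicting B from A generally differs from
#' predicting A from B. Upper and lower prediction-rate limits are the 97.5%
#' and 2.5% percentiles of a nonparametric bootstrap that resamples sites
#' (multinomially over the four table cells); a positive lower limit marks a
#' significant asymmetric (commensal-type) dependence. The reported p-value
#' comes from the Yates chi-square of the same table.
#'
#' @param t Contingency table from [contingency()] (cells `a`..`d` in the
#'   first-species-by-second-species layout).
#' @param direction `"ab"`: first species predicts second; `"ba"`: reverse.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List `lambda`, `upper` (L_B), `lower` (lambda_BO), `p`,
#'   `significant` (`lower > 0`), `n_boot`.
#' @export
gk_lambda <- function(t, direction = c("ab", "ba"), n_boot = 1000, seed = 1) {
  direction <- match.arg(direction)
  if (t$n - max(t$a + t$c, t$b + t$d, t$a + t$b, t$c + t$d) < 0) {
    stop("invalid contingency table")
  }
  est <- gk_lambda_point(t, direction)
  if (is.na(est)) {
    warning("predicted species present at all or no sites: lambda undefined")
    return(list(lambda = NA_real_, upper = NA_real_, lower = NA_real_,
                p = NA_real_, significant = NA, n_boot = n_boot))
  }
  if (n_boot < 1) stop("n_boot must be a positive integer")
  probs <- c(t$a, t$b, t$c, t$d) / t$n
  boot <- local({
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
    draws <- stats::rmultinom(n_boot, size = t$n, prob = probs)
    apply(draws, 2, function(cells) {
      gk_lambda_point(list(a = cells[1], b = cells[2], c = cells[3],
                           d = cells[4], n = t$n), direction)
    })
  })
  qs <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  chi2 <- suppressWarnings(yates_chi2(t))
  p <- if (is.na(chi2)) NA_real_ else stats::pchisq(chi2, df = 1,
                                                    lower.tail = FALSE)
  list(lambda = est, upper = qs[2], lower = qs[1], p = p,
       significant = qs[1] > 0, n_boot = n_boot)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Directed lambda table over a community
#'
#' Computes [gk_lambda()] in both directions for every species pair involving
#' the focal species (or every pair when `focal` is `NULL`).
#'
#' @param m A `site_species_matrix`.
#' @param focal Optional focal species name.
#' @param species Optional species subset.
#' @inheritParams gk_lambda
#' @return Data frame `predictor`, `predicted`, `lambda`, `upper`, `lower`,
#'   `p`, `significant`.
#' @export
lambda_table <- function(m, focal = NULL, species = NULL, n_boot = 1000,
                         seed = 1) {
  pres <- m$presence
  if (!is.null(species)) pres <- pres[, species, drop = FALSE]
  sp <- colnames(pres)
  if (!is.null(focal) && !(focal %in% sp)) stop("focal species not present: ", focal)
  pairs <- utils::combn(length(sp), 2)
  keep <- if (is.null(focal)) seq_len(ncol(pairs)) else
    which(apply(pairs, 2, function(ik) focal %in% sp[ik]))
  rows <- lapply(keep, function(j) {
    ik <- pairs[, j]
    t <- contingency(pres[, ik[1]], pres[, ik[2]])
    ab <- gk_lambda(t, "ab", n_boot = n_boot, seed = seed + j)
    ba <- gk_lambda(t, "ba", n_boot = n_boot, seed = seed + j + ncol(pairs))
    data.frame(predictor = sp[c(ik[1], ik[2])],
               predicted = sp[c(ik[2], ik[1])],
               lambda = c(ab$lambda, ba$lambda),
               upper = c(ab$upper, ba$upper),
               lower = c(ab$lower, ba$lower),
               p = c(ab$p, ba$p),
               significant = c(ab$significant, ba$significant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
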