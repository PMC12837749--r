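#' The reference community table
#'
#' The species composition of the reference 67-camera Asian elephant
#' community survey: taxonomy, number of independent photographs, the
#' printed relative abundance index, the number of camera sites at which
#' each species was detected, and whether the species passed the
#' mean-RAI screen (printed mean 10.9). The printed RAI column is carried
#' verbatim as data; it is not recomputable from the photograph counts
#' alone (its denominator is not stated), so it is treated as reference
#' input rather than as a derived quantity.
#'
#' @return Data frame with columns `class`, `order`, `family`, `species`,
#'   `n_photographs`, `rai_printed`, `occupancy`, `selected`.
#' @export
community_table <- function() {
  path <- system.file("extdata", "community_table.csv", package = "camassoc")
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(rep("character", 4), "integer", "numeric",
                                 "integer", "logical"))
}

#' Aggregate checks on the reference community table
#'
#' Summarises the table into the headline community statistics: species,
#' family and order counts, total independent photographs, and the number
#' of species whose printed RAI exceeds the printed community mean.
#'
#' @param tab Output of [community_table()] (the default).
#' @param mean_rai The printed community mean RAI used by the screen.
#' @return Named list of counts.
#' @export
community_summary <- function(tab = community_table(), mean_rai = 10.9) {
  list(n_species = nrow(tab),
       n_families = length(unique(tab$family)),
       n_orders = length(unique(tab$order)),
       total_photographs = sum(tab$n_photographs),
       n_selected = sum(tab$rai_printed > mean_rai))
}
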