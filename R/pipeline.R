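#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. Either `input` (a
#' detections CSV) or `preset` (a synthetic community, see [load_preset()])
#' must be given.
#'
#' @param input Path to a detections CSV, or `NULL`.
#' @param preset Preset name / YAML path for a synthetic run, or `NULL`.
#' @param out_dir Report directory (created).
#' @param focal Focal species for the lambda and activity stages (`NULL`
#'   analyses all pairs).
#' @param window_minutes Independence window (default 30).
#' @param n_boot Bootstrap replicates for lambda and activity CIs.
#' @param n_perm Permutation replicates for the rhythm test (0 = skip).
#' @param min_activity_n Minimum events per species for activity analysis.
#' @param df_override Degrees of freedom for the variance-ratio W band
#'   (`NULL` = number of sites).
#' @param all_pairs Keep non-significant edges in the network?
#' @param seed Master seed; every stochastic stage derives from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, preset = NULL, out_dir = "camassoc_run",
                       focal = NULL, window_minutes = 30, n_boot = 1000,
                       n_perm = 0, min_activity_n = 10, df_override = NULL,
                       all_pairs = FALSE, seed = 1) {
  if (is.null(input) == is.null(preset)) {
    stop("give exactly one of `input` (detections CSV) or `preset`")
  }
  stopifnot(window_minutes > 0, n_boot >= 1, n_perm >= 0, min_activity_n >= 2,
            seed == as.integer(seed))
  structure(list(input = input, preset = preset, out_dir = out_dir,
                 focal = focal, window_minutes = window_minutes,
                 n_boot = n_boot, n_perm = n_perm,
                 min_activity_n = min_activity_n, df_override = df_override,
                 all_pairs = all_pairs, seed = as.integer(seed)),
            class = "run_config")
}

stage_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

# JSON-safe echo of the configuration: a preset passed as a community_spec
# object is replaced by a structural summary rather than serialised whole.
config_echo <- function(config) {
  out <- unclass(config)
  if (inherits(out$preset, "community_spec")) {
    sp <- out$preset
    out$preset <- list(type = "community_spec", n_sites = sp$n_sites,
                       n_species = nrow(sp$species),
                       n_associations = if (is.null(sp$associations)) 0L
                                        else nrow(sp$associations),
                       n_days = sp$n_days, start_date = sp$start_date)
  }
  out
}

#' Run the full association pipeline
#'
#' Executes, in order: detection input (file or synthetic preset),
#' independence filtering, site-by-species matrix construction, relative
#' abundance screening, distributional breadth, Pianka overlap, the
#' community variance-ratio test, pairwise Phi / Yates chi-square on the
#' RAI-selected species (plus the focal species), directed lambda tests for
#' the focal species, diel activity overlap, and network assembly. Writes
#' every table as CSV into `config$out_dir` along with a machine-readable
#' `manifest.json` (package version, seed, config echo, stage row counts).
#' Identical config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results and `files`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) file.path(config$out_dir, name)
  files <- character(0)
  put <- function(df, name) {
    utils::write.csv(df, outfile(name), row.names = FALSE)
    files[[name]] <<- outfile(name)
  }

  stage_msg("input")
  if (!is.null(config$preset)) {
    sim <- simulate_community(config$preset, seed = config$seed)
    records <- sim$records
  } else {
    records <- read_detections(config$input)
  }

  stage_msg("independence filter (", config$window_minutes, " min)")
  events <- filter_independent(records, config$window_minutes)
  put(transform(events, event_start = format(event_start,
                                             "%Y-%m-%d %H:%M:%S")),
      "events.csv")

  stage_msg("site x species matrix")
  m <- build_matrix(events)
  put(data.frame(site_id = rownames(m$counts), m$counts,
                 check.names = FALSE), "matrix.csv")

  stage_msg("relative abundance")
  abundance <- rai(m)
  put(abundance, "abundance.csv")
  analysed <- union(abundance$species[abundance$selected], config$focal)
  analysed <- intersect(sort(analysed), colnames(m$counts))

  stage_msg("distributional breadth + spatial overlap")
  breadth <- niche_breadth(m)
  put(breadth, "breadth.csv")
  O <- pianka_matrix(m)
  put(data.frame(species = rownames(O), O, check.names = FALSE),
      "overlap_matrix.csv")
  put(overlap_pairs(O), "overlap_pairs.csv")

  stage_msg("community variance ratio")
  comm <- variance_ratio(m, df = config$df_override)
  put(data.frame(vr = comm$vr, w = comm$w, df = comm$df,
                 band_low = comm$band[1], band_high = comm$band[2],
                 verdict = comm$verdict), "community.csv")

  stage_msg("pairwise associations (", length(analysed), " species)")
  if (length(analysed) < 2) stop("pairwise association stage: fewer than two ",
                                 "species pass the RAI screen")
  assoc <- pair_associations(m, species = analysed)
  put(assoc, "pairwise.csv")

  stage_msg("lambda predictability")
  lambdas <- lambda_table(m, focal = config$focal, species = analysed,
                          n_boot = config$n_boot, seed = config$seed + 1L)
  put(lambdas, "lambda.csv")

  stage_msg("diel activity overlap")
  activity <- tryCatch(
    activity_overlap_table(events[events$species %in% analysed, ],
                           focal = config$focal,
                           min_n = config$min_activity_n,
                           n_boot = config$n_boot, n_perm = config$n_perm,
                           seed = config$seed + 2L),
    error = function(e) {
      stage_msg("activity stage skipped: ", conditionMessage(e))
      NULL
    })
  if (!is.null(activity)) put(activity, "activity.csv")
  curves <- do.call(rbind, lapply(analysed, function(sp) {
    th <- to_radians(events[events$species == sp, ])
    if (length(th) < config$min_activity_n) return(NULL)
    cbind(species = sp, activity_curve(th))
  }))
  if (!is.null(curves)) put(curves, "activity_curves.csv")

  stage_msg("network assembly")
  network <- build_network(abundance, assoc, lambdas, breadth = breadth,
                           focal = config$focal,
                           all_pairs = config$all_pairs)
  files <- c(files, export_network(network, config$out_dir,
                                   format = "graphml"))

  manifest <- list(
    package = "camassoc",
    version = as.character(utils::packageVersion("camassoc")),
    seed = config$seed,
    config = config_echo(config),
    notes = paste("rhythm_difference_test is a label-permutation stand-in;",
                  "the original rhythm-comparison procedure is unspecified"),
    stages = list(n_records = nrow(records), n_events = nrow(events),
                  n_sites = nrow(m$counts), n_species = ncol(m$counts),
                  n_analysed = length(analysed),
                  vr = comm$vr, w = comm$w, verdict = comm$verdict))
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files[["manifest.json"]] <- outfile("manifest.json")

  invisible(list(records = records, events = events, matrix = m,
                 abundance = abundance, breadth = breadth, overlap = O,
                 community = comm, pairwise = assoc, lambdas = lambdas,
                 activity = activity, network = network, files = files))
}
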