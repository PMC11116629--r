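#' Configuration for an end-to-end pipeline run
#'
#' A fully serializable description of a run; a saved configuration re-runs
#' to identical outputs for the deterministic stages (simulate, segment,
#' kinetics).
#'
#' @param out_dir output directory for all stage outputs and the manifest.
#' @param plate_csv plate metadata CSV (required unless `scenario` is given,
#'   in which case the simulated plate is used).
#' @param scenario optional [scenario()] (or path to a YAML/JSON scenario
#'   file) to simulate before analysis.
#' @param channels channels to segment.
#' @param control_groups named list mapping each channel to its calibration /
#'   normalization reference group.
#' @param sigma Gaussian smoothing scale, px.
#' @param thresholds optional manual threshold override (named per timepoint
#'   or scalar), bypassing calibration.
#' @param rout_q ROUT Q for outlier flagging.
#' @param chamber_lines optional named list of [chamber_line()]s per well
#'   (or path to a JSON file `well -> chamber -> list(p1, p2)`) enabling the
#'   cardiac-function stage.
#' @param seed integer seed.
#' @param verbose print per-stage progress.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(out_dir, plate_csv = NULL, scenario = NULL,
                       channels = c("BFP", "mCherry"),
                       control_groups = list(BFP = "negative_control",
                                             mCherry = "not_ablated"),
                       sigma = 2, thresholds = NULL, rout_q = 0.01,
                       chamber_lines = NULL, seed = 1L, verbose = TRUE) {
  if (missing(out_dir) || is.null(out_dir)) stop("config field missing: out_dir")
  if (is.null(plate_csv) && is.null(scenario))
    stop("config field missing: plate_csv (or scenario)")
  miss <- setdiff(channels, names(control_groups))
  if (length(miss))
    stop("control_groups lacks channel(s): ", paste(miss, collapse = ", "))
  structure(list(out_dir = out_dir, plate_csv = plate_csv,
                 scenario = scenario, channels = channels,
                 control_groups = control_groups, sigma = sigma,
                 thresholds = thresholds, rout_q = rout_q,
                 chamber_lines = chamber_lines, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

config_hash <- function(config) {
  # md5 of the canonical JSON serialization (scenario objects included)
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full regeneration-quantification pipeline
#'
#' Executes the stages in order — simulate (optional), calibrate + segment
#' per channel, kinetics, statistics, cardiac function (optional) — writing
#' each stage's output as plain CSV under `config$out_dir` together with a
#' JSON run manifest (configuration hash, package version, per-stage row
#' counts, collected warnings). Any stage error aborts the run with the
#' stage name attached.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the manifest and the in-memory stage
#'   outputs (`plate`, `areas`, `kinetics`, `summary`, `stats`, `cardio`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("larvalheart")),
                   config_hash = config_hash(config), seed = config$seed,
                   stages = list(), warnings = character(0))
  note <- function(...) if (config$verbose) message(sprintf(...))
  run_stage <- function(name, expr) {
    note("stage %s ...", name)
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  plate_csv <- config$plate_csv
  if (!is.null(config$scenario)) {
    scn <- config$scenario
    if (is.character(scn)) scn <- read_scenario(scn)
    sim <- run_stage("simulate",
                     simulate_cohort(scn, file.path(config$out_dir, "videos"),
                                     seed = config$seed, force = TRUE))
    plate_csv <- sim$plate_csv
  }
  plate <- run_stage("load_plate", load_plate(plate_csv))
  manifest$stages$load_plate <- list(rows = nrow(plate))

  areas <- list()
  for (ch in config$channels) {
    thresholds <- config$thresholds
    if (is.null(thresholds))
      thresholds <- run_stage(paste0("calibrate_", ch),
                              calibrate_plate(plate, ch,
                                              config$control_groups[[ch]],
                                              config$sigma))
    areas[[ch]] <- run_stage(paste0("segment_", ch),
                             segment_plate(plate, ch, thresholds,
                                           config$sigma))
  }
  areas_all <- do.call(rbind, areas)
  write.csv(areas_all, file.path(config$out_dir, "areas.csv"),
            row.names = FALSE)
  manifest$stages$segment <- list(rows = nrow(areas_all))

  kin <- list()
  for (ch in config$channels) {
    ref <- config$control_groups[[ch]]
    sub <- areas[[ch]]
    if (ch != "BFP") {
      # mCherry is meaningful only in recombined groups; restrict to groups
      # that actually carry signal in at least half their larvae
      keep <- vapply(split(sub$area_um2 > 0, sub$group), mean, numeric(1))
      sub <- sub[sub$group %in% c(names(keep[keep >= 0.5]), ref), ]
    }
    kin[[ch]] <- run_stage(paste0("kinetics_", ch),
                           normalize_to_control(sub, ref, config$rout_q))
  }
  kin_all <- do.call(rbind, kin)
  write.csv(kin_all, file.path(config$out_dir, "kinetics.csv"),
            row.names = FALSE)
  summary <- summarize_kinetics(kin_all[kin_all$channel == config$channels[1], ])
  write.csv(summary, file.path(config$out_dir, "kinetics_summary.csv"),
            row.names = FALSE)
  manifest$stages$kinetics <- list(rows = nrow(kin_all))

  stats_out <- NULL
  bfp_kin <- kin[[config$channels[1]]]
  ok <- !bfp_kin$outlier_flag
  if (length(unique(bfp_kin$group)) >= 2 &&
      length(unique(bfp_kin$timepoint)) >= 2) {
    stats_out <- run_stage("stats",
                           two_way_anova_tukey(bfp_kin[ok, ]))
    write.csv(stats_out$anova_table,
              file.path(config$out_dir, "anova.csv"), row.names = FALSE)
    write.csv(stats_out$comparisons,
              file.path(config$out_dir, "comparisons.csv"), row.names = FALSE)
    write.csv(normality_tests(stats_out$residuals),
              file.path(config$out_dir, "normality.csv"), row.names = FALSE)
    manifest$stages$stats <- list(rows = nrow(stats_out$comparisons))
  }

  cardio <- NULL
  if (!is.null(config$chamber_lines)) {
    lines_by_well <- config$chamber_lines
    if (is.character(lines_by_well)) {
      raw <- jsonlite::read_json(lines_by_well, simplifyVector = FALSE)
      lines_by_well <- lapply(raw, function(chs)
        lapply(names(chs), function(nm)
          chamber_line(unlist(chs[[nm]]$p1), unlist(chs[[nm]]$p2), nm)))
    }
    cardio <- run_stage("cardio", {
      rows <- lapply(names(lines_by_well), function(w) {
        rec <- plate[plate$well == w, ]
        if (nrow(rec) == 0) return(NULL)
        do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
          vid <- read_video(rec[[paste0("path_", config$channels[1])]][i],
                            rec$pixel_size_um[i], rec$frame_rate_fps[i],
                            config$channels[1])
          out <- analyze_cardiac_function(vid, lines_by_well[[w]])
          cbind(data.frame(well = w, timepoint = rec$timepoint[i],
                           stringsAsFactors = FALSE), out)
        }))
      })
      do.call(rbind, rows)
    })
    if (!is.null(cardio)) {
      write.csv(cardio, file.path(config$out_dir, "cardio.csv"),
                row.names = FALSE)
      manifest$stages$cardio <- list(rows = nrow(cardio))
    }
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("done: %s", config$out_dir)
  invisible(list(manifest = manifest, plate = plate, areas = areas_all,
                 kinetics = kin_all, summary = summary, stats = stats_out,
                 cardio = cardio))
}
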