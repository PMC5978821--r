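#' Configuration for an end-to-end pipeline run
#'
#' Bundles everything a run needs: where to write, the cohort spec for the
#' simulate stage, the frame-selection `k`, the on-disk frame format and
#' the master seed.  Every stage communicates with the next only through
#' files under `out_dir`, so any stage can be rerun in isolation, and the
#' whole run is a deterministic function of the config.
#'
#' @param out_dir Run directory (created by [run_pipeline()]).
#' @param spec A [cohort_spec()]; its `seed` is overridden by `seed` here
#'   so one number controls the run.
#' @param k Frames kept per recording (>= 1).
#' @param format Frame format on disk, `"csv"` or `"tiff16"`.
#' @param scale,offset Quantisation used when `format = "tiff16"`.
#' @param seed Master seed, recorded in every output header.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, spec = cohort_spec(), k = 20L,
                       format = c("csv", "tiff16"),
                       scale = 0.01, offset = 0, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_tl("`k` must be >= 1")
  format <- match.arg(format)
  seed <- as.integer(seed)
  spec$seed <- seed
  structure(list(out_dir = out_dir, spec = spec, k = k, format = format,
                 scale = scale, offset = offset, seed = seed),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' The JSON mirrors [run_config()]'s arguments; `spec` holds the cohort
#' spec fields (`groups`, `positions`, `duration_s`, `rate_hz`) and
#' `phantom` any [phantom_params()] overrides.
#'
#' @param path JSON config file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- do.call(phantom_params, as.list(cfg$phantom %||% list()))
  sp <- cfg$spec %||% list()
  groups <- if (is.null(sp$groups)) default_cohort_groups() else
    lapply(sp$groups, function(g) {
      g$region_probs <- unlist(g$region_probs)
      g
    })
  spec <- cohort_spec(
    groups = groups, base_params = base,
    positions = sp$positions %||% c("anterior_sitting", "anterior_standing"),
    duration_s = sp$duration_s %||% 20, rate_hz = sp$rate_hz %||% 30,
    k = cfg$k %||% 20L, seed = cfg$seed %||% 1L)
  run_config(out_dir = out_dir %||% cfg$out_dir,
             spec = spec, k = cfg$k %||% 20L,
             format = cfg$format %||% "csv",
             scale = cfg$scale %||% 0.01, offset = cfg$offset %||% 0,
             seed = cfg$seed %||% 1L)
}

log_line <- function(log_path, stage, msg) {
  line <- sprintf("%s [%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), stage, msg)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(line)
}

write_table_with_header <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# thermolimp v%s seed=%d\n",
              as.character(utils::packageVersion("thermolimp")), seed),
      file = con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output table
#'
#' Reads a CSV written by the pipeline, skipping the `#` seed header.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_pipeline_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Stage 1: simulate a cohort to disk
#'
#' Generates the cohort of `config$spec` and writes `subjects.csv`, one
#' recording directory per subject x position
#' (`recordings/<subject>/<position>/manifest.json` + frames) and one ROI
#' table per subject (`rois/<subject>.tsv`: label, leg, top, left, bottom,
#' right for the affected-leg ROIs relevant to the complaint).
#'
#' @param config A [run_config()].
#' @return The cohort directory, invisibly.
#' @export
stage_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out, "run.log")
  log_line(log, "simulate", sprintf("seed=%d groups=%s", config$seed,
           paste(names(config$spec$groups), collapse = ",")))
  cohort <- generate_cohort(config$spec)
  write_table_with_header(cohort$subjects, file.path(out, "subjects.csv"),
                          config$seed)
  dir.create(file.path(out, "rois"), showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$subjects))) {
    s <- cohort$subjects[i, ]
    rois <- phantom_rois(config$spec$base_params, s$affected_side)
    labs <- relevant_rois(s$complaint_region)
    tab <- do.call(rbind, lapply(rois[labs], function(r)
      data.frame(label = r$label, leg = r$leg, top = r$top, left = r$left,
                 bottom = r$bottom, right = r$right)))
    utils::write.table(tab, file.path(out, "rois",
                                      paste0(s$subject_id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (pos in names(cohort$recordings[[s$subject_id]])) {
      write_recording(cohort$recordings[[s$subject_id]][[pos]],
                      file.path(out, "recordings", s$subject_id, pos),
                      format = config$format,
                      scale = config$scale, offset = config$offset)
    }
    log_line(log, "simulate", sprintf("subject %s written", s$subject_id))
  }
  invisible(out)
}

#' Stage 2: select frames for every recording
#'
#' For each recording directory under `out_dir/recordings`, scores frames
#' and writes the selected indices (one per line) to `frames.txt` next to
#' the manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, the number of recordings processed.
#' @export
stage_select_frames <- function(config) {
  out <- config$out_dir
  log <- file.path(out, "run.log")
  manifests <- list.files(file.path(out, "recordings"), "manifest.json",
                          recursive = TRUE, full.names = TRUE)
  if (!length(manifests)) stop_tl("no recordings found under ", out)
  for (mp in manifests) {
    rec <- load_recording(mp)
    idx <- select_best_frames(rec, k = config$k)
    writeLines(as.character(idx), file.path(dirname(mp), "frames.txt"))
    log_line(log, "select-frames",
             sprintf("%s: kept %d/%d frames", dirname(mp), length(idx),
                     n_frames(rec)))
  }
  invisible(length(manifests))
}

#' Stage 3: measure paired ROIs
#'
#' For every subject, position and relevant ROI: loads the recording and
#' its selected frames, mirrors the affected-leg ROI about the image
#' midline and measures the pair.  Writes `measurements.csv`.
#'
#' @param config A [run_config()].
#' @return The measurements data frame, invisibly.
#' @export
stage_measure <- function(config) {
  out <- config$out_dir
  log <- file.path(out, "run.log")
  subjects <- read_pipeline_table(file.path(out, "subjects.csv"))
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    roi_tab <- utils::read.table(
      file.path(out, "rois", paste0(s$subject_id, ".tsv")),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    pos_dirs <- list.dirs(file.path(out, "recordings", s$subject_id),
                          recursive = FALSE)
    for (pd in pos_dirs) {
      rec <- load_recording(file.path(pd, "manifest.json"))
      idx <- as.integer(readLines(file.path(pd, "frames.txt")))
      width <- ncol(rec$frames[[1]]$temps)
      for (j in seq_len(nrow(roi_tab))) {
        r <- roi(roi_tab$label[j], roi_tab$leg[j], roi_tab$top[j],
                 roi_tab$left[j], roi_tab$bottom[j], roi_tab$right[j])
        m <- measure_pair(rec, paired_roi(r, mirror_roi(r, width)), idx)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, diagnosis = s$diagnosis,
          complaint_region = s$complaint_region, position = rec$position,
          roi = r$label, n_frames = m$n_frames,
          affected_mean = m$affected_mean, healthy_mean = m$healthy_mean,
          pct_diff = m$pct_diff, stringsAsFactors = FALSE)
      }
      log_line(log, "measure", sprintf("%s %s: %d ROI pairs",
               s$subject_id, rec$position, nrow(roi_tab)))
    }
  }
  meas <- do.call(rbind, rows)
  rownames(meas) <- NULL
  write_table_with_header(meas, file.path(out, "measurements.csv"),
                          config$seed)
  invisible(meas)
}

#' Stage 4: cohort summaries
#'
#' Applies the exclusion rules, writes the descriptive complaint summary
#' (`descriptive_summary.csv`), the group-summary table at full precision
#' (`group_summary.csv`) and its formatted 2-decimal rendering
#' (`group_summary_formatted.csv`).
#'
#' @param config A [run_config()].
#' @return The group-summary data frame, invisibly.
#' @export
stage_summarize <- function(config) {
  out <- config$out_dir
  log <- file.path(out, "run.log")
  subjects <- read_pipeline_table(file.path(out, "subjects.csv"))
  meas <- read_pipeline_table(file.path(out, "measurements.csv"))
  excl <- apply_exclusions(subjects)
  if (nrow(excl$excluded))
    write_table_with_header(excl$excluded, file.path(out, "excluded.csv"),
                            config$seed)
  meas <- meas[meas$subject_id %in% excl$included$subject_id, , drop = FALSE]
  desc <- descriptive_summary(excl$included)
  write_table_with_header(desc, file.path(out, "descriptive_summary.csv"),
                          config$seed)
  grp <- summarize_cohort(meas)
  write_table_with_header(grp, file.path(out, "group_summary.csv"),
                          config$seed)
  write_table_with_header(format_group_summary(grp),
                          file.path(out, "group_summary_formatted.csv"),
                          config$seed)
  log_line(log, "summarize",
           sprintf("%d included / %d excluded subjects, %d summary rows",
                   nrow(excl$included), nrow(excl$excluded), nrow(grp)))
  invisible(grp)
}

#' Run the full pipeline
#'
#' simulate -> select-frames -> measure -> summarize, sequentially, into
#' `config$out_dir`.  Deterministic given the config (including its seed):
#' rerunning with the same config reproduces byte-identical measurement
#' and summary tables.  A failure in any stage aborts with the stage name;
#' outputs of completed stages are left intact.
#'
#' @param config A [run_config()].
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- list(simulate = stage_simulate,
                 `select-frames` = stage_select_frames,
                 measure = stage_measure,
                 summarize = stage_summarize)
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](config),
             error = function(e) stop_tl("stage '", nm, "' failed: ",
                                         conditionMessage(e)))
  }
  invisible(config$out_dir)
}
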