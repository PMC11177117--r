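#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Can be built in code or loaded from YAML/JSON via [read_pipeline_config()].
#'
#' @param stack_path,sidecar_path input acquisition (see
#'   [read_acquisition()]).
#' @param out_dir output directory (created if missing).
#' @param extinction_csv extinction table CSV; `NULL` uses the bundled
#'   representative table.
#' @param pathlengths a [pathlength_set()] or named list of its fields.
#' @param baseline_frames optional `c(from, to)` timepoint range for the
#'   baseline; default full record.
#' @param detrend remove per-pixel linear trends (default `TRUE`).
#' @param crosstalk_c red-into-green crosstalk ratio subtracted before
#'   dF/F (default 0 = no correction).
#' @param lambda_ex,lambda_em wavelengths for the green hemodynamic
#'   correction (nm).
#' @param correct_channels channels to hemodynamically correct (default
#'   `"470"`; the red channel may be added).
#' @param onsets_csv optional CSV of stimulus onsets (column `onset_s`).
#' @param pre_s,post_s,trial_dt_s trial window and grid (s).
#' @param pupil_video optional pupil video (TIFF stack).
#' @param pupil_roi,pupil_threshold ellipse ROI and intensity cutoff for
#'   [pupil_trace()].
#' @param seed RNG seed recorded in the manifest.
#' @param log_base attenuation log base (default 10).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(stack_path, sidecar_path, out_dir,
                            extinction_csv = NULL,
                            pathlengths = pathlength_set(),
                            baseline_frames = NULL,
                            detrend = TRUE, crosstalk_c = 0,
                            lambda_ex = 470, lambda_em = 523,
                            correct_channels = "470",
                            onsets_csv = NULL, pre_s = 2, post_s = 10,
                            trial_dt_s = 0.1,
                            pupil_video = NULL, pupil_roi = NULL,
                            pupil_threshold = NULL,
                            seed = 1L, log_base = 10) {
  if (is.list(pathlengths) && !inherits(pathlengths, "pathlength_set"))
    pathlengths <- do.call(pathlength_set, pathlengths)
  cfg <- as.list(environment())
  for (f in c("stack_path", "sidecar_path", "extinction_csv",
              "onsets_csv", "pupil_video")) {
    path <- cfg[[f]]
    if (!is.null(path) && !file.exists(path))
      .stopf("config error: %s '%s' does not exist", f, path)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path a `.yml`/`.yaml` or `.json` config file whose keys match
#'   the arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  raw <- if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

.content_md5 <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(obj, con, version = 2L)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Run the full processing pipeline
#'
#' Executes, in order: demultiplexing, per-channel baselines, hemoglobin
#' estimation from the 525/625-nm reflectance channels, optional crosstalk
#' subtraction (intensity domain, before dF/F), dF/F, linear detrending,
#' hemodynamic correction of the green channel, optional trial alignment
#' and ratio maps, and optional pupil quantification.  Results go to
#' `out_dir` (`results.h5`, trace CSVs, ratio-map CSVs) with a JSON
#' manifest recording input hashes, the configuration, package version and
#' content hashes of every output.  Any stage error aborts with a
#' stage-named message and removes partial outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  made <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(made)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  eps <- stage("extinction", {
    if (is.null(cfg$extinction_csv)) default_extinction_table()
    else read_extinction_table(cfg$extinction_csv)
  })
  acq <- stage("load", read_acquisition(cfg$stack_path, cfg$sidecar_path))
  chans <- stage("demultiplex", demultiplex(acq))
  bframes <- if (is.null(cfg$baseline_frames)) NULL
    else seq(cfg$baseline_frames[1L], cfg$baseline_frames[2L])
  maps <- stage("hemodynamics", {
    b525 <- compute_baseline(chans[["525"]], bframes)
    b625 <- compute_baseline(chans[["625"]], bframes)
    consts <- precompute_constants(eps, cfg$pathlengths, b525, b625,
                                   log_base = cfg$log_base)
    estimate_hemodynamics(chans[["525"]], chans[["625"]], consts)
  })
  f470 <- chans[["470"]]
  if (cfg$crosstalk_c > 0)
    f470 <- stage("crosstalk",
                  correct_crosstalk(f470, chans[["565"]], cfg$crosstalk_c))
  dff <- stage("dff", {
    out <- list("470" = compute_dff(f470, compute_baseline(f470, bframes)),
                "565" = compute_dff(chans[["565"]],
                                    compute_baseline(chans[["565"]], bframes)))
    if (cfg$detrend) out <- lapply(out, detrend_linear)
    out
  })
  dff <- stage("hemodynamic_correction", {
    for (ch in cfg$correct_channels)
      dff[[ch]] <- correct_hemodynamics(dff[[ch]], maps, eps,
                                        cfg$pathlengths,
                                        lambda_ex = cfg$lambda_ex,
                                        lambda_em = cfg$lambda_em)
    dff
  })
  h5 <- file.path(cfg$out_dir, "results.h5")
  stage("write_stacks", {
    write_results(list(hbo = maps$hbo, hbr = maps$hbr, hbt = maps$hbt,
                       dff_470 = dff[["470"]]$data,
                       dff_565 = dff[["565"]]$data),
                  h5,
                  units = c(hbo = "M", hbr = "M", hbt = "M",
                            dff_470 = "fractional", dff_565 = "fractional"))
    made <- c(made, h5)
  })
  time_s <- (seq_len(dim(maps$hbo)[3L]) - 1L) * maps$dt_s
  roi_mean <- function(a) apply(a, 3L, mean, na.rm = TRUE)
  traces_csv <- file.path(cfg$out_dir, "traces.csv")
  stage("write_traces", {
    write_trace(time_s,
                list(hbo_M = roi_mean(maps$hbo), hbr_M = roi_mean(maps$hbr),
                     hbt_M = roi_mean(maps$hbt),
                     dff_470 = roi_mean(dff[["470"]]$data),
                     dff_565 = roi_mean(dff[["565"]]$data)),
                traces_csv)
    made <- c(made, traces_csv)
  })
  map_files <- character(0)
  if (!is.null(cfg$onsets_csv)) {
    stage("trials", {
      onsets <- utils::read.csv(cfg$onsets_csv)$onset_s
      for (ch in c("470", "565")) {
        tt <- align_trials(dff[[ch]], onsets, cfg$pre_s, cfg$post_s,
                           dt = cfg$trial_dt_s,
                           quantity = paste0("dff_", ch))
        rm_ <- ratio_map(tt, latency_s = if (ch == "565") 0.1 else 1.7)
        f <- file.path(cfg$out_dir, sprintf("ratio_map_%s.csv", ch))
        utils::write.table(rm_, f, sep = ",", row.names = FALSE,
                           col.names = FALSE)
        map_files <- c(map_files, f)
        made <- c(made, f)
      }
    })
  }
  pupil_file <- NULL
  if (!is.null(cfg$pupil_video)) {
    stage("pupil", {
      pages <- tiff::readTIFF(cfg$pupil_video, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      video <- array(unlist(pages), c(dim(pages[[1L]])[1:2], length(pages)))
      p <- pupil_trace(video, cfg$pupil_roi, cfg$pupil_threshold)
      pupil_file <- file.path(cfg$out_dir, "pupil.csv")
      write_trace(p$time_s, list(raw_px = p$raw_px, norm = p$norm),
                  pupil_file)
      made <- c(made, pupil_file)
    })
  }
  manifest <- list(
    package = "mesowide",
    version = as.character(utils::packageVersion("mesowide")),
    seed = cfg$seed,
    inputs = list(stack = unname(tools::md5sum(cfg$stack_path)),
                  sidecar = unname(tools::md5sum(cfg$sidecar_path))),
    config = cfg[!vapply(cfg, is.function, logical(1))],
    outputs = c(
      list(results_h5 = .content_md5(read_results(h5)),
           traces_csv = unname(tools::md5sum(traces_csv))),
      if (length(map_files)) list(ratio_maps = unname(tools::md5sum(map_files))),
      if (!is.null(pupil_file)) list(pupil_csv = unname(tools::md5sum(pupil_file)))))
  class(manifest$config) <- NULL
  manifest$config$pathlengths <- unclass(manifest$config$pathlengths)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
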