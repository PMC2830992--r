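#' Validate a pipeline configuration
#'
#' Configuration is YAML. Known keys (unknown keys are rejected):
#' \preformatted{
#' stacks: glob or directory of subject volumes        (required)
#' cut_script: path to a cut-script text file          (optional)
#' output_dir: output directory                        (required)
#' reference: subject index or id, or "random"         (default 1)
#' stages: [rigid, affine, bspline]                    (default all three)
#' bspline_repeats: 1
#' registration: {pyramid_levels, max_iterations, initial_step, min_step,
#'                grad_delta, bspline_max_iterations, bspline_pgtol}
#' seed: 1
#' log_level: info | quiet
#' }
#'
#' @param source path to a YAML file, or YAML text.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(source) {
  cfg <- if (file.exists(source)) yaml::read_yaml(source)
  else yaml::yaml.load(source)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  known <- c("stacks", "cut_script", "output_dir", "reference", "stages",
             "bspline_repeats", "registration", "seed", "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (req in c("stacks", "output_dir"))
    if (is.null(cfg[[req]])) stop("missing required config key: ", req)
  cfg$reference <- if (is.null(cfg$reference)) 1L else cfg$reference
  cfg$stages <- if (is.null(cfg$stages)) c("rigid", "affine", "bspline")
  else unlist(cfg$stages)
  cfg$bspline_repeats <- if (is.null(cfg$bspline_repeats)) 1L
  else as.integer(cfg$bspline_repeats)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$log_level <- if (is.null(cfg$log_level)) "info" else cfg$log_level
  ropts <- do.call(registration_options,
                   if (is.null(cfg$registration)) list() else cfg$registration)
  cfg$registration <- ropts
  # protocol validation happens here so bad stage orders fail before work
  protocol <- averaging_protocol(reference_index =
                                   if (identical(cfg$reference, "random"))
                                     "random" else as.integer(cfg$reference),
                                 stages = cfg$stages,
                                 bspline_repeats = cfg$bspline_repeats,
                                 opts = ropts)
  cfg$protocol <- protocol
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(...)
}

#' Run the full generic-model pipeline
#'
#' Loads the subject stacks, replays the cut script on each (virtual
#' dissection), runs the iterative registration and averaging protocol,
#' and writes: per-stage averaged stacks (float NRRD), per-subject
#' transforms (JSON), the generic volume (NRRD), the generic surface mesh
#' (PLY) and a stage report (JSON) with per-stage sharpness ratios and the
#' final cross-subject Dice/RMSE report. The run is deterministic given
#' the config and seed.
#'
#' @param config a `pipeline_config` from [validate_config()], or a path /
#'   YAML text to validate.
#' @return the output directory, invisibly; the stage report is also
#'   returned as attribute `"report"`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  files <- if (dir.exists(config$stacks))
    list.files(config$stacks, pattern = "\\.(nrrd|mhd)$", full.names = TRUE)
  else Sys.glob(config$stacks)
  files <- sort(files)
  if (length(files) == 0) stop("no input stacks found: ", config$stacks)
  pipeline_log(config, "loading ", length(files), " subject stack(s)")
  stacks <- lapply(files, read_stack)
  names(stacks) <- tools::file_path_sans_ext(basename(files))
  if (!is.null(config$cut_script)) {
    pipeline_log(config, "replaying cut script ", config$cut_script)
    script <- parse_cut_script(readLines(config$cut_script))
    stacks <- lapply(stacks, apply_cuts, s = script)
  }
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  result <- iterative_average(stacks, config$protocol, seed = config$seed)
  for (s in seq_along(result$stages)) {
    st <- result$stages[[s]]
    write_stack(st$average,
                file.path(out, sprintf("stage%d_%s_average.nrrd", s, st$model)))
    for (i in seq_along(st$transforms))
      save_transform(st$transforms[[i]],
                     file.path(out, sprintf("stage%d_%s_subject%02d.json",
                                            s, st$model, i)))
  }
  write_stack(result$generic_volume, file.path(out, "generic.nrrd"))
  write_mesh(result$generic_mesh, file.path(out, "generic.ply"))
  final_stacks <- registered_stacks(result)
  names(final_stacks) <- names(stacks)
  report_obj <- comparison_report(final_stacks,
                                  averaged = result$generic_volume)
  report <- list(
    config = list(reference = config$reference,
                  stages = config$protocol$stages,
                  bspline_repeats = config$protocol$bspline_repeats,
                  seed = config$seed,
                  registration = config$registration),
    stage_models = result$stage_models,
    sharpness_ratios = result$sharpness,
    generic_threshold = result$threshold,
    dice = report_obj$dice, rmse = report_obj$rmse,
    rmse_vs_generic = report_obj$rmse_vs_averaged,
    dice_summary = report_obj$summary)
  writeLines(jsonlite::toJSON(report, digits = NA, auto_unbox = TRUE,
                              matrix = "rowmajor"),
             file.path(out, "report.json"))
  pipeline_log(config, "pipeline complete: ", out)
  structure(invisible(out), report = report)
}
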