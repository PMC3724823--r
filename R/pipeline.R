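# Configuration, the end-to-end pipeline driver, and the command-line
# entry point.

#' Build a pipeline configuration
#'
#' Every stage parameter defaults to the published value where one exists:
#' 45 spline samples, 45-degree crossing, 10 mm subject search radius, 500
#' seeds, 2 mm curvature radius, 30 mm minimum length, 0.05 amplitude
#' cutoff. Either a phantom block (the default) or real-data paths
#' (`dwi`, `bvec`, `bval`, `mask`, `ac_point`) drive the input stage.
#'
#' @param input List: either `list(type = "phantom", ...)` with arguments
#'   for [make_cn_phantom()] plus `n_subjects`, `snr`, or
#'   `list(type = "paths", dwi =, bvec =, bval =, mask =, ac_point =)`.
#' @param n_samples,search_radius,central_window,head_window Axis-stage
#'   parameters.
#' @param tracking List of tracking parameters.
#' @param rule_file Optional JSON bundle-rule file.
#' @param rng_seed Master seed; all stage seeds derive from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(type = "phantom"),
                            n_samples = 45,
                            search_radius = 10,
                            central_window = c(0.25, 0.65),
                            head_window = c(0.60, 0.90),
                            tracking = list(n_seeds = 500, step = 0.5,
                                            curvature_radius = 2,
                                            min_length = 30, cutoff = 0.05,
                                            cutoff_mode = "relative"),
                            rule_file = NULL,
                            rng_seed = 1L) {
  defaults <- list(n_seeds = 500, step = 0.5, curvature_radius = 2,
                   min_length = 30, cutoff = 0.05, cutoff_mode = "relative")
  tracking <- utils::modifyList(defaults, tracking)
  structure(list(input = input, n_samples = n_samples,
                 search_radius = search_radius,
                 central_window = central_window, head_window = head_window,
                 tracking = tracking, rule_file = rule_file,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with fields as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j[intersect(names(j), names(formals(pipeline_config)))])
}

#' Run the full parcellation pipeline
#'
#' Orchestrates the published stage order: tensors, spline axis, radiality
#' profile, boundary detection, tri-partition, tractography, bundle
#' classification, endpoint target maps. All artifacts (FA/direction/RGB
#' NIfTI maps, profile CSVs, boundary JSON, label volume, TCK streamlines,
#' bundle table, endpoint densities, run log) are written under `out_dir`.
#' Two runs with the same config and seed produce identical outputs.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created).
#' @return Invisible list with the in-memory stage results and the
#'   artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(paste0(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("cnparcel pipeline; master seed ", config$rng_seed)
  stage <- "input"
  result <- list()
  tryCatch({
    if ((config$input$type %||% "phantom") == "phantom") {
      ph_args <- config$input[setdiff(names(config$input),
                                      c("type", "n_subjects", "snr"))]
      truth <- do.call(make_cn_phantom, ph_args)
      n_subj <- config$input$n_subjects %||% 1
      snr <- config$input$snr %||% 20
      sigma <- if (is.finite(snr) && snr > 0) 1 / snr else 0
      logf("phantom: ", sum(truth$mask), " voxels, ", n_subj,
           " subject(s), SNR ", snr)
      dwis <- lapply(seq_len(n_subj), function(s) {
        simulate_dwi(truth, s0 = 1, noise_sigma = sigma,
                     rng_seed = config$rng_seed * 1000L + s)
      })
      write_phantom(truth, dwis[[1]], out_dir)
      mask <- truth$mask
      affine <- truth$affine
      ac <- truth$ac_point
      result$truth <- truth
    } else {
      dwi_v <- read_nifti(config$input$dwi)
      scheme <- read_gradient_table(config$input$bvec, config$input$bval)
      dwis <- list(structure(list(signal = dwi_v$data, scheme = scheme,
                                  voxel_size = dwi_v$voxel_size,
                                  affine = dwi_v$affine),
                             class = "dwi_volume"))
      mv <- read_mask(config$input$mask)
      mask <- mv$data
      affine <- mv$affine
      ac <- as.numeric(config$input$ac_point)
      logf("input: ", config$input$dwi)
    }

    stage <- "tensorfit"
    fields <- lapply(dwis, fit_tensors, mask = mask)
    write_tensor_maps(fields[[1]], out_dir)
    logf("tensors: mean FA ", round(mean(fields[[1]]$fa), 4))

    stage <- "axis"
    spline <- fit_longitudinal_spline(mask, affine, ac,
                                      n_samples = config$n_samples)
    profiles <- lapply(seq_along(fields), function(s) {
      radiality_profile(fields[[s]], spline, subject = s)
    })
    for (s in seq_along(profiles)) {
      write_profile_csv(profiles[[s]],
                        file.path(out_dir, sprintf("profile_s%02d.csv", s)))
    }
    group <- detect_group_boundaries(profiles,
                                     central_window = config$central_window,
                                     head_window = config$head_window)
    write_boundaries_json(group, file.path(out_dir, "boundaries_group.json"))
    subj <- refine_subject_boundaries(profiles[[1]], group,
                                      radius = config$search_radius)
    write_boundaries_json(subj, file.path(out_dir, "boundaries_subject.json"))
    logf("boundaries: group b45 ", round(group$b_45, 3), " mm, bmin ",
         round(group$b_min, 3), " mm")

    stage <- "segment"
    labels <- segment_cn(mask, spline, group, affine)
    write_nifti(labels, file.path(out_dir, "labels.nii.gz"), affine, "int16")

    stage <- "tracking"
    tp <- config$tracking
    dfield <- tensor_direction_field(fields[[1]])
    sset <- track_streamlines(dfield, mask, n_seeds = tp$n_seeds,
                              step = tp$step,
                              curvature_radius = tp$curvature_radius,
                              min_length = tp$min_length,
                              cutoff = tp$cutoff,
                              cutoff_mode = tp$cutoff_mode,
                              rng_seed = config$rng_seed * 1000L + 777L)
    write_tck(sset, file.path(out_dir, "streamlines.tck"))
    logf("tracking: ", length(sset$streamlines), " of ", tp$n_seeds,
         " streamlines retained (step ", tp$step, " mm, R ",
         tp$curvature_radius, " mm, min ", tp$min_length, " mm, cutoff ",
         tp$cutoff, " ", tp$cutoff_mode, ")")

    stage <- "bundles"
    rules <- if (!is.null(config$rule_file)) {
      read_bundle_rules(config$rule_file)
    } else list()
    assign <- if (length(rules)) classify_bundles(sset, rules, affine)
    else rep("unassigned", length(sset$streamlines))
    utils::write.csv(data.frame(streamline = seq_along(assign),
                                bundle = assign),
                     file.path(out_dir, "bundles.csv"), row.names = FALSE)

    stage <- "targets"
    dens <- endpoint_density(sset, labels, affine)
    for (nm in names(dens)) {
      write_nifti(dens[[nm]],
                  file.path(out_dir, paste0("endpoints_", nm, ".nii.gz")),
                  affine)
    }
    logf("targets: ", paste(names(dens), vapply(dens, sum, numeric(1)),
                            collapse = ", "))

    result <- c(result, list(
      fields = fields, spline = spline, profiles = profiles,
      group_boundaries = group, subject_boundaries = subj,
      labels = labels, streamlines = sset, bundles = assign,
      endpoint_density = dens, out_dir = out_dir
    ))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         " (completed artifacts remain in ", out_dir, ")", call. = FALSE)
  })
  invisible(result)
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline: `--config cfg.json --out dir
#' [--seed N]`), `phantom` (`--out dir [--seed N] [--snr X]`), `typical`
#' (`--costs file.csv`: prints the most typical subject index). Invoked by
#' the `inst/cli/cnparcel` wrapper script.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
cnparcel_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: cnparcel <run|phantom|typical> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    opt[[key]] <- if (i + 1 <= length(rest)) rest[i + 1] else NA
    i <- i + 2
  }
  seed <- as.integer(opt$seed %||% 1)
  switch(cmd,
    run = {
      cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
      else pipeline_config(rng_seed = seed)
      cfg$rng_seed <- seed
      run_pipeline(cfg, opt$out %||% "cnparcel_out")
      cat("pipeline complete:", opt$out %||% "cnparcel_out", "\n")
    },
    phantom = {
      truth <- make_cn_phantom()
      snr <- as.numeric(opt$snr %||% 20)
      dwi <- simulate_dwi(truth, noise_sigma = if (snr > 0) 1 / snr else 0,
                          rng_seed = seed)
      write_phantom(truth, dwi, opt$out %||% "phantom_out")
      cat("phantom written to", opt$out %||% "phantom_out", "\n")
    },
    typical = {
      cm <- as.matrix(utils::read.csv(opt$costs, header = FALSE))
      cat("most typical subject:", choose_typical_subject(cm), "\n")
    },
    {
      cat("unknown subcommand:", cmd, "\n")
      return(invisible(1L))
    }
  )
  invisible(0L)
}
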