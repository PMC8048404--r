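#' Project configuration
#'
#' All settings of a processing run, saveable as a YAML preset and reloaded
#' for subsequent scans. Angle grids may be given as explicit vectors or as
#' `list(min =, max =, step =)`.
#'
#' @param input_dir directory with one subdirectory per perspective, each
#'   named `x{+ddd}_y{ddd}` and holding that perspective's focal stack.
#' @param output_dir directory for EDOF images, masks, cut-outs and the
#'   `.sfm` scene.
#' @param x_angles,y_angles numeric vectors or `list(min, max, step)`.
#' @param radius camera-to-centre distance, mm.
#' @param intrinsics a [camera_intrinsics()] or the corresponding named list.
#' @param focus_threshold [select_focused()] cutoff.
#' @param mask a [mask_params()] or corresponding named list.
#' @param cutout_mode `"alpha"` or `"zero"`.
#' @param grey_projector `"average"` or `"l_star"` (blending contrast
#'   analysis).
#' @param blend_window local-contrast window for [blend_hard_mask()].
#' @return an object of class `"project_config"`.
#' @export
project_config <- function(input_dir, output_dir,
                           x_angles = list(min = 0, max = 0, step = 1),
                           y_angles = list(min = 0, max = 359, step = 90),
                           radius = 150,
                           intrinsics = NULL,
                           focus_threshold = 0,
                           mask = mask_params(),
                           cutout_mode = "zero",
                           grey_projector = "average",
                           blend_window = 7L) {
  expand_angles <- function(a) {
    if (is.list(a)) seq(a$min, a$max, by = a$step) else as.numeric(a)
  }
  if (is.list(intrinsics) && !inherits(intrinsics, "camera_intrinsics"))
    intrinsics <- do.call(camera_intrinsics, intrinsics)
  if (is.list(mask) && !inherits(mask, "mask_params"))
    mask <- do.call(mask_params, mask)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 x_angles = expand_angles(x_angles),
                 y_angles = expand_angles(y_angles),
                 radius = radius, intrinsics = intrinsics,
                 focus_threshold = focus_threshold, mask = mask,
                 cutout_mode = match.arg(cutout_mode, c("zero", "alpha")),
                 grey_projector = match.arg(grey_projector,
                                            c("average", "l_star")),
                 blend_window = as.integer(blend_window)),
            class = "project_config")
}

#' Save / load a project configuration as YAML
#'
#' Round-trips losslessly: `load_config(save_config(cfg, f))` reproduces the
#' configuration.
#'
#' @param config a [project_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   `"project_config"`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "project_config"))
  lst <- unclass(config)
  lst$intrinsics <- if (!is.null(lst$intrinsics)) unclass(lst$intrinsics)
  lst$mask <- unclass(lst$mask)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  lst <- yaml::read_yaml(path)
  project_config(input_dir = lst$input_dir, output_dir = lst$output_dir,
                 x_angles = lst$x_angles, y_angles = lst$y_angles,
                 radius = lst$radius, intrinsics = lst$intrinsics,
                 focus_threshold = lst$focus_threshold,
                 mask = lst$mask, cutout_mode = lst$cutout_mode,
                 grey_projector = lst$grey_projector,
                 blend_window = lst$blend_window)
}

perspective_name <- function(x_deg, y_deg)
  sprintf("x%+04d_y%03d", round(x_deg), round(y_deg))

#' Run the full processing pipeline over a project
#'
#' For every perspective directory: focus-filter the stack, align it to the
#' most distal plane, blend the hard-mask EDOF image, mask it, write the
#' mask and cut-out, and embed the camera metadata in the cut-out. After all
#' perspectives, the analytic pose grid is written as `scene.sfm`. The stage
#' order is fixed; each stage's outputs fully determine the next stage's
#' inputs, so perspectives are independent and the run is deterministic for
#' a given configuration.
#'
#' Expected layout: `input_dir/x{+ddd}_y{ddd}/*.png|tif`, one subdirectory
#' per (x, y) grid point. A missing perspective directory is an error; stage
#' warnings (e.g. an empty mask) are collected in the report without
#' aborting the remaining perspectives.
#'
#' @param config a [project_config()].
#' @return run report: data frame with one row per perspective (`perspective`,
#'   `n_input`, `n_retained`, `warnings`, `cutout`), with the scene path in
#'   the `"sfm"` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "project_config"))
  if (!dir.exists(config$input_dir))
    stop("run_pipeline: input directory not found: ", config$input_dir)
  grid <- expand.grid(y = config$y_angles, x = config$x_angles)
  pnames <- perspective_name(grid$x, grid$y)
  dirs <- file.path(config$input_dir, pnames)
  missing <- !dir.exists(dirs)
  if (all(missing)) stop("run_pipeline: no perspective directories in ",
                         config$input_dir)
  if (any(missing)) stop("run_pipeline: missing perspective directories: ",
                         paste(pnames[missing], collapse = ", "))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(pnames))
  for (i in seq_along(pnames)) {
    sf_log("INFO", "perspective ", pnames[i], ": stacking")
    stack <- read_stack_dir(dirs[i], perspective_id = c(grid$x[i], grid$y[i]))
    n_in <- length(stack)
    warns <- character(0)
    withCallingHandlers({
      kept <- select_focused(stack, config$focus_threshold)
      if (length(kept) == 0L) {
        rows[[i]] <- data.frame(perspective = pnames[i], n_input = n_in,
                                n_retained = 0L,
                                warnings = "no in-focus image",
                                cutout = NA_character_)
        return_flag <- TRUE
      } else return_flag <- FALSE
      if (!return_flag) {
        aligned <- align_stack(kept)
        blend <- blend_hard_mask(aligned$stack, window = config$blend_window,
                                 grey_projector = config$grey_projector)
        res <- mask_pipeline(blend$edof, config$mask, mode = config$cutout_mode)
        edof_path <- file.path(config$output_dir,
                               paste0(pnames[i], "_edof.png"))
        mask_path <- file.path(config$output_dir,
                               paste0(pnames[i], "_mask.png"))
        cut_path <- file.path(config$output_dir,
                              paste0(pnames[i], "_cutout.png"))
        write_image(blend$edof, edof_path)
        write_mask(res$mask, mask_path)
        write_image(res$cutout, cut_path)
        if (!is.null(config$intrinsics)) {
          write_exif(cut_path, config$intrinsics)
          write_exif(edof_path, config$intrinsics)
        }
        rows[[i]] <- data.frame(perspective = pnames[i], n_input = n_in,
                                n_retained = length(kept),
                                warnings = if (res$empty) "empty mask" else "",
                                cutout = cut_path)
      }
    }, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    if (length(warns) && !is.na(rows[[i]]$cutout))
      rows[[i]]$warnings <- paste(c(rows[[i]]$warnings[nzchar(rows[[i]]$warnings)],
                                    warns), collapse = "; ")
  }
  report <- do.call(rbind, rows)
  sfm_path <- NA_character_
  if (!is.null(config$intrinsics)) {
    cfg <- scan_config(config$x_angles, config$y_angles, config$radius,
                       config$intrinsics,
                       image_names = paste0(pnames, "_cutout.png"))
    scene <- pose_grid(cfg)
    sfm_path <- file.path(config$output_dir, "scene.sfm")
    write_sfm(scene, sfm_path)
  }
  attr(report, "sfm") <- sfm_path
  sf_log("INFO", "pipeline complete: ", nrow(report), " perspectives")
  report
}
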