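#' Read a stabilization run configuration from YAML
#'
#' The schema mirrors [stab_config()]:
#'
#' ```yaml
#' seed: 7
#' period_ms: 62.5
#' stacks:
#'   x: {range_nm: 200, step_nm: 20, settle_buffer_ms: 100}
#'   y: {range_nm: 200, step_nm: 20}
#'   z: {range_nm: 200, step_nm: 20}
#' gains: {kp: 0.6, ki: 0.05, kii: 0.001, output_limit_nm: 100}
#' calibration: {x: 1.0, y: 1.0, z: 1.0}
#' ```
#'
#' Missing blocks take the package defaults; a malformed field is
#' reported with its schema path.
#'
#' @param path YAML file.
#' @param seed_override Optional seed taking precedence over the file.
#' @return A `stab_config`.
#' @export
read_run_config <- function(path, seed_override = NULL) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  get_num <- function(block, field, default, where) {
    v <- block[[field]]
    if (is.null(v)) return(default)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config field ", where, ".", field, " must be a finite number")
    }
    v
  }
  mk_stack <- function(ax) {
    b <- raw$stacks[[ax]]
    axis_stack_config(ax,
                      range_nm = get_num(b, "range_nm", 200,
                                         paste0("stacks.", ax)),
                      step_nm = get_num(b, "step_nm", 20,
                                        paste0("stacks.", ax)),
                      settle_buffer_ms = get_num(b, "settle_buffer_ms", 100,
                                                 paste0("stacks.", ax)))
  }
  g <- raw$gains
  gains <- controller_gains(
    kp = get_num(g, "kp", 0.6, "gains"),
    ki = get_num(g, "ki", 0.05, "gains"),
    kii = get_num(g, "kii", 0.001, "gains"),
    output_limit_nm = get_num(g, "output_limit_nm", 100, "gains"),
    stage_limit_nm = get_num(g, "stage_limit_nm", 50000, "gains"))
  cal <- c(x = get_num(raw$calibration, "x", 1, "calibration"),
           y = get_num(raw$calibration, "y", 1, "calibration"),
           z = get_num(raw$calibration, "z", 1, "calibration"))
  seed <- if (!is.null(seed_override)) as.integer(seed_override)
          else as.integer(get_num(raw, "seed", 1, "(top level)"))
  stab_config(stack_x = mk_stack("x"), stack_y = mk_stack("y"),
              stack_z = mk_stack("z"), gains = gains, calibration = cal,
              period_ms = get_num(raw, "period_ms", 62.5, "(top level)"),
              max_consecutive_failures =
                get_num(raw, "max_consecutive_failures", 25, "(top level)"),
              seed = seed)
}

#' Read a scene/noise/drift description from YAML
#'
#' ```yaml
#' scene:
#'   pattern: holey_carbon
#'   field_px: [128, 128]
#'   pixel_size_nm: [75, 78]
#'   defocus_nm: 2000
#' noise: {frac_saturation: 0.7, read_sigma: 10}   # or omit for noiseless
#' drift: {kind: linear, rate_nm_per_iter: [0.5, 0, 0]}
#' stage: {settle_alpha: 1.0}
#' ```
#'
#' @param path YAML file.
#' @return List with `scene`, `noise` (possibly `NULL`), `drift`,
#'   `stage`.
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop("no such scene file: ", path)
  raw <- yaml::read_yaml(path)
  sc <- raw$scene
  if (is.null(sc)) stop("scene file ", path, " has no 'scene' block")
  scene_args <- sc[intersect(names(sc), names(formals(virtual_scene)))]
  unknown <- setdiff(names(sc), names(formals(virtual_scene)))
  if (length(unknown)) {
    stop("unknown scene field(s): ",
         paste0("scene.", unknown, collapse = ", "))
  }
  scene <- do.call(virtual_scene, scene_args)
  noise <- if (is.null(raw$noise)) NULL else {
    do.call(noise_model,
            raw$noise[intersect(names(raw$noise),
                                names(formals(noise_model)))])
  }
  drift <- if (is.null(raw$drift)) drift_model("none") else {
    do.call(drift_model,
            raw$drift[intersect(names(raw$drift),
                                names(formals(drift_model)))])
  }
  stage <- if (is.null(raw$stage)) stage_state() else {
    do.call(stage_state,
            raw$stage[intersect(names(raw$stage),
                                names(formals(stage_state)))])
  }
  list(scene = scene, noise = noise, drift = drift, stage = stage)
}

#' Rebuild a run configuration from a loop-log header
#'
#' Every log written by [write_loop_log()] embeds the fully resolved
#' configuration and seed in its first line, so the run can be
#' reproduced exactly from the log alone (plus the scene description the
#' header points to).
#'
#' @param header Parsed header list (attribute `header` of
#'   [read_loop_log()]).
#' @return A `stab_config` equal to the one that produced the log.
#' @export
config_from_header <- function(header) {
  mk <- function(s) axis_stack_config(s$axis, range_nm = s$range_nm,
                                      step_nm = s$step_nm,
                                      settle_buffer_ms = s$settle_buffer_ms)
  g <- header$gains
  stab_config(stack_x = mk(header$stacks$x),
              stack_y = mk(header$stacks$y),
              stack_z = mk(header$stacks$z),
              gains = controller_gains(kp = g$kp, ki = g$ki, kii = g$kii,
                                       output_limit_nm = g$output_limit_nm,
                                       stage_limit_nm = g$stage_limit_nm),
              calibration = unlist(header$calibration)[AXES],
              period_ms = header$period_ms,
              max_consecutive_failures = header$max_consecutive_failures,
              seed = header$seed)
}

# serialize the parts of a config that a log header needs for exact
# reproduction
config_header <- function(config, scene_path = NULL, extra = list()) {
  h <- list(
    seed = config$seed,
    period_ms = config$period_ms,
    stacks = lapply(config$stacks, function(s) {
      s[c("axis", "range_nm", "step_nm", "settle_buffer_ms")]
    }),
    gains = unclass(config$gains),
    calibration = as.list(config$calibration),
    max_consecutive_failures = config$max_consecutive_failures)
  if (!is.null(scene_path)) h$scene_file <- scene_path
  utils::modifyList(h, extra)
}
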