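#' Write a trajectory to CSV
#'
#' Plain-text CSV with header `t,agent_id,x,y,vx,vy`, numeric fields printed
#' with six decimals (micrometer-scale precision, far below model noise),
#' rows ordered time-major then id-minor.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ped_trajectory"))
  d <- traj$data[order(traj$data$t, traj$data$agent_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t,agent_id,x,y,vx,vy", con)
  if (nrow(d)) {
    writeLines(sprintf("%.6f,%d,%.6f,%.6f,%.6f,%.6f", d$t,
                       as.integer(d$agent_id), d$x, d$y, d$vx, d$vy), con)
  }
  invisible(path)
}

#' Read a trajectory file
#'
#' Reads either the package's own CSV dialect (`t,agent_id,x,y,vx,vy`) or
#' the whitespace-separated `id frame x y` dialect common to published
#' pedestrian-experiment trajectory archives, in which case frame numbers
#' are converted to seconds via `fps` and velocities are reconstructed by
#' forward differences.
#'
#' @param path input file path.
#' @param format `"auto"`, `"csv"` or `"id_frame_xy"`.
#' @param fps frame rate (frames/s) for the `id frame x y` dialect.
#' @param agents optional data.frame (`agent_id`, `r`, `w`); defaults are
#'   used otherwise.
#' @param period_x spatial period along x, if the trajectory comes from a
#'   periodic scenario.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "csv", "id_frame_xy"),
                            fps = 16, agents = NULL, period_x = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  if (format == "auto") {
    format <- if (grepl("^t,agent_id", first)) "csv" else "id_frame_xy"
  }
  if (format == "csv") {
    d <- read.csv(path)
    req <- c("t", "agent_id", "x", "y", "vx", "vy")
    if (!all(req %in% names(d)))
      stop("malformed trajectory CSV: expected header t,agent_id,x,y,vx,vy")
    bad <- which(!stats::complete.cases(d[req]))
    if (length(bad))
      stop("malformed row at line ", bad[1] + 1L, " of ", path)
  } else {
    raw <- utils::read.table(path, header = FALSE,
                             col.names = c("agent_id", "frame", "x", "y"),
                             colClasses = "character")
    for (cl in names(raw)) raw[[cl]] <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(!stats::complete.cases(raw))
    if (length(bad)) stop("malformed row at line ", bad[1], " of ", path)
    raw$t <- raw$frame / fps
    raw <- raw[order(raw$t, raw$agent_id), ]
    d <- do.call(rbind, lapply(split(raw, raw$agent_id), function(g) {
      n <- nrow(g)
      vx <- if (n > 1) c(diff(g$x) / diff(g$t), NA) else NA
      vy <- if (n > 1) c(diff(g$y) / diff(g$t), NA) else NA
      if (n > 1) {
        vx[n] <- vx[n - 1]
        vy[n] <- vy[n - 1]
      } else {
        vx <- 0; vy <- 0
      }
      data.frame(t = g$t, agent_id = g$agent_id, x = g$x, y = g$y,
                 vx = vx, vy = vy)
    }))
  }
  if (anyDuplicated(d[, c("t", "agent_id")])) {
    dup <- which(duplicated(d[, c("t", "agent_id")]))[1]
    stop("duplicate (t, agent_id) at data row ", dup)
  }
  trajectory(d, agents = agents, period_x = period_x)
}

#' Write a scenario to a YAML file
#'
#' Serializes the obstacle polygons (closed coordinate rings), spawn
#' specification, waypoint chains, measurement region and world bounds so
#' the scenario can be rebuilt byte-identically with [read_scenario()].
#'
#' @param scenario a `ped_scenario`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "ped_scenario"))
  lst <- list(
    name = scenario$name,
    bounds = scenario$bounds,
    mode = scenario$mode,
    period_x = scenario$period_x,
    seed = scenario$seed,
    defaults = scenario$defaults,
    polygons = lapply(scenario$polygons, function(p)
      list(x = as.numeric(p[, 1]), y = as.numeric(p[, 2]))),
    agents = as.list(scenario$agents),
    inflow = scenario$inflow,
    measurement = scenario$measurement,
    waypoints = if (is.null(scenario$waypoints)) NULL else
      lapply(scenario$waypoints, function(w)
        list(x = as.numeric(w$pts[, 1]), y = as.numeric(w$pts[, 2]),
             dwell = w$dwell, capture = w$capture,
             terminal = w$terminal)))
  yaml::write_yaml(lst, path, precision = 12)
  invisible(path)
}

#' Read a scenario from a YAML file
#'
#' @param path file written by [write_scenario()].
#' @return A `ped_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path)
  lst <- yaml::read_yaml(path)
  polys <- lapply(lst$polygons, function(p) cbind(p$x, p$y))
  agents <- as.data.frame(lst$agents)
  if (nrow(agents) == 0)
    agents <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                         dir = integer(0), pref_speed = numeric(0))
  wps <- if (is.null(lst$waypoints)) NULL else
    lapply(lst$waypoints, function(w)
      list(pts = cbind(w$x, w$y), dwell = w$dwell, capture = w$capture,
           terminal = w$terminal))
  new_scenario(lst$name, lst$bounds, polys, lst$mode, agents,
               waypoints = wps, inflow = lst$inflow,
               measurement = lst$measurement, period_x = lst$period_x,
               seed = lst$seed, defaults = lst$defaults)
}

#' Write a run manifest
#'
#' Records everything needed to replay a simulation bit-for-bit: the full
#' configuration, the seed, the package version and the output paths.
#'
#' @param path manifest path (YAML).
#' @param config the [simulation_config()] used.
#' @param scenario_path path of the scenario file used.
#' @param outputs named list/character of output paths.
#' @param elapsed wall time in seconds (informational only).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, scenario_path, outputs,
                               elapsed = NA_real_) {
  cfg <- unclass(config)
  cfg$filter <- unclass(cfg$filter)
  cfg$sf <- unclass(cfg$sf)
  yaml::write_yaml(list(
    package = "pedflow",
    version = as.character(utils::packageVersion("pedflow")),
    seed = config$seed,
    scenario = scenario_path,
    config = cfg,
    outputs = as.list(outputs),
    elapsed_s = elapsed), path)
  invisible(path)
}
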