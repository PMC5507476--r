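#' Write a trajectory to tabular text
#'
#' One row per circle per snapshot (id, coordinates, lineage, polarity
#' components, TE pair link, time, stage label), written as a single CSV
#' that round-trips losslessly through [read_trajectory()].
#'
#' @param trajectory a list of snapshot data frames (as recorded by
#'   [simulate_embryo()]) or a `blastosim_run`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  if (inherits(trajectory, "blastosim_run")) trajectory <- trajectory$trajectory
  if (length(trajectory) == 0) stop("empty trajectory")
  for (q in seq_along(trajectory)) trajectory[[q]]$snapshot <- q
  df <- do.call(rbind, trajectory)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path file path.
#' @return a list of snapshot data frames.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- split(df[setdiff(names(df), "snapshot")], df$snapshot)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Lineage colour palette
#'
#' TE blue, undetermined ICM white, epiblast green, PrE red.
#' @return a named character vector of colours.
#' @export
lineage_palette <- function() {
  c(TE = "#4575b4", UNDETERMINED_ICM = "#ffffff",
    EPI = "#1a9850", PRE = "#d73027")
}

#' Render trajectory snapshots as images
#'
#' Draws each 2D snapshot as unit circles coloured by lineage (TE blue,
#' undetermined white, epiblast green, PrE red), one PNG per snapshot.
#'
#' @param trajectory a list of snapshot data frames or a `blastosim_run`.
#' @param dir output directory (created if needed).
#' @param width,height image size in pixels.
#' @return character vector of file paths, invisibly.
#' @export
render_frames <- function(trajectory, dir, width = 640, height = 640) {
  if (inherits(trajectory, "blastosim_run")) trajectory <- trajectory$trajectory
  if (length(trajectory) == 0) stop("empty trajectory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pal <- lineage_palette()
  all_x <- unlist(lapply(trajectory, `[[`, "x"))
  all_y <- unlist(lapply(trajectory, `[[`, "y"))
  lim_x <- range(all_x) + c(-2, 2)
  lim_y <- range(all_y) + c(-2, 2)
  paths <- character(length(trajectory))
  for (q in seq_along(trajectory)) {
    snap <- trajectory[[q]]
    paths[q] <- file.path(dir, sprintf("frame_%03d.png", q))
    grDevices::png(paths[q], width = width, height = height)
    graphics::par(mar = c(1, 1, 2, 1))
    graphics::plot(NA, xlim = lim_x, ylim = lim_y, asp = 1, axes = FALSE,
                   xlab = "", ylab = "",
                   main = if (!is.null(snap$stage)) snap$stage[1] else "")
    graphics::symbols(snap$x, snap$y, circles = rep(1, nrow(snap)),
                      inches = FALSE, add = TRUE,
                      bg = pal[snap$lineage], fg = "grey30")
    te <- snap$lineage == "TE"
    if (any(te))
      graphics::arrows(snap$x[te], snap$y[te],
                       snap$x[te] + 1.5 * snap$pol_x[te],
                       snap$y[te] + 1.5 * snap$pol_y[te],
                       length = 0.05, col = "grey10")
    grDevices::dev.off()
  }
  invisible(paths)
}

#' Run manifest
#'
#' Everything needed to reproduce an ensemble exactly: the experiment name,
#' master seed, per-replicate seeds, package version and parameter echo.
#'
#' @param spec an [experiment_spec()].
#' @param path optional JSON output path.
#' @return the manifest list (invisibly written to `path` when given).
#' @export
run_manifest <- function(spec, path = NULL) {
  man <- list(
    experiment = spec$name,
    package_version = as.character(utils::packageVersion("blastosim")),
    master_seed = spec$seed,
    n_replicates = spec$n_replicates,
    replicate_seeds = replicate_seeds(spec$seed, spec$n_replicates),
    rules = unclass(spec$rules),
    schedule = unclass(spec$schedule),
    params = unclass(spec$params),
    manipulation = spec$manipulation,
    timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(man)
}

#' Write per-replicate outcomes and an ensemble summary
#'
#' @param ensemble a `blastosim_ensemble` from [run_ensemble()].
#' @param csv_path path for the per-replicate CSV.
#' @param json_path optional path for the JSON summary.
#' @return `csv_path`, invisibly.
#' @export
write_ensemble <- function(ensemble, csv_path, json_path = NULL) {
  write.csv(as.data.frame(ensemble), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    s <- attr(ensemble, "summary")
    jsonlite::write_json(s, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csv_path)
}
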