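# Plain-text readers/writers: TRC markers, force CSV, events JSON, feature
# table CSV with a units header row, YAML run configuration.

#' Write marker trajectories as TRC
#'
#' Standard tab-separated TRC with the usual two header blocks. Coordinates
#' are written in metres.
#'
#' @param markers named list of n x 3 matrices.
#' @param rate_hz marker sampling rate.
#' @param path output file.
#' @export
write_trc <- function(markers, rate_hz, path) {
  n <- nrow(markers[[1]])
  nm <- names(markers)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("PathFileType\t4\t(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(rate_hz, rate_hz, n, length(nm), "m", rate_hz, 1, n, sep = "\t"),
    paste0("Frame#\tTime\t",
           paste(vapply(nm, function(x) paste0(x, "\t\t"), ""), collapse = "\t")),
    paste0("\t\t", paste(unlist(lapply(seq_along(nm), function(i)
      paste0(c("X", "Y", "Z"), i))), collapse = "\t"))
  ), con)
  mat <- do.call(cbind, markers)
  tt <- (seq_len(n) - 1) / rate_hz
  utils::write.table(
    data.frame(seq_len(n), tt, mat),
    con, sep = "\t", row.names = FALSE, col.names = FALSE)
}

#' Read a TRC marker file
#' @param path TRC file written by [write_trc()] (or compatible).
#' @return list `markers` (named list of n x 3), `rate_hz`.
#' @export
read_trc <- function(path) {
  hdr <- readLines(path, n = 5)
  meta <- strsplit(hdr[3], "\t")[[1]]
  rate <- as.numeric(meta[1])
  labels <- strsplit(hdr[4], "\t")[[1]]
  labels <- labels[labels != "" & !(labels %in% c("Frame#", "Time"))]
  dat <- utils::read.table(path, skip = 5, sep = "\t", header = FALSE)
  markers <- list()
  for (i in seq_along(labels)) {
    cols <- 2 + (i - 1) * 3 + 1:3
    markers[[labels[i]]] <- as.matrix(dat[, cols])
  }
  list(markers = markers, rate_hz = rate)
}

#' Write force-plate channels as CSV
#' @param forces a `sampled_signal` with named channels.
#' @param path output file.
#' @export
write_force_csv <- function(forces, path) {
  df <- data.frame(time = signal_times(forces), forces$values)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read force-plate CSV
#' @param path file written by [write_force_csv()].
#' @return a `sampled_signal`.
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path)
  dt <- stats::median(diff(df$time))
  sampled_signal(as.matrix(df[, -1]), 1 / dt, df$time[1],
                 channels = names(df)[-1])
}

#' Write a complete synthetic trial to disk
#'
#' TRC markers + force CSV + JSON truth sidecar + JSON anthropometry.
#'
#' @param trial a `dj_trial`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return invisible vector of the written paths.
#' @export
write_trial <- function(trial, dir, stem = "trial") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(stem, ".trc"))
  p2 <- file.path(dir, paste0(stem, "_forces.csv"))
  p3 <- file.path(dir, paste0(stem, "_truth.json"))
  p4 <- file.path(dir, paste0(stem, "_anthro.json"))
  write_trc(trial$recording$markers, trial$recording$marker_rate_hz, p1)
  write_force_csv(trial$recording$forces, p2)
  tr <- trial$truth
  tr$com_z <- NULL; tr$com_times <- NULL; tr$ankle_moment_y <- NULL
  tr$joint_angle_profiles <- NULL
  jsonlite::write_json(unclass(tr), p3, auto_unbox = TRUE, digits = 10)
  jsonlite::write_json(trial$recording$anthropometry, p4, auto_unbox = TRUE)
  invisible(c(p1, p2, p3, p4))
}

#' Read a trial written by [write_trial()]
#' @param dir directory.
#' @param stem file-name stem.
#' @return list shaped like a `dj_trial$recording` (plus `truth` if present).
#' @export
read_trial <- function(dir, stem = "trial") {
  trc <- read_trc(file.path(dir, paste0(stem, ".trc")))
  forces <- read_force_csv(file.path(dir, paste0(stem, "_forces.csv")))
  anth <- jsonlite::read_json(file.path(dir, paste0(stem, "_anthro.json")),
                              simplifyVector = TRUE)
  rec <- list(markers = trc$markers, marker_rate_hz = trc$rate_hz,
              forces = forces, anthropometry = anth)
  tp <- file.path(dir, paste0(stem, "_truth.json"))
  out <- list(recording = rec)
  if (file.exists(tp))
    out$truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  out
}

#' Write a feature table with a units header row
#'
#' CSV whose first line is the schema version, second line the column names,
#' third line the units, then the data.
#'
#' @param tab feature table from [assemble_feature_table()].
#' @param path output file.
#' @export
write_feature_table <- function(tab, path) {
  units <- attr(tab, "units")
  if (is.null(units)) units <- rep("", ncol(tab))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# djpls feature table v1", con)
  writeLines(paste(names(tab), collapse = ","), con)
  writeLines(paste(units[names(tab)], collapse = ","), con)
  utils::write.table(tab, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

#' Read a feature table written by [write_feature_table()]
#' @param path file path.
#' @return data.frame with `units` attribute.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, n = 3)
  if (!startsWith(lines[1], "# djpls feature table"))
    stop("not a djpls feature table: ", path)
  nm <- strsplit(lines[2], ",")[[1]]
  un <- strsplit(lines[3], ",")[[1]]
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  names(dat) <- nm
  attr(dat, "units") <- stats::setNames(un, nm)
  dat
}

#' Default run configuration
#'
#' All tunable constants of the pipeline in one list; round-trips through
#' YAML unchanged.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    filter = list(cutoff_hz = 20, auto_residual = FALSE),
    force_threshold_n = 20,
    aggregate = "mean",
    cv = list(folds = 10, seed = 1, max_components = 10),
    cor_threshold = 0.95,
    vif_threshold = 10,
    vip_threshold = 1,
    filter_mode = "paper_faithful",  # or "leak_free"
    out_dir = "djpls_out"
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(cfg$cv$folds >= 2, cfg$force_threshold_n > 0,
            cfg$cor_threshold > 0, cfg$vif_threshold > 0)
  structure(cfg, class = "run_config")
}

#' Read/write run configuration as YAML
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
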