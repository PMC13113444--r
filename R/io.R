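# File I/O: TRC marker trajectories, subject configuration, force-profile
# and reference-waveform CSVs. TRC is the tab-separated marker format of
# optical motion-capture systems; no established R reader exists, so a
# minimal one is provided here.

#' Write landmark trajectories to a TRC file
#'
#' Writes a standard tab-separated TRC marker file (header with rates,
#' frame counts, units and marker names; one row per frame with
#' X/Y/Z triplets). Foot-strike events are written to a sidecar CSV
#' (`<path>.events.csv`, columns `side`, `time_s`).
#'
#' @param trial A `gait_trial` (its `landmarks` are written), or a named
#'   list of Tx3 marker matrices with attributes supplied via `time` and
#'   `rate_hz`.
#' @param path Output file path.
#' @param time,rate_hz Required when `trial` is a plain list of matrices.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trial, path, time = trial$time,
                      rate_hz = trial$rate_hz) {
  markers <- if (inherits(trial, "gait_trial")) trial$landmarks else trial
  nm <- names(markers)
  nT <- length(time)
  head1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  head2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                 "Units", "OrigDataRate", "OrigDataStartFrame",
                 "OrigNumFrames", sep = "\t")
  head3 <- paste(rate_hz, rate_hz, nT, length(nm), "mm", rate_hz, 1, nT,
                 sep = "\t")
  head4 <- paste(c("Frame#", "Time",
                   as.vector(rbind(nm, "", ""))), collapse = "\t")
  head5 <- paste(c("", "", as.vector(vapply(seq_along(nm), function(i)
    paste0(c("X", "Y", "Z"), i), character(3)))), collapse = "\t")
  dat <- do.call(cbind, markers)
  body <- vapply(seq_len(nT), function(k)
    paste(c(k, sprintf("%.5f", time[k]), sprintf("%.5f", dat[k, ])),
          collapse = "\t"), character(1))
  writeLines(c(head1, head2, head3, head4, head5, body), path)
  if (inherits(trial, "gait_trial")) {
    ev <- rbind(data.frame(side = "right", time_s = trial$events_right),
                data.frame(side = "left", time_s = trial$events_left))
    utils::write.csv(ev, paste0(path, ".events.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a TRC marker-trajectory file
#'
#' @param path TRC file path.
#' @return List with `rate_hz`, `time`, and `markers` (named list of Tx3
#'   matrices, mm). Events are read from a `<path>.events.csv` sidecar if
#'   present (`events_right`, `events_left`).
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L || !startsWith(lines[1], "PathFileType"))
    stop("not a TRC file: ", path)
  meta <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(meta[1])
  names_row <- strsplit(lines[4], "\t")[[1]]
  nm <- names_row[-(1:2)]
  nm <- nm[nzchar(nm)]
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t")
  time <- dat[[2]]
  markers <- lapply(seq_along(nm), function(i) {
    m <- as.matrix(dat[, 2 + (3 * (i - 1) + 1):(3 * i), drop = FALSE])
    dimnames(m) <- NULL
    m
  })
  names(markers) <- nm
  out <- list(rate_hz = rate, time = time, markers = markers)
  evp <- paste0(path, ".events.csv")
  if (file.exists(evp)) {
    ev <- utils::read.csv(evp)
    out$events_right <- ev$time_s[ev$side == "right"]
    out$events_left <- ev$time_s[ev$side == "left"]
  }
  out
}

#' Read marker trajectories from a plain CSV file
#'
#' Fallback format: a `time` column plus `<marker>_x`, `<marker>_y`,
#' `<marker>_z` columns in millimetres.
#'
#' @param path CSV file path.
#' @return Same structure as [read_trc()] (without events).
#' @export
read_marker_csv <- function(path) {
  dat <- utils::read.csv(path)
  if (!"time" %in% names(dat)) stop("marker CSV needs a 'time' column")
  cols <- setdiff(names(dat), "time")
  base <- unique(sub("_[xyz]$", "", cols))
  markers <- lapply(base, function(b) {
    need <- paste0(b, "_", c("x", "y", "z"))
    if (!all(need %in% cols)) stop("incomplete x/y/z triplet for ", b)
    unname(as.matrix(dat[, need]))
  })
  names(markers) <- base
  dt <- diff(dat$time)
  list(rate_hz = 1 / stats::median(dt), time = dat$time, markers = markers)
}

#' Read a subject configuration file
#'
#' JSON or YAML with keys `height_mm`, `mass_kg`, optional
#' `sitting_height_mm`, optional `sternum_head_mm`, and
#' `segment_lengths_mm` (a map segment name -> length in mm).
#'
#' @param path Path to `.json`, `.yml` or `.yaml`.
#' @return An [anthro_profile()].
#' @export
read_subject_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  anthro_profile(height_mm = cfg$height_mm, mass_kg = cfg$mass_kg,
                 segment_lengths_mm = unlist(cfg$segment_lengths_mm),
                 sitting_height_mm = cfg$sitting_height_mm,
                 sternum_head_mm = cfg$sternum_head_mm)
}

#' Write force profiles to a long-format CSV
#'
#' One row per muscle and grid point: columns `muscle`, `cycle_pct`,
#' `active`, `passive`, `applied_offset_pct`.
#'
#' @param profiles Named list of [force_profile()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_force_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(muscle = p$muscle, cycle_pct = p$grid, active = p$active,
               passive = p$passive, applied_offset_pct = p$applied_offset_pct))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read force profiles from a long-format CSV
#'
#' @param path CSV as written by [write_force_profiles()].
#' @return Named list of [force_profile()]s.
#' @export
read_force_profiles <- function(path) {
  dat <- utils::read.csv(path)
  out <- lapply(split(dat, dat$muscle), function(d) {
    d <- d[order(d$cycle_pct), ]
    force_profile(d$muscle[1], d$active, d$passive,
                  d$applied_offset_pct[1])
  })
  out[unique(dat$muscle)]
}

#' Read reference waveforms from a wide CSV
#'
#' Expects a `cycle_pct` column (0-100) plus one column per muscle;
#' waveforms are interpolated onto the 101-point grid if needed.
#'
#' @param path CSV file path.
#' @return Named list of length-101 numeric series.
#' @export
read_reference_waveforms <- function(path) {
  dat <- utils::read.csv(path)
  if (!"cycle_pct" %in% names(dat))
    stop("reference CSV needs a 'cycle_pct' column")
  grid <- 0:100
  out <- lapply(setdiff(names(dat), "cycle_pct"), function(m)
    stats::approx(dat$cycle_pct, dat[[m]], xout = grid, rule = 2)$y)
  names(out) <- setdiff(names(dat), "cycle_pct")
  out
}
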