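TRACK_LABELS <- c("midline", "left_margin", "right_margin")

#' Assemble a validated set of tracked organ curves
#'
#' A `track_set` holds the three ordered 3D point tracks of one organ:
#' the midline (central vasculature) and the left and right margins.
#' Point order matters: index 0 is the blade--petiole junction end, the
#' origin from which arc length and cumulative angles are measured.
#' Coordinates are stored in micrometres, right-handed axes, z = imaging
#' axis.
#'
#' @param midline,left_margin,right_margin numeric matrices with 3 columns
#'   (x, y, z) and at least 4 rows each, in tracking order.
#' @param unit_scale length-3 numeric, per-axis multiplier converting the
#'   supplied coordinates to micrometres (use the voxel size when tracks
#'   are in voxel units). Default `c(1, 1, 1)` means coordinates are
#'   already in micrometres.
#' @param source_id free-text sample identifier.
#' @return An object of class `track_set`: a list with elements `tracks`
#'   (named list of 3-column matrices in micrometres), `unit_scale` and
#'   `source_id`.
#' @examples
#' z <- seq(0, 3200, by = 200)
#' ts <- track_set(cbind(0, 0, z), cbind(100, 0, z), cbind(-100, 0, z))
#' ts
#' @export
track_set <- function(midline, left_margin, right_margin,
                      unit_scale = c(1, 1, 1), source_id = "") {
  tracks <- list(midline = midline, left_margin = left_margin,
                 right_margin = right_margin)
  unit_scale <- as.numeric(unit_scale)
  if (length(unit_scale) != 3 || any(!is.finite(unit_scale)) ||
      any(unit_scale <= 0)) {
    stop("unit_scale must be three positive finite numbers", call. = FALSE)
  }
  tracks <- lapply(tracks, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 3) stop("each track needs 3 coordinate columns", call. = FALSE)
    sweep(m, 2, unit_scale, `*`)
  })
  for (lab in TRACK_LABELS) {
    m <- tracks[[lab]]
    if (nrow(m) < 4) {
      stop(sprintf("track '%s' has %d points; at least 4 are required for cubic fitting",
                   lab, nrow(m)), call. = FALSE)
    }
    if (any(!is.finite(m))) {
      stop(sprintf("track '%s' contains non-finite coordinates", lab), call. = FALSE)
    }
    step <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
    if (any(step <= 0)) {
      stop(sprintf("track '%s' has duplicated consecutive positions", lab),
           call. = FALSE)
    }
  }
  structure(list(tracks = tracks, unit_scale = unit_scale,
                 source_id = as.character(source_id)[1]),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  n <- vapply(x$tracks, nrow, integer(1))
  chord <- vapply(x$tracks, function(m) {
    sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
  }, numeric(1))
  cat("Tracked organ curves", if (nzchar(x$source_id)) paste0("(", x$source_id, ")"),
      "\n")
  for (lab in TRACK_LABELS) {
    cat(sprintf("  %-13s %4d points, chord length %.1f um\n", lab, n[[lab]],
                chord[[lab]]))
  }
  invisible(x)
}

#' Read tracked curves from the canonical CSV interchange format
#'
#' The canonical tracks file is a comma-delimited UTF-8 table with header
#' exactly `track,point,x,y,z`. `track` is one of `midline`,
#' `left_margin`, `right_margin`; `point` is the 0-based ordinal along the
#' track with 0 at the blade--petiole junction end; x, y, z are
#' coordinates in micrometres (or voxels, combined with `unit_scale`).
#'
#' @param path path to the CSV file (or a connection).
#' @param unit_scale per-axis micrometre multiplier applied to x, y, z
#'   (default identity).
#' @return a [track_set].
#' @examples
#' # a synthetic twisted petiole shipped with the package
#' path <- system.file("extdata", "synthetic_petiole_tracks.csv",
#'                     package = "rodtwist")
#' tracks <- read_tracks_csv(path)
#' tracks
#' @export
read_tracks_csv <- function(path, unit_scale = c(1, 1, 1)) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  expected <- c("track", "point", "x", "y", "z")
  if (!identical(names(df), expected)) {
    stop(sprintf("tracks CSV header must be exactly '%s' (got '%s')",
                 paste(expected, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
  bad_lab <- setdiff(unique(df$track), TRACK_LABELS)
  if (length(bad_lab)) {
    stop(sprintf("unknown track label: %s", paste(bad_lab, collapse = ", ")),
         call. = FALSE)
  }
  missing_lab <- setdiff(TRACK_LABELS, unique(df$track))
  if (length(missing_lab)) {
    stop(sprintf("missing track: %s", paste(missing_lab, collapse = ", ")),
         call. = FALSE)
  }
  num <- lapply(df[c("point", "x", "y", "z")], function(col) {
    suppressWarnings(as.numeric(col))
  })
  bad_row <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad_row)) {
    stop(sprintf("non-numeric coordinate in tracks CSV at data row %d", bad_row[1]),
         call. = FALSE)
  }
  df$point <- num$point; df$x <- num$x; df$y <- num$y; df$z <- num$z
  df <- df[order(match(df$track, TRACK_LABELS), df$point), ]
  tr <- lapply(split(df, factor(df$track, levels = TRACK_LABELS)), function(d) {
    if (!identical(as.integer(d$point), seq_len(nrow(d)) - 1L)) {
      stop(sprintf("track '%s': point indices must be unique and contiguous from 0",
                   d$track[1]), call. = FALSE)
    }
    as.matrix(d[, c("x", "y", "z")])
  })
  track_set(tr$midline, tr$left_margin, tr$right_margin,
            unit_scale = unit_scale,
            source_id = if (is.character(path)) basename(path) else "")
}

#' Write a track set to the canonical CSV format
#'
#' Inverse of [read_tracks_csv()]; coordinates are written in micrometres
#' with 0-based point indices.
#'
#' @param tracks a [track_set].
#' @param path destination path.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  lines <- "track,point,x,y,z"
  for (lab in TRACK_LABELS) {
    m <- tracks$tracks[[lab]]
    lines <- c(lines, sprintf("%s,%d,%.17g,%.17g,%.17g", lab,
                              seq_len(nrow(m)) - 1L, m[, 1], m[, 2], m[, 3]))
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Read tracked curves from an MTrackJ-style data file
#'
#' Minimal permissive reader for the track/point block structure of
#' MTrackJ `.mdf` exports: lines beginning with `Track` start a new track
#' and lines beginning with `Point` carry `id x y z ...` fields. The first
#' three tracks are interpreted positionally as midline, left margin and
#' right margin, matching the tracking convention in which track 1 is the
#' midvein and tracks 2 and 3 are the margins. Coordinates are scaled from
#' voxels to micrometres with `voxel_size`. Known structural headers
#' (`MTrackJ`, `Displaying`, `Offset`, `Assembly`, `Cluster`, `End`) are
#' skipped silently; other unrecognized lines are skipped with a warning.
#' This is not a full implementation of the MTrackJ format; the CSV format
#' of [read_tracks_csv()] is the canonical interchange.
#'
#' @param path path to the mdf file.
#' @param voxel_size length-3 numeric, micrometres per voxel along x, y, z.
#' @return a [track_set].
#' @export
read_mtrackj_mdf <- function(path, voxel_size = c(1, 1, 1)) {
  lines <- readLines(path, warn = FALSE)
  known <- "^(MTrackJ|Displaying|Offset|Assembly|Cluster|End)\\b"
  tracks <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^Track\\b", ln)) {
      if (!is.null(cur)) tracks <- c(tracks, list(cur))
      cur <- list()
    } else if (grepl("^Point\\b", ln)) {
      if (is.null(cur)) {
        stop(sprintf("mdf line %d: point line before any track header", i),
             call. = FALSE)
      }
      fields <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]][-1]))
      if (length(fields) < 4 || any(is.na(fields[1:4]))) {
        stop(sprintf("mdf line %d: cannot parse point line", i), call. = FALSE)
      }
      cur <- c(cur, list(fields[2:4]))
    } else if (!grepl(known, ln)) {
      warning(sprintf("mdf line %d: skipping unrecognized line", i), call. = FALSE)
    }
  }
  if (!is.null(cur)) tracks <- c(tracks, list(cur))
  if (length(tracks) < 3) {
    stop(sprintf("mdf file has %d track(s); three are required (midline, left margin, right margin)",
                 length(tracks)), call. = FALSE)
  }
  mats <- lapply(tracks[1:3], function(tr) do.call(rbind, tr))
  track_set(mats[[1]], mats[[2]], mats[[3]], unit_scale = voxel_size,
            source_id = basename(path))
}

PROFILE_HEADER <- paste("s_um", "tau_rad_per_um", "kappa1_rad_per_um",
                        "kappa2_rad_per_um", "twist_cum_deg",
                        "bend_lat_cum_deg", "bend_vert_cum_deg", sep = ",")

profile_df <- function(profile) {
  if (inherits(profile, "rod_deformation")) profile$profile else as.data.frame(profile)
}

#' Write a deformation profile to CSV
#'
#' One row per arc-length grid point. Local rates are written in
#' rad/micrometre; cumulative angle columns are written in degrees.
#' Values survive a write/read round trip to at least 12 significant
#' digits.
#'
#' @param profile a `rod_deformation` object or its profile data frame
#'   (columns `s_um`, `tau`, `kappa1`, `kappa2`, `twist_cum`,
#'   `bend_lat_cum`, `bend_vert_cum`; rates in rad/um, cumulative angles
#'   in rad).
#' @param path destination path.
#' @export
write_profile_csv <- function(profile, path) {
  p <- profile_df(profile)
  if (nrow(p) == 0) stop("profile is empty", call. = FALSE)
  cols <- c("s_um", "tau", "kappa1", "kappa2", "twist_cum", "bend_lat_cum",
            "bend_vert_cum")
  if (!all(cols %in% names(p))) {
    stop("profile is missing required columns", call. = FALSE)
  }
  vals <- as.matrix(p[, cols])
  if (any(!is.finite(vals))) {
    stop("profile contains non-finite values", call. = FALSE)
  }
  deg <- 180 / pi
  rows <- sprintf("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g",
                  p$s_um, p$tau, p$kappa1, p$kappa2,
                  p$twist_cum * deg, p$bend_lat_cum * deg, p$bend_vert_cum * deg)
  writeLines(c(PROFILE_HEADER, rows), path)
  invisible(NULL)
}

#' Read a deformation profile written by [write_profile_csv()]
#'
#' @param path path to the profile CSV.
#' @return a data frame with rates in rad/um and cumulative angles in rad
#'   (the package-internal representation).
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  expected <- strsplit(PROFILE_HEADER, ",")[[1]]
  if (!identical(names(df), expected)) {
    stop("not a profile CSV: unexpected header", call. = FALSE)
  }
  rad <- pi / 180
  data.frame(s_um = df$s_um, tau = df$tau_rad_per_um,
             kappa1 = df$kappa1_rad_per_um, kappa2 = df$kappa2_rad_per_um,
             twist_cum = df$twist_cum_deg * rad,
             bend_lat_cum = df$bend_lat_cum_deg * rad,
             bend_vert_cum = df$bend_vert_cum_deg * rad)
}
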