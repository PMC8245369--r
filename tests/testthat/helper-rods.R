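# Fixtures built in code: simple axis-aligned rods and wavy tracks.

DEG_PER_MM <- pi / 180 / 1000  # deg/mm -> rad/um

# Straight rod along +z with margins at +/- radius on x; the axis-aligned
# configuration in which the material frame is known exactly.
straight_rod_tracks <- function(length_um = 3200, radius_um = 100,
                                spacing_um = 100) {
  z <- seq(0, length_um, by = spacing_um)
  track_set(cbind(0, 0, z), cbind(radius_um, 0, z), cbind(-radius_um, 0, z))
}

# Apply one rotation matrix + translation to every track of a track_set.
transform_tracks <- function(ts, R = diag(3), t = c(0, 0, 0)) {
  tr <- lapply(ts$tracks, function(m) sweep(m %*% t(R), 2, t, `+`))
  track_set(tr$midline, tr$left_margin, tr$right_margin,
            source_id = ts$source_id)
}

rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Wavy 40-point track whose curvature changes sign 12 times: the fixture
# on which global poly9/gauss8 fits must misfit while cubic interpolation
# is exact.
wavy_track <- function() {
  t <- seq(0, 1, length.out = 40)
  cbind(3200 * t, 30 * sin(13 * pi * t), 15 * cos(9 * pi * t))
}

interior <- function(s, margin_um) {
  s >= margin_um & s <= max(s) - margin_um
}

# Minimal MTrackJ-style fixture: 3 tracks x 4 points in voxel units.
write_mdf_fixture <- function(path) {
  writeLines(c(
    "MTrackJ 1.5.1 Data File",
    "Assembly 1",
    "Cluster 1",
    "Track 1",
    "Point 1 10.0 10.0 1.0 1.0 1",
    "Point 2 10.5 10.0 2.0 1.0 1",
    "Point 3 11.0 10.5 3.0 1.0 1",
    "Point 4 11.0 11.0 4.0 1.0 1",
    "Track 2",
    "Point 1 20.0 10.0 1.0 1.0 1",
    "Point 2 20.5 10.0 2.0 1.0 1",
    "Point 3 21.0 10.5 3.0 1.0 1",
    "Point 4 21.0 11.0 4.0 1.0 1",
    "Track 3",
    "Point 1 0.0 10.0 1.0 1.0 1",
    "Point 2 0.5 10.0 2.0 1.0 1",
    "Point 3 1.0 10.5 3.0 1.0 1",
    "Point 4 1.0 11.0 4.0 1.0 1",
    "End of MTrackJ Data File"), path)
  path
}
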