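#' Read and write MRC volumes
#'
#' Minimal, standards-conforming MRC2014 I/O for mode 2 (float32) volumes
#' and stacks. On disk, MRC columns/rows/sections map to (x, y, z) with z
#' the beam axis. `write_volume` stores the voxel size in the cell header;
#' mode 2 round trips are bit-exact at float32 precision and the voxel
#' size survives to 1e-4 Angstrom. Integer modes (0, 1, 6) are read with a
#' conversion warning.
#'
#' @param path file path.
#' @param vol a [density_volume()].
#' @return `read_volume` returns a [density_volume()].
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (any(c(nx, ny, nz) <= 0) || !(mode %in% c(0, 1, 2, 6)))
    stop(sprintf("corrupt or unsupported MRC header at byte 0: nx/ny/nz/mode = %d/%d/%d/%d",
                 nx, ny, nz, mode), call. = FALSE)
  mxyz <- hdr[8:10]
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 1024)
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "0" = { warning("MRC mode 0 (int8) converted to float", call. = FALSE)
            as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE,
                               endian = "little")) },
    "1" = { warning("MRC mode 1 (int16) converted to float", call. = FALSE)
            as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                               endian = "little")) },
    "6" = { warning("MRC mode 6 (uint16) converted to float", call. = FALSE)
            as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                               endian = "little")) })
  if (length(vals) != n)
    stop(sprintf("truncated MRC data: expected %d voxels, read %d at byte offset %d",
                 n, length(vals), 1024), call. = FALSE)
  voxel <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  density_volume(array(vals, c(nx, ny, nz)), voxel)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$values)
  con <- file(path, "wb")
  on.exit(close(con))
  vals <- as.vector(vol$values)
  writeBin(as.integer(c(d, 2L)), con, size = 4, endian = "little")     # nx ny nz mode
  writeBin(integer(3), con, size = 4, endian = "little")               # nstart
  writeBin(as.integer(d), con, size = 4, endian = "little")            # mx my mz
  writeBin(as.numeric(d * vol$voxel_A), con, size = 4, endian = "little") # cella
  writeBin(rep(90, 3), con, size = 4, endian = "little")               # cellb
  writeBin(1:3, con, size = 4, endian = "little")                      # mapc mapr maps
  writeBin(as.numeric(c(min(vals), max(vals), mean(vals))), con,
           size = 4, endian = "little")                                # dmin dmax dmean
  writeBin(integer(2), con, size = 4, endian = "little")               # ispg nsymbt
  writeBin(integer(25), con, size = 4, endian = "little")              # extra
  writeBin(numeric(3), con, size = 4, endian = "little")               # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.integer(16708), con, size = 4, endian = "little")        # machst 0x44 0x41
  writeBin(as.numeric(stats::sd(vals)), con, size = 4, endian = "little")
  writeBin(integer(1), con, size = 4, endian = "little")               # nlabl
  writeBin(raw(800), con)                                              # labels
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Write a projection stack as an MRC stack plus a .tlt angle file
#'
#' @param stack a [projection_stack()].
#' @param path MRC output path; the angle list goes to `sub('.mrc', '.tlt')`
#'   (IMOD dialect, one angle per line) unless `tlt_path` is given.
#' @param tlt_path optional explicit angle-file path.
#' @return the MRC path, invisibly.
#' @export
write_stack <- function(stack, path, tlt_path = sub("\\.mrc$", ".tlt", path)) {
  stopifnot(inherits(stack, "projection_stack"))
  vol <- density_volume(stack$images, stack$pixel_A)
  write_volume(vol, path)
  write_tlt(stack$angles_deg, tlt_path)
  invisible(path)
}

#' Read / write IMOD-style tilt-angle files
#' @param path .tlt path (one angle in degrees per line).
#' @param angles_deg numeric angle vector.
#' @return `read_tlt` returns the numeric angle vector.
#' @export
read_tlt <- function(path) as.numeric(readLines(path))

#' @rdname read_tlt
#' @export
write_tlt <- function(angles_deg, path) {
  writeLines(formatC(angles_deg, format = "f", digits = 2), path)
  invisible(path)
}

# ---- STAR dialect -----------------------------------------------------------

star_columns <- c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
                  "rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
                  "rlnOriginX", "rlnOriginY", "rlnOriginZ")

#' Read and write orientation tables (STAR dialect)
#'
#' The documented column set: `rlnAngleRot/Tilt/Psi` (intrinsic ZYZ,
#' degrees), `rlnCoordinateX/Y/Z` (particle centers, voxels),
#' `rlnOriginX/Y/Z` (shifts, voxels), plus `rlnImageName` (particle id) and
#' `rlnMicrographName` (source tomogram). Round trips preserve all fields
#' to 1e-6.
#'
#' @param path STAR file path.
#' @param records list of [orientation_record()]s.
#' @return `read_orientations` returns a list of [orientation_record()]s;
#'   `orientations_table` converts such a list to a tibble.
#' @export
read_orientations <- function(path) {
  lines <- trimws(readLines(path))
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0) stop("no loop_ block in STAR file", call. = FALSE)
  i <- loop_at[1] + 1
  cols <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("^_", "", sub("\\s*#\\d+$", "", lines[i])))
    i <- i + 1
  }
  missing <- setdiff(star_columns, cols)
  if (length(missing))
    stop("STAR file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  body <- lines[i:length(lines)]
  body <- body[nzchar(body) & !startsWith(body, "data_")]
  tab <- utils::read.table(text = body, col.names = cols,
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(r) {
    orientation_record(
      particle_id = if ("rlnImageName" %in% cols) tab$rlnImageName[r]
                    else as.character(r),
      transform = rigid_transform(
        c(tab$rlnAngleRot[r], tab$rlnAngleTilt[r], tab$rlnAnglePsi[r]),
        c(tab$rlnOriginX[r], tab$rlnOriginY[r], tab$rlnOriginZ[r])),
      source_tomogram = if ("rlnMicrographName" %in% cols)
        tab$rlnMicrographName[r] else NA_character_,
      center_vox = c(tab$rlnCoordinateX[r], tab$rlnCoordinateY[r],
                     tab$rlnCoordinateZ[r]))
  })
}

#' @rdname read_orientations
#' @export
write_orientations <- function(records, path) {
  tab <- orientations_table(records)
  cols <- c("rlnImageName", "rlnMicrographName", star_columns)
  hdr <- c("data_particles", "", "loop_",
           sprintf("_%s #%d", cols, seq_along(cols)))
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, format = "f", digits = 6) else as.character(x)
  }
  body <- do.call(paste, c(lapply(cols, function(cn) fmt(tab[[cn]])), sep = "  "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname read_orientations
#' @export
orientations_table <- function(records) {
  tibble::tibble(
    rlnImageName = vapply(records, function(r) as.character(r$particle_id), ""),
    rlnMicrographName = vapply(records, function(r)
      ifelse(is.na(r$source_tomogram), "unknown", r$source_tomogram), ""),
    rlnAngleRot = vapply(records, function(r) r$transform$euler_deg[1], 0),
    rlnAngleTilt = vapply(records, function(r) r$transform$euler_deg[2], 0),
    rlnAnglePsi = vapply(records, function(r) r$transform$euler_deg[3], 0),
    rlnCoordinateX = vapply(records, function(r) as.numeric(r$center_vox[1]), 0),
    rlnCoordinateY = vapply(records, function(r) as.numeric(r$center_vox[2]), 0),
    rlnCoordinateZ = vapply(records, function(r) as.numeric(r$center_vox[3]), 0),
    rlnOriginX = vapply(records, function(r) r$transform$shift_vox[1], 0),
    rlnOriginY = vapply(records, function(r) r$transform$shift_vox[2], 0),
    rlnOriginZ = vapply(records, function(r) r$transform$shift_vox[3], 0))
}

#' Write template-match results as a STAR-dialect table + JSON summary
#'
#' @param matches tibble from [template_match()].
#' @param star_path output STAR path (coordinates, angles, cc).
#' @param json_path optional JSON summary path.
#' @return `star_path`, invisibly.
#' @export
write_matches <- function(matches, star_path, json_path = NULL) {
  cols <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
            "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi", "rlnCrossCorrelation")
  hdr <- c("data_matches", "", "loop_",
           sprintf("_%s #%d", cols, seq_along(cols)))
  vals <- cbind(matches$x, matches$y, matches$z, matches$rot, matches$tilt,
                matches$psi, matches$cc)
  body <- apply(vals, 1, function(r)
    paste(formatC(r, format = "f", digits = 6), collapse = "  "))
  writeLines(c(hdr, body), star_path)
  if (!is.null(json_path))
    jsonlite::write_json(list(n_matches = nrow(matches),
                              mean_cc = if (nrow(matches)) mean(matches$cc) else NA,
                              max_cc = if (nrow(matches)) max(matches$cc) else NA),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(star_path)
}
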