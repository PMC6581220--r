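#' Write a list-mode event stream
#'
#' Two dialects: a CSV text format (header metadata in a leading `# {json}`
#' comment line) intended for small fixtures, and a flat binary format
#' (little-endian: t_us as float64, crystal indices as int32) with a JSON
#' sidecar `<path>.json`, selected by the `.csv` extension.
#'
#' @param events An [event_stream()].
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  header <- list(geometry = events$geom_name, duration_ms = events$duration_ms,
                 rate_cps = events$rate_cps, n_emitted = events$n_emitted,
                 n_events = n_events(events),
                 columns = c("t_us", "crystal_a", "crystal_b"))
  if (grepl("\\.csv$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", jsonlite::toJSON(header, auto_unbox = TRUE)), con)
    utils::write.table(
      data.frame(t_us = events$t_us, crystal_a = events$crystal_a,
                 crystal_b = events$crystal_b),
      con, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(events$t_us), con, size = 8, endian = "little")
    writeBin(as.integer(events$crystal_a), con, size = 4, endian = "little")
    writeBin(as.integer(events$crystal_b), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a list-mode event stream
#'
#' @param path Path written by [write_events()].
#' @return An [event_stream()].
#' @export
read_events <- function(path) {
  if (grepl("\\.csv$", path)) {
    first <- readLines(path, n = 1)
    if (!startsWith(first, "# "))
      stop("malformed event file header (line 1): expected '# {json}'")
    header <- jsonlite::fromJSON(sub("^# ", "", first))
    df <- utils::read.csv(path, comment.char = "#")
    if (!all(c("t_us", "crystal_a", "crystal_b") %in% names(df)))
      stop("malformed event file: missing columns")
    ev <- event_stream(df$t_us, df$crystal_a, df$crystal_b)
  } else {
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("missing sidecar header: ", side)
    header <- jsonlite::fromJSON(side)
    n <- header$n_events
    con <- file(path, "rb")
    on.exit(close(con))
    t_us <- readBin(con, "numeric", n, size = 8, endian = "little")
    a <- readBin(con, "integer", n, size = 4, endian = "little")
    b <- readBin(con, "integer", n, size = 4, endian = "little")
    if (length(t_us) < n || length(a) < n || length(b) < n)
      stop("truncated event file: expected ", n, " events")
    ev <- event_stream(t_us, a, b)
  }
  ev$geom_name <- header$geometry
  ev$duration_ms <- header$duration_ms
  ev$rate_cps <- header$rate_cps
  ev$n_emitted <- header$n_emitted
  ev
}

#' Write a trajectory as JSON lines
#'
#' One JSON object per pose: `t_ms`, quaternion `q` (w, x, y, z),
#' translation `t` (mm) and `accepted`. A `#` header line records the frame
#' duration and format version.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(
    list(format = "awakepet-trajectory", version = 1,
         frame_duration_ms = traj$frame_duration_ms), auto_unbox = TRUE)), con)
  n <- length(traj$t_ms)
  lines <- vapply(seq_len(n), function(i) {
    jsonlite::toJSON(list(t_ms = traj$t_ms[i],
                          q = traj$quaternions[i, ],
                          t = traj$translations[i, ],
                          accepted = traj$accepted[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#' @param path Input path.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  recs <- lapply(lines[-1], jsonlite::fromJSON)
  trajectory(
    t_ms = vapply(recs, `[[`, numeric(1), "t_ms"),
    quaternions = do.call(rbind, lapply(recs, `[[`, "q")),
    translations = do.call(rbind, lapply(recs, `[[`, "t")),
    accepted = vapply(recs, `[[`, logical(1), "accepted"),
    frame_duration_ms = header$frame_duration_ms)
}

#' Write a volume as NIfTI-1
#'
#' Units are mm; the world frame is the scanner (or head) frame used by the
#' grid. Voxel sizes and origin are stored in the sform.
#'
#' @param vol A [voxel_image()], [mu_map()] or [brain_atlas()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  values <- if (inherits(vol, "mu_map")) vol$mu
            else if (inherits(vol, "brain_atlas")) vol$labels
            else vol$values
  g <- vol$grid
  img <- RNifti::asNifti(array(values, g$shape))
  RNifti::pixdim(img) <- g$voxel_size
  m <- diag(4)
  m[1:3, 1:3] <- diag(g$voxel_size)
  m[1:3, 4] <- g$origin + 0.5 * g$voxel_size
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Input path.
#' @param type `"image"`, `"mu"` or `"atlas"`.
#' @param region_names Required for `type = "atlas"`.
#' @export
read_volume <- function(path, type = c("image", "mu", "atlas"),
                        region_names = NULL) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  vx <- c(abs(xf[1, 1]), abs(xf[2, 2]), abs(xf[3, 3]))
  origin <- xf[1:3, 4] - 0.5 * vx
  g <- grid_spec(dim(img), vx, origin)
  arr <- array(as.numeric(img), dim(img))
  switch(type,
         image = voxel_image(g, arr),
         mu = mu_map(g, arr),
         atlas = {
           if (is.null(region_names)) stop("atlas read requires region_names")
           brain_atlas(g, round(arr), region_names)
         })
}

#' Read / write an SUV table CSV
#'
#' Columns: subject, group, condition, region, suv.
#' @param path CSV path.
#' @export
read_suv_table <- function(path) {
  suv_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_suv_table
#' @param table A validated SUV table data frame.
#' @export
write_suv_table <- function(table, path) {
  utils::write.csv(suv_table(table), path, row.names = FALSE)
  invisible(path)
}

#' Bundled group-mean SUV table
#'
#' Group-mean regional SUVs (five brain regions, test / retest / memantine
#' conditions, anesthetized and awake groups) from an awake-mouse FDG
#' test-retest and memantine-challenge experiment, as used by the worked
#' examples and the acceptance script.
#'
#' @return An [suv_table()] data frame.
#' @export
reference_suv_means <- function() {
  read_suv_table(system.file("extdata", "reference_suv_means.csv",
                             package = "awakepet", mustWork = TRUE))
}
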