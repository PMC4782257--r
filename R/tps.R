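#' Read and write TPS landmark files
#'
#' Plain-text TPS records as produced by common 2D digitizing software:
#' each specimen is one record with `LM=k`, k lines of `x y` coordinates,
#' then optional `IMAGE=`, `ID=` and `SCALE=` lines. On read, coordinates
#' are multiplied by the record's scale factor (default 1.0) so that returned
#' points are in physical units.
#'
#' @param path file path.
#' @return `read_tps`: a list of landmark configurations; each element is a
#'   list with `specimen_id` (from IMAGE= or ID=), `points` (k x 2 matrix in
#'   physical units), and `scale`.
#' @export
read_tps <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i], ignore.case = TRUE))
      stop("malformed TPS file at line ", i, ": expected LM=")
    k <- as.integer(sub("^LM=", "", lines[i], ignore.case = TRUE))
    if (is.na(k) || k < 1L) stop("bad LM= count at line ", i)
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      xy <- suppressWarnings(as.numeric(strsplit(lines[i + j], "[ \t]+")[[1]]))
      if (length(xy) != 2L || anyNA(xy))
        stop("bad coordinate line ", i + j, " in TPS file")
      coords[j, ] <- xy
    }
    i <- i + k + 1L
    image <- NA_character_; id <- NA_character_; scale <- 1.0
    while (i <= length(lines) && !grepl("^LM=", lines[i], ignore.case = TRUE)) {
      if (grepl("^IMAGE=", lines[i], ignore.case = TRUE)) {
        image <- sub("^IMAGE=", "", lines[i], ignore.case = TRUE)
      } else if (grepl("^ID=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      } else if (grepl("^SCALE=", lines[i], ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE=", "", lines[i], ignore.case = TRUE))
        if (is.na(scale) || scale <= 0) stop("bad SCALE= at line ", i)
      } else {
        stop("unrecognized TPS keyword at line ", i, ": ", lines[i])
      }
      i <- i + 1L
    }
    sid <- if (!is.na(image) && nzchar(image)) image else id
    pts <- coords * scale
    if (nrow(pts) >= 2L && any(stats::dist(pts) == 0))
      stop("coincident landmarks in specimen ", sid)
    out[[length(out) + 1L]] <- list(specimen_id = sid, points = pts,
                                    scale = scale)
  }
  out
}

#' @rdname read_tps
#' @param configs list of configurations as returned by `read_tps` or built
#'   by [traits_to_landmarks()]. All must share the same landmark count.
#'   Coordinates are written as `points / scale` (raw digitizer units) with
#'   the scale recorded on a SCALE= line, so a round trip reproduces the
#'   physical coordinates.
#' @export
write_tps <- function(configs, path) {
  ks <- vapply(configs, function(cf) nrow(cf$points), integer(1))
  if (length(unique(ks)) != 1L)
    stop("all configurations must have the same landmark count")
  con <- file(path, "w")
  on.exit(close(con))
  for (n in seq_along(configs)) {
    cf <- configs[[n]]
    scale <- if (is.null(cf$scale)) 1.0 else cf$scale
    raw <- cf$points / scale
    writeLines(sprintf("LM=%d", nrow(raw)), con)
    writeLines(sprintf("%.12g %.12g", raw[, 1], raw[, 2]), con)
    writeLines(sprintf("IMAGE=%s", cf$specimen_id), con)
    writeLines(sprintf("ID=%d", n), con)
    writeLines(sprintf("SCALE=%.12g", scale), con)
  }
  invisible(path)
}
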