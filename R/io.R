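# List-mode and raster file formats. Both are plain text: a block of
# '#key value' header lines followed by tab-separated records (list-mode)
# or whitespace-separated values in x-fastest order (rasters).

.LISTMODE_VERSION <- 1L
.LISTMODE_COLS <- c("id", "angle_deg", "y0", "th_y0", "z0", "th_z0",
                    "y1", "th_y1", "z1", "th_z1", "e_in", "e_out", "wepl",
                    "species")

.write_header <- function(con, fields) {
  for (nm in names(fields))
    writeLines(sprintf("#%s %s", nm, paste(fields[[nm]], collapse = " ")), con)
}

.read_header <- function(path) {
  lines <- readLines(path, n = 64)
  hl <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hl), " ")
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = " ")),
                  vapply(kv, `[`, "", 1))
}

#' Write list-mode events to a text file
#'
#' Writes a versioned header (format version, species, initial energy,
#' tracker geometry, seed, phantom id) followed by one tab-separated record
#' per history. Units: mm, MeV, rad; the projection angle in degrees.
#'
#' @param events Event `data.frame` (see [simulate_projection()]).
#' @param path Output path.
#' @param phantom_id Free-text phantom identifier for the header.
#' @param seed Seed recorded in the header (provenance only).
#' @return `path`, invisibly.
#' @export
write_listmode <- function(events, path, phantom_id = "unknown", seed = NA) {
  geom <- attr(events, "geometry")
  has_label <- "label" %in% names(events)
  cols <- c(.LISTMODE_COLS, if (has_label) "label")
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(
    `ionct-listmode` = .LISTMODE_VERSION,
    species = as.character(events$species[1]),
    energy = if (!is.null(geom)) geom$energy else NA,
    x0 = if (!is.null(geom)) geom$x0 else NA,
    x1 = if (!is.null(geom)) geom$x1 else NA,
    seed = seed, phantom = phantom_id,
    columns = cols
  ))
  tab <- events[, cols]
  for (j in seq_along(tab)) # %.17g keeps doubles exact across the round trip
    if (is.double(tab[[j]])) tab[[j]] <- sprintf("%.17g", tab[[j]])
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read list-mode events
#'
#' Parses the header, validates the format version and the column set
#' (naming any missing column), and restores the geometry attribute. Files
#' without a truth label column (experimental-style data) load with label
#' `"unknown"`; such events are refused by truth-based evaluation.
#'
#' @param path Input path written by [write_listmode()].
#' @return Event `data.frame`.
#' @export
read_listmode <- function(path) {
  hdr <- .read_header(path)
  if (is.null(hdr[["ionct-listmode"]]))
    stop("read_listmode: not an ionct list-mode file (missing version header)")
  if (as.integer(hdr[["ionct-listmode"]]) != .LISTMODE_VERSION)
    stop(sprintf("read_listmode: unsupported format version %s", hdr[["ionct-listmode"]]))
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != stats::median(nf))[1]
    stop(sprintf("read_listmode: malformed record at data line %d", bad))
  }
  ev <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  for (cc in setdiff(names(ev), c("id", "species", "label")))
    ev[[cc]] <- as.double(ev[[cc]])
  if ("id" %in% names(ev)) ev$id <- as.integer(ev$id)
  missing <- setdiff(.LISTMODE_COLS, names(ev))
  if (length(missing))
    stop(sprintf("read_listmode: missing column(s): %s", paste(missing, collapse = ", ")))
  if (!"label" %in% names(ev)) ev$label <- "unknown"
  num <- function(x) suppressWarnings(as.numeric(x))
  attr(ev, "geometry") <- list(x0 = num(hdr$x0), x1 = num(hdr$x1),
                               energy = num(hdr$energy))
  ev
}

#' Write an RSP image or 2D map as a text raster
#'
#' Header lines carry the dimensions, spacing and origin; values follow in
#' x-fastest order. `tomo_grid` objects are written as single-slice
#' rasters.
#'
#' @param img An [rsp_image()] or `tomo_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  if (inherits(img, "tomo_grid")) {
    vals <- array(img$values, c(length(img$x), length(img$y), 1))
    img <- rsp_image(pmax(vals, 0), spacing = c(img$pixel, img$pixel, 1))
  }
  d <- dim(img$values)
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(`ionct-raster` = 1, dim = d, spacing = img$spacing,
                          origin = img$origin))
  writeLines(paste(sprintf("%.17g", as.vector(img$values)), collapse = " "), con)
  invisible(path)
}

#' Read a text raster written by [write_raster()]
#'
#' @param path Input path.
#' @return An [rsp_image()].
#' @export
read_raster <- function(path) {
  hdr <- .read_header(path)
  if (is.null(hdr[["ionct-raster"]])) stop("read_raster: not an ionct raster")
  d <- as.integer(strsplit(hdr$dim, " ")[[1]])
  sp <- as.numeric(strsplit(hdr$spacing, " ")[[1]])
  org <- as.numeric(strsplit(hdr$origin, " ")[[1]])
  vals <- scan(path, comment.char = "#", quiet = TRUE)
  if (length(vals) != prod(d))
    stop(sprintf("read_raster: expected %d values, found %d", prod(d), length(vals)))
  rsp_image(array(vals, d), spacing = sp, origin = org)
}
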