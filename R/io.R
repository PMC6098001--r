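# Plain-text interchange formats.
#
# All artefacts serialise to TSV with '#'-prefixed metadata headers
# (values JSON-encoded), so that fixtures are human-readable and
# diff-able.  STXM stacks are written as a directory of per-energy TSV
# grids plus a JSON sidecar; binary image formats are deliberately not
# used.

.write_meta <- function(metadata, con) {
  for (k in names(metadata)) {
    v <- jsonlite::toJSON(metadata[[k]], auto_unbox = TRUE, digits = NA,
                          null = "null")
    writeLines(paste0("# ", k, "\t", v), con)
  }
}

.read_meta <- function(lines) {
  meta_lines <- grep("^# ", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    body <- sub("^# ", "", ln)
    kv <- strsplit(body, "\t", fixed = TRUE)[[1]]
    if (length(kv) == 2)
      out[[kv[1]]] <- jsonlite::fromJSON(kv[2], simplifyVector = TRUE)
  }
  out
}

#' Read and write 1D line scans as TSV
#'
#' Two columns (`q` in 1/Angstrom, `intensity` in counts) preceded by
#' `#`-prefixed metadata lines with JSON-encoded values.
#'
#' @param scan a [line_scan()].
#' @param path file path.
#' @return `read_line_scan()` returns a [line_scan()];
#'   `write_line_scan()` returns `path` invisibly.
#' @export
write_line_scan <- function(scan, path) {
  stopifnot(inherits(scan, "line_scan"))
  con <- file(path, "w"); on.exit(close(con))
  .write_meta(scan$metadata, con)
  writeLines("q\tintensity", con)
  writeLines(paste(format(scan$q, digits = 15),
                   format(scan$intensity, digits = 15), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_line_scan
#' @export
read_line_scan <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  dat <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                    sep = "\t")
  line_scan(dat$q, dat$intensity, metadata = meta)
}

#' Read and write 2D reciprocal-space maps as gridded TSV
#'
#' Metadata header lines, then a grid: first row holds the `q_par` axis
#' (first cell `q_z\\q_par`), each following row one `q_z` value followed
#' by the intensities at that `q_z`.
#'
#' @param map a [reciprocal_map()].
#' @param path file path.
#' @return `read_reciprocal_map()` returns a [reciprocal_map()].
#' @export
write_reciprocal_map <- function(map, path) {
  stopifnot(inherits(map, "reciprocal_map"))
  con <- file(path, "w"); on.exit(close(con))
  .write_meta(map$metadata, con)
  writeLines(paste(c("q_z\\q_par", format(map$q_par, digits = 12)),
                   collapse = "\t"), con)
  for (j in seq_along(map$q_z))
    writeLines(paste(c(format(map$q_z[j], digits = 12),
                       format(map$intensity[, j], digits = 12)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_reciprocal_map
#' @export
read_reciprocal_map <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  body <- lines[!startsWith(lines, "#")]
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  q_par <- as.numeric(hdr[-1])
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  q_z <- vapply(rows, function(r) as.numeric(r[1]), numeric(1))
  intensity <- vapply(rows, function(r) as.numeric(r[-1]),
                      numeric(length(q_par)))
  reciprocal_map(q_par, q_z, intensity, metadata = meta)
}

#' Read and write head-group surfaces as 4-column TSV
#'
#' Columns `leaflet`, `x`, `y`, `z` (Angstrom) after metadata headers.
#'
#' @param surface a [surface_point_cloud()].
#' @param path file path.
#' @return `read_surface()` returns a [surface_point_cloud()].
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "surface_point_cloud"))
  con <- file(path, "w"); on.exit(close(con))
  meta <- surface$metadata
  meta$d0 <- surface$d0
  .write_meta(meta, con)
  writeLines("leaflet\tx\ty\tz", con)
  p <- surface$points
  writeLines(paste(p$leaflet, format(p$x, digits = 12),
                   format(p$y, digits = 12), format(p$z, digits = 12),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  dat <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                    sep = "\t")
  d0 <- meta$d0
  meta$d0 <- NULL
  surface_point_cloud(dat, d0 = d0, metadata = meta)
}

#' Read and write STXM stacks as a directory of text files
#'
#' Layout: `meta.json` (energies, i0, pixel size, metadata),
#' `energies.tsv`, and one `image_NNN.tsv` intensity grid per energy.
#' A plain-text stand-in for the multi-page image formats instrument
#' software produces.
#'
#' @param stack an [stxm_stack()].
#' @param dir directory (created if missing).
#' @return `read_stxm_stack()` returns an [stxm_stack()].
#' @export
write_stxm_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "stxm_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(energies = stack$energies, i0 = stack$i0,
         pixel_nm = stack$pixel_nm, metadata = stack$metadata),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  write.table(data.frame(energy_eV = stack$energies),
              file.path(dir, "energies.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (k in seq_along(stack$energies))
    write.table(stack$images[, , k],
                file.path(dir, sprintf("image_%03d.tsv", k)), sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_stxm_stack
#' @export
read_stxm_stack <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"),
                             simplifyVector = TRUE)
  imgs <- lapply(seq_along(meta$energies), function(k)
    as.matrix(read.table(file.path(dir, sprintf("image_%03d.tsv", k)),
                         sep = "\t", header = FALSE)))
  md <- meta$metadata
  if (is.null(md)) md <- list()
  stxm_stack(meta$energies, simplify2array(imgs), i0 = meta$i0,
             pixel_nm = meta$pixel_nm, metadata = md)
}

#' Serialise peak fits to a flat report
#'
#' @param fits list of `peak_fit` objects.
#' @param path optional JSON path; when `NULL` the data.frame is returned
#'   only.
#' @return A data.frame of fit parameters, invisibly when written.
#' @export
peak_report <- function(fits, path = NULL) {
  if (inherits(fits, "peak_fit")) fits <- list(fits)
  df <- do.call(rbind, lapply(fits, function(p)
    data.frame(center = p$center, fwhm = p$fwhm, amplitude = p$amplitude,
               area = p$area, model = p$model, goodness = p$goodness,
               converged = p$converged)))
  if (!is.null(path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
    return(invisible(df))
  }
  df
}
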