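# ---- scan TSV format ------------------------------------------------------
# A plain-text grid with '#'-prefixed "key: value" metadata lines followed
# by tab-separated rows (rows run along y). Values are written with full
# double precision so a write -> read round trip is lossless.

scan_header <- function(image) {
  h <- c("dotdepth scan v1",
         sprintf("pitch_mm: %.17g", image$pitch),
         sprintf("origin_mm: %.17g %.17g", image$origin[1], image$origin[2]),
         sprintf("detector: %s", image$detector),
         "units: intensity")
  if (!is.null(image$geometry)) {
    g <- image$geometry
    h <- c(h, sprintf("deltaD_mm: %.17g %.17g", g$deltaD_vec[1], g$deltaD_vec[2]),
           sprintf("d0_mm: %.17g", g$d0),
           sprintf("arrangement: %s", g$arrangement))
  }
  if (!is.null(image$medium)) {
    m <- image$medium
    h <- c(h, sprintf("mu_a0_per_mm: %.17g", m$mu_a0),
           sprintf("mu_s0_prime_per_mm: %.17g", m$mu_s0_prime),
           sprintf("convention: %s", m$convention))
  }
  paste0("# ", h)
}

#' Write a scan image to a TSV file
#'
#' Plain-text grid with a `#`-prefixed metadata header (pitch, origin,
#' detector label, pair geometry and medium when present). The round trip
#' through [read_scan()] is lossless.
#'
#' @param image a [scan_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(image, path) {
  stopifnot(inherits(image, "scan_image"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(scan_header(image), con)
  body <- apply(image$values, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

parse_scan_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    ln <- sub("^#\\s*", "", ln)
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Read a scan image from a TSV file
#'
#' @param path a file written by [write_scan()].
#' @return a [scan_image()].
#' @export
read_scan <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- parse_scan_header(lines[is_hdr])
  for (key in c("pitch_mm", "origin_mm", "detector"))
    if (is.null(kv[[key]]))
      stop("scan file is missing required metadata key: ", key)
  vals <- do.call(rbind, lapply(lines[!is_hdr], function(ln)
    as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]])))
  geometry <- NULL
  if (!is.null(kv$deltaD_mm) && !is.null(kv$d0_mm)) {
    dv <- as.numeric(strsplit(kv$deltaD_mm, " ")[[1]])
    geometry <- pair_geometry(as.numeric(kv$d0_mm), dv,
                              arrangement = kv$arrangement %||% "symmetric")
  }
  medium <- NULL
  if (!is.null(kv$mu_a0_per_mm))
    medium <- optical_medium(as.numeric(kv$mu_a0_per_mm),
                             as.numeric(kv$mu_s0_prime_per_mm),
                             convention = kv$convention %||% "mua_independent")
  scan_image(vals, pitch = as.numeric(kv$pitch_mm),
             origin = as.numeric(strsplit(kv$origin_mm, " ")[[1]]),
             detector = kv$detector, geometry = geometry, medium = medium)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a scan image as 32-bit float TIFF with a JSON sidecar
#'
#' The TIFF holds the raw intensity grid; acquisition metadata (pitch,
#' origin, detector, geometry, medium) goes to `<path>.json`.
#'
#' @param image a [scan_image()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_scan_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  stopifnot(inherits(image, "scan_image"))
  tiff::writeTIFF(image$values, path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(pitch_mm = image$pitch, origin_mm = image$origin,
               detector = image$detector)
  if (!is.null(image$geometry))
    meta$geometry <- list(d0_mm = image$geometry$d0,
                          deltaD_mm = image$geometry$deltaD_vec,
                          arrangement = image$geometry$arrangement)
  if (!is.null(image$medium))
    meta$medium <- list(mu_a0_per_mm = image$medium$mu_a0,
                        mu_s0_prime_per_mm = image$medium$mu_s0_prime,
                        convention = image$medium$convention)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# ---- depth curve TSV ------------------------------------------------------

#' Write / read a depth curve as TSV
#'
#' Two-column (`alpha`, `z_over_d0`) TSV with a `#`-prefixed metadata
#' header recording the build parameters and conventions.
#'
#' @param curve a [build_depth_curve()] result.
#' @param path file path.
#' @return `write_depth_curve`: `path` invisibly; `read_depth_curve`: a
#'   `depth_curve`.
#' @export
write_depth_curve <- function(curve, path) {
  stopifnot(inherits(curve, "depth_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c(
    "dotdepth depth_curve v1",
    sprintf("d0_mm: %.17g", curve$d0),
    sprintf("deltaD_mm: %.17g", curve$deltaD),
    sprintf("arrangement: %s", curve$arrangement),
    sprintf("mu_a0_per_mm: %.17g", curve$medium$mu_a0),
    sprintf("mu_s0_prime_per_mm: %.17g", curve$medium$mu_s0_prime),
    sprintf("convention: %s", curve$medium$convention),
    sprintf("partial: %s", curve$partial),
    sprintf("z_step_mm: %.17g", curve$provenance$z_step),
    sprintf("scan_step_mm: %.17g", curve$provenance$scan_step),
    sprintf("localization: %s", curve$provenance$localization),
    sprintf("inclusion: %s", curve$provenance$inclusion),
    "columns: alpha z_over_d0")), con)
  writeLines(sprintf("%.17g\t%.17g", curve$samples$alpha,
                     curve$samples$z_over_d0), con)
  invisible(path)
}

#' @rdname write_depth_curve
#' @export
read_depth_curve <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- parse_scan_header(lines[is_hdr])
  body <- do.call(rbind, strsplit(lines[!is_hdr], "\t", fixed = TRUE))
  samples <- data.frame(alpha = as.numeric(body[, 1]),
                        z_over_d0 = as.numeric(body[, 2]))
  structure(
    list(samples = samples,
         medium = optical_medium(as.numeric(kv$mu_a0_per_mm),
                                 as.numeric(kv$mu_s0_prime_per_mm),
                                 convention = kv$convention),
         d0 = as.numeric(kv$d0_mm), deltaD = as.numeric(kv$deltaD_mm),
         arrangement = kv$arrangement,
         partial = identical(kv$partial, "TRUE"),
         provenance = list(z_step = as.numeric(kv$z_step_mm),
                           scan_step = as.numeric(kv$scan_step_mm),
                           localization = kv$localization,
                           convention = kv$convention,
                           inclusion = kv$inclusion,
                           discrepancy_metric = "percent of d0 at matched alpha")),
    class = "depth_curve")
}

# ---- alpha map TSV + JSON summary -----------------------------------------

#' Write an alpha map as TSV (NaN for unmatched pixels) plus JSON summary
#'
#' @param amap an [alpha_map()].
#' @param path TSV output path; the summary (match fraction, alpha
#'   histogram) goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_alpha_map <- function(amap, path) {
  stopifnot(inherits(amap, "alpha_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c(
    "dotdepth alpha_map v1",
    sprintf("pitch_mm: %.17g", amap$pitch),
    sprintf("origin_mm: %.17g %.17g", amap$origin[1], amap$origin[2]),
    sprintf("deltaD_mm: %.17g %.17g", amap$deltaD_vec[1], amap$deltaD_vec[2]),
    sprintf("window_mm: %.17g", amap$window),
    "no_match: NaN")), con)
  writeLines(apply(amap$alpha, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  a <- amap$alpha[!is.na(amap$alpha)]
  jsonlite::write_json(
    list(match_fraction = amap$match_fraction, n_skeleton = amap$n_skeleton,
         alpha_quantum = amap$alpha_quantum,
         alpha_histogram = as.list(table(round(a / amap$alpha_quantum)))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
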