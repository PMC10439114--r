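#' @useDynLib nanocluster, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor fft median optim pnorm quantile rbinom rnorm
#'   rpois runif sd setNames
#' @importFrom utils read.csv
NULL

# canonical ThunderSTORM-compatible headers, in order
TS_HEADERS <- c(frame = "frame", x_nm = "x [nm]", y_nm = "y [nm]",
                sigma_nm = "sigma [nm]", photons = "intensity [photon]",
                uncertainty_nm = "uncertainty [nm]")

#' Create a localization table
#'
#' The canonical tabular representation of fitted single-molecule events.
#' Coordinates and PSF sigma are in nanometres, intensity in photons,
#' uncertainty is the estimated lateral localization precision in nm.
#'
#' @param frame Integer acquisition frame (>= 1).
#' @param x_nm,y_nm Coordinates in nm (>= 0).
#' @param sigma_nm Fitted PSF standard deviation in nm.
#' @param photons Fitted photon count.
#' @param uncertainty_nm Lateral precision estimate in nm.
#' @param n_merged Number of raw detections merged into the row (>= 1).
#' @returns A `data.frame` with class `localization_table`.
#' @export
localization_table <- function(frame = integer(), x_nm = numeric(),
                               y_nm = numeric(), sigma_nm = numeric(),
                               photons = numeric(),
                               uncertainty_nm = numeric(),
                               n_merged = NULL) {
  df <- data.frame(frame = as.integer(frame), x_nm = as.numeric(x_nm),
                   y_nm = as.numeric(y_nm), sigma_nm = as.numeric(sigma_nm),
                   photons = as.numeric(photons),
                   uncertainty_nm = as.numeric(uncertainty_nm))
  if (!is.null(n_merged)) df$n_merged <- as.integer(n_merged)
  validate_localizations(df)
  class(df) <- c("localization_table", "data.frame")
  df
}

validate_localizations <- function(df) {
  num <- c("x_nm", "y_nm", "sigma_nm", "photons", "uncertainty_nm")
  for (col in num)
    if (any(!is.finite(df[[col]]))) stop("non-finite values in column ", col)
  if (nrow(df) && any(df$x_nm < 0 | df$y_nm < 0))
    stop("coordinates must be >= 0")
  if (!is.null(df$n_merged) && nrow(df) && any(df$n_merged < 1))
    stop("n_merged must be >= 1")
  invisible(df)
}

#' Read a localization table from CSV
#'
#' Reads ThunderSTORM-style CSV tables. The `thunderstorm_csv` dialect
#' expects the headers `"frame"`, `"x [nm]"`, `"y [nm]"`, `"sigma [nm]"`,
#' `"intensity [photon]"`, `"uncertainty [nm]"`; `plain_csv` expects the
#' package's field names (`frame`, `x_nm`, ...). Unknown columns are
#' preserved.
#'
#' @param path CSV file path.
#' @param dialect One of `"thunderstorm_csv"`, `"plain_csv"`.
#' @returns A `localization_table`.
#' @export
read_localizations <- function(path, dialect = "thunderstorm_csv") {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- match.arg(dialect, c("thunderstorm_csv", "plain_csv"))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- if (dialect == "thunderstorm_csv") TS_HEADERS else
    setNames(names(TS_HEADERS), names(TS_HEADERS))
  missing <- setdiff(unname(map), names(df))
  if (length(missing))
    stop("missing mandatory column: ", paste0('"', missing, '"', collapse = ", "))
  out <- df
  names(out)[match(unname(map), names(df))] <- names(map)
  # mandatory columns first, extras after
  out <- out[, c(names(map), setdiff(names(out), names(map))), drop = FALSE]
  for (col in names(map)) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad))
      stop("non-numeric value in column ", col, " at row ", bad[1])
    out[[col]] <- v
  }
  out$frame <- as.integer(out$frame)
  if (!is.null(out$n_merged)) out$n_merged <- as.integer(out$n_merged)
  validate_localizations(out)
  class(out) <- c("localization_table", "data.frame")
  out
}

#' Write a localization table to ThunderSTORM-compatible CSV
#'
#' Emits the exact ThunderSTORM header strings for the six standard columns;
#' any extra columns (e.g. `n_merged`) are appended after them. Numeric
#' values are printed as plain decimals with 6 significant digits so a
#' write/read round trip is the identity to the printed precision.
#'
#' @param table A `localization_table`.
#' @param path Output file path.
#' @returns `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  validate_localizations(table)
  extras <- setdiff(names(table), names(TS_HEADERS))
  headers <- c(unname(TS_HEADERS), extras)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(paste0('"', headers, '"', collapse = ","), con)
  if (nrow(table)) {
    cols <- c(names(TS_HEADERS), extras)
    txt <- vapply(cols, function(col) {
      v <- table[[col]]
      if (is.integer(v)) format(v, scientific = FALSE, trim = TRUE)
      else formatC(v, digits = 6, format = "g", flag = "-")
    }, character(nrow(table)))
    if (nrow(table) == 1) txt <- matrix(txt, nrow = 1)
    writeLines(apply(txt, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a raw movie from a TIFF stack
#'
#' Single-channel 3-D stacks only. Camera counts are converted to photons
#' via `(counts - camera_offset) / counts_per_photon`, clipped at 0.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm Physical pixel size in nm (default 100).
#' @param camera_offset Camera baseline in counts.
#' @param counts_per_photon Camera gain in counts per photon.
#' @returns A `raw_movie`: list with `frames` (array frame x row x col, in
#'   photons), `pixel_size_nm`, `camera_offset`, `counts_per_photon`.
#' @export
read_movie <- function(path, pixel_size_nm = 100, camera_offset = 0,
                       counts_per_photon = 1) {
  stopifnot(pixel_size_nm > 0, counts_per_photon > 0)
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  if (any(vapply(imgs, function(m) length(dim(m)) != 2L, logical(1))))
    stop("unsupported format: multi-channel TIFF")
  nr <- nrow(imgs[[1]]); nc <- ncol(imgs[[1]])
  frames <- array(0, dim = c(length(imgs), nr, nc))
  for (i in seq_along(imgs))
    frames[i, , ] <- pmax((imgs[[i]] - camera_offset) / counts_per_photon, 0)
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 camera_offset = camera_offset,
                 counts_per_photon = counts_per_photon),
            class = "raw_movie")
}

#' Write a movie as a 16-bit TIFF stack
#'
#' @param movie A `raw_movie` (frames in photons) or a 3-D array of counts.
#' @param path Output path.
#' @returns `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  frames <- if (inherits(movie, "raw_movie")) movie$frames else movie
  stopifnot(length(dim(frames)) == 3)
  lst <- lapply(seq_len(dim(frames)[1]), function(i) {
    m <- round(frames[i, , ])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(lst, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Create a pixel image
#'
#' A diffraction-limited intensity image with physical pixel size and an
#' optional boolean region-of-interest mask of the same shape.
#'
#' @param values Numeric matrix of intensities.
#' @param pixel_size_nm Pixel size in nm.
#' @param mask Optional logical matrix, same shape as `values`.
#' @export
pixel_image <- function(values, pixel_size_nm = 100, mask = NULL) {
  stopifnot(is.matrix(values), pixel_size_nm > 0)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(values)))
      stop("mask shape must equal values shape")
    mask <- matrix(as.logical(mask), nrow(values))
  }
  structure(list(values = values, pixel_size_nm = pixel_size_nm, mask = mask),
            class = "pixel_image")
}

#' Default run configuration
#'
#' All tunables of every pipeline stage with their defaults. Thresholds
#' that the quality filters use (photons > 600, sigma in \[50, 200\] nm,
#' uncertainty < 30 nm), the drift corrector's 3 bins at magnification 5,
#' and the 50 nm / 20 frame merging rule are the published processing
#' recipe; the remaining keys are package choices, documented where defined.
#'
#' @returns A nested named list.
#' @export
default_config <- function() {
  list(
    io = list(pixel_size_nm = 100, camera_offset = 0, counts_per_photon = 1),
    reconstruction = list(threshold_multiplier = 2, fit_radius_px = 5,
                          sigma0_px = 1.6),
    filter = list(min_photons = 600, sigma_range_nm = c(50, 200),
                  max_uncertainty_nm = 30),
    drift = list(n_bins = 3, magnification = 5),
    merge = list(max_distance_nm = 50, max_gap_frames = 20,
                 anchor = "centroid"),
    cluster = list(radii_nm = seq(10, 500, by = 10), r_local_nm = 50,
                   grid_step_nm = 5, edge_correction = "none",
                   threshold_n_sim = 100, threshold_quantile = 0.99,
                   min_cluster_cells = 3),
    coloc = list(cbc_r_max_nm = 500, cbc_n_steps = 20, seg_factor = 2,
                 control_mode = "reflect"),
    pixel = list(clustering_threshold_factor = 1.5,
                 background_percentile = 0.05),
    seed = 1
  )
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file path.
#' @returns The merged configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user, "")
}

merge_config <- function(def, user, prefix) {
  if (is.null(user)) return(def)
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key: ", paste0(prefix, unknown, collapse = ", "))
  for (key in names(user)) {
    if (is.list(def[[key]]) && !is.null(names(def[[key]])))
      def[[key]] <- merge_config(def[[key]], user[[key]],
                                 paste0(prefix, key, "."))
    else def[[key]] <- user[[key]]
  }
  def
}
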