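# Histoblot densitometry: circular-cursor ROI measurement on grayscale
# images, eight-point background correction, and developmental/regional
# profile tables.

#' Read a grayscale histoblot image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG into a numeric matrix scaled
#' to 0-255 arbitrary units (multi-channel images are averaged to
#' grayscale). Histoblot scans are assumed to encode more signal as higher
#' pixel value; scans where darker means more signal can be flipped with
#' `invert = TRUE` (value becomes `255 - value`).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param invert Logical; invert the grey scale.
#' @return Numeric matrix (rows = y, columns = x) in 0-255 units.
#' @export
read_histoblot_image <- function(path, invert = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("read_histoblot_image: unsupported extension '%s'", ext)))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  img <- img * 255
  if (isTRUE(invert)) img <- 255 - img
  img
}

#' Circular-cursor ROI set for one histoblot image
#'
#' Describes the measurement cursors on an image: named region ROIs and the
#' background ROIs whose average is subtracted from every region value.
#' Eight background determinations per image are expected; a deviating
#' count is accepted with a warning.
#'
#' @param image_id Identifier of the image the ROIs belong to.
#' @param pixel_size_mm Physical size of one pixel (mm).
#' @param rois Data frame with columns `name`, `cx`, `cy` (pixel
#'   coordinates, may be fractional) and `kind` (`"region"` or
#'   `"background"`).
#' @param cursor_diameter_mm Diameter of the open circular cursor (mm);
#'   default 0.10.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(image_id, pixel_size_mm, rois, cursor_diameter_mm = 0.10) {
  rois <- as.data.frame(rois, stringsAsFactors = FALSE)
  req <- c("name", "cx", "cy", "kind")
  if (!all(req %in% names(rois)))
    stop("roi_set: rois must have columns name, cx, cy, kind")
  if (!all(rois$kind %in% c("region", "background")))
    stop("roi_set: roi kind must be 'region' or 'background'")
  if (pixel_size_mm <= 0 || cursor_diameter_mm <= 0)
    stop("roi_set: pixel_size_mm and cursor_diameter_mm must be positive")
  nbg <- sum(rois$kind == "background")
  if (nbg != 8L)
    warning(sprintf("roi_set: expected 8 background ROIs, got %d", nbg))
  structure(list(image_id = as.character(image_id),
                 pixel_size_mm = pixel_size_mm,
                 cursor_diameter_mm = cursor_diameter_mm,
                 rois = rois[, req]),
            class = "roi_set")
}

#' Read an ROI definition file (JSON)
#'
#' Format: `{image_id, pixel_size_mm, cursor_diameter_mm, rois: [{name, cx,
#' cy, kind}, ...]}`.
#'
#' @param path JSON path.
#' @return An [roi_set()].
#' @export
read_roi_set <- function(path) {
  js <- jsonlite::fromJSON(path)
  for (f in c("image_id", "pixel_size_mm", "rois"))
    if (is.null(js[[f]]))
      stop(sprintf("read_roi_set: missing field '%s'", f))
  roi_set(js$image_id, js$pixel_size_mm, js$rois,
          cursor_diameter_mm = js$cursor_diameter_mm %||% 0.10)
}

#' Write an ROI definition file (JSON)
#'
#' @param rs An [roi_set()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_roi_set <- function(rs, path) {
  stopifnot(inherits(rs, "roi_set"))
  jsonlite::write_json(
    list(image_id = rs$image_id, pixel_size_mm = rs$pixel_size_mm,
         cursor_diameter_mm = rs$cursor_diameter_mm, rois = rs$rois),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean pixel value inside an open circular cursor
#'
#' Averages the pixels whose centers fall strictly inside the circle of the
#' given physical diameter centered at `(cx, cy)` (pixel coordinates;
#' pixel centers are at integer coordinates). The cursor must lie fully
#' inside the image; a clipped circle is an error.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param cx,cy Cursor center in pixel coordinates.
#' @param pixel_size_mm Physical pixel size (mm).
#' @param diameter_mm Cursor diameter (mm); default 0.10.
#' @return Mean pixel value, with attribute `n_pixels` (number of pixel
#'   centers counted).
#' @export
measure_roi <- function(image, cx, cy, pixel_size_mm, diameter_mm = 0.10) {
  stopifnot(is.matrix(image))
  r <- diameter_mm / (2 * pixel_size_mm)
  if (cx - r < 0.5 || cx + r > ncol(image) + 0.5 ||
      cy - r < 0.5 || cy + r > nrow(image) + 0.5)
    stop("measure_roi: circle clipped by the image border")
  cols <- max(1L, ceiling(cx - r)):min(ncol(image), floor(cx + r))
  rows <- max(1L, ceiling(cy - r)):min(nrow(image), floor(cy + r))
  grid <- expand.grid(row = rows, col = cols)
  inside <- (grid$col - cx)^2 + (grid$row - cy)^2 < r^2
  if (!any(inside))
    stop("measure_roi: no pixel center inside the cursor")
  vals <- image[cbind(grid$row[inside], grid$col[inside])]
  structure(mean(vals), n_pixels = sum(inside))
}

#' Measure all cursors of an ROI set
#'
#' @param image Numeric matrix.
#' @param rs An [roi_set()].
#' @return Data frame with columns `name`, `kind`, `mean_value`, `n_pixels`.
#' @export
measure_roi_set <- function(image, rs) {
  stopifnot(inherits(rs, "roi_set"))
  out <- lapply(seq_len(nrow(rs$rois)), function(i) {
    roi <- rs$rois[i, ]
    m <- tryCatch(
      measure_roi(image, roi$cx, roi$cy, rs$pixel_size_mm,
                  rs$cursor_diameter_mm),
      error = function(e) stop(sprintf("ROI '%s': %s", roi$name,
                                       conditionMessage(e)), call. = FALSE))
    data.frame(name = roi$name, kind = roi$kind, mean_value = as.numeric(m),
               n_pixels = attr(m, "n_pixels"), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Background-correct raw ROI densities
#'
#' Subtracts the mean of the background determinations (eight per image in
#' the standard design) from each raw value, flooring at 0 so corrected
#' densities stay in non-negative arbitrary units.
#'
#' @param raw Numeric vector of raw region densities.
#' @param background_values Numeric vector of background ROI means (>= 1;
#'   8 expected).
#' @return Numeric vector of corrected densities, `max(0, raw - mean(bg))`.
#' @export
background_correct <- function(raw, background_values) {
  if (length(background_values) < 1)
    stop("background_correct: at least one background value required")
  pmax(0, raw - mean(background_values))
}

#' Measure and background-correct one histoblot image
#'
#' Runs [measure_roi_set()], averages the background ROIs and applies
#' [background_correct()] to every region ROI.
#'
#' @param image Numeric matrix (see [read_histoblot_image()]).
#' @param rs An [roi_set()].
#' @param age Optional age label (e.g. `"P15"`).
#' @param animal_id Optional animal identifier (one animal = one n).
#' @return Data frame with columns `image_id`, `region`, `age`,
#'   `animal_id`, `raw_density`, `corrected_density`, `n_pixels`.
#' @export
histoblot_measure <- function(image, rs, age = NA_character_,
                              animal_id = NA_character_) {
  meas <- measure_roi_set(image, rs)
  bg <- meas$mean_value[meas$kind == "background"]
  if (length(bg) < 1)
    stop("histoblot_measure: ROI set has no background ROIs")
  reg <- meas[meas$kind == "region", , drop = FALSE]
  data.frame(image_id = rs$image_id, region = reg$name,
             age = age, animal_id = animal_id,
             raw_density = reg$mean_value,
             corrected_density = background_correct(reg$mean_value, bg),
             n_pixels = reg$n_pixels,
             stringsAsFactors = FALSE)
}

parse_age <- function(age) as.numeric(sub("^[Pp]", "", age))

#' Developmental expression profile per region
#'
#' Aggregates background-corrected densities over animals into a mean +/-
#' SEM per region and age, with each animal's regional mean counting as one
#' observation, plus a per-region curve normalised to its maximum mean.
#' Missing region/age cells are simply absent from the output (never
#' reported as zero); the SEM is `NA` when only one animal contributes.
#'
#' @param measurements Data frame with columns `region`, `age`,
#'   `animal_id`, `corrected_density` (e.g. rows of [histoblot_measure()]).
#' @return Data frame with columns `region`, `age`, `age_days`, `n_animals`,
#'   `mean_density`, `sem_density`, `normalised`, sorted by region and age.
#' @export
developmental_profile <- function(measurements) {
  req <- c("region", "age", "animal_id", "corrected_density")
  if (!all(req %in% names(measurements)))
    stop("developmental_profile: measurements must have columns region, age, animal_id, corrected_density")
  per_animal <- stats::aggregate(
    list(density = measurements$corrected_density),
    by = list(region = measurements$region, age = measurements$age,
              animal_id = measurements$animal_id),
    FUN = mean)
  out <- do.call(rbind, lapply(
    split(per_animal, list(per_animal$region, per_animal$age), drop = TRUE),
    function(g) data.frame(
      region = g$region[1], age = g$age[1],
      age_days = parse_age(g$age[1]),
      n_animals = nrow(g),
      mean_density = mean(g$density),
      sem_density = if (nrow(g) > 1) stats::sd(g$density) / sqrt(nrow(g))
                    else NA_real_,
      stringsAsFactors = FALSE)))
  out <- do.call(rbind, lapply(split(out, out$region), function(g) {
    g$normalised <- if (max(g$mean_density) > 0)
      g$mean_density / max(g$mean_density) else NA_real_
    g
  }))
  out <- out[order(out$region, out$age_days), ]
  rownames(out) <- NULL
  out
}
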