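# Kinetic-perimetry isopter geometry: hemifield areas along the horizontal
# meridian and the vertical meridian asymmetry (VMA) index.

.ISOPTERS <- c("V1e", "III1e", "II1e", "I1e")
# I1e is charted but excluded from VMA analysis by default (areas are
# extracted for V1e, III1e and II1e).
.VMA_ISOPTERS <- c("V1e", "III1e", "II1e")

#' Construct an isopter chart
#'
#' An isopter is the contour of equal sensitivity to a kinetic stimulus of a
#' given size/intensity, recorded as polar points (meridian angle, radius in
#' degrees of visual angle) around the fixation point.
#'
#' @param eye `"left"` or `"right"`.
#' @param isopter one of `"V1e"`, `"III1e"`, `"II1e"`, `"I1e"`.
#' @param angle_deg meridian angles in `[0, 360)`, unique.
#' @param radius_deg radii in degrees, `>= 0`.
#' @return A list of class `isopter_chart`.
#' @export
isopter_chart <- function(eye, isopter, angle_deg, radius_deg) {
  eye <- match.arg(eye, c("left", "right"))
  isopter <- match.arg(isopter, .ISOPTERS)
  if (length(angle_deg) != length(radius_deg)) stop("angle/radius length mismatch")
  if (length(angle_deg) < 3L) stop("need at least 3 isopter points")
  if (any(radius_deg < 0)) stop("radii must be non-negative")
  ang <- angle_deg %% 360
  if (anyDuplicated(ang)) stop("meridian angles must be unique within an isopter")
  ord <- order(ang)
  structure(list(eye = eye, isopter = isopter,
                 angle_deg = ang[ord], radius_deg = radius_deg[ord]),
            class = "isopter_chart")
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Clip a polygon to a half-plane (y >= 0 if upper, else y <= 0), inserting
# the meridian intersection points (Sutherland-Hodgman against one edge).
clip_halfplane <- function(x, y, upper = TRUE) {
  sgn <- if (upper) 1 else -1
  n <- length(x)
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    in_i <- sgn * y[i] >= 0
    in_j <- sgn * y[j] >= 0
    if (in_i) { ox <- c(ox, x[i]); oy <- c(oy, y[i]) }
    if (in_i != in_j) {
      t <- y[i] / (y[i] - y[j])
      ox <- c(ox, x[i] + t * (x[j] - x[i])); oy <- c(oy, 0)
    }
  }
  list(x = ox, y = oy)
}

#' Upper and lower hemifield areas of an isopter
#'
#' The polar points are converted to Cartesian coordinates, closed into a
#' polygon in angle order, split along the horizontal meridian (y = 0) with
#' intersection points inserted, and each hemifield's area is computed with
#' the shoelace formula. Sorted unique meridian angles with non-negative
#' radii make the polygon star-shaped about fixation, hence simple.
#'
#' @param chart an [isopter_chart()].
#' @return A list with `upper_area` and `lower_area` in squared degrees.
#' @export
hemifield_areas <- function(chart) {
  stopifnot(inherits(chart, "isopter_chart"))
  a <- chart$angle_deg * pi / 180
  x <- chart$radius_deg * cos(a)
  y <- chart$radius_deg * sin(a)
  up <- clip_halfplane(x, y, upper = TRUE)
  lo <- clip_halfplane(x, y, upper = FALSE)
  list(upper_area = if (length(up$x) >= 3L) shoelace_area(up$x, up$y) else 0,
       lower_area = if (length(lo$x) >= 3L) shoelace_area(lo$x, lo$y) else 0)
}

#' Vertical meridian asymmetry index
#'
#' `VMA = (lower_area - upper_area) / mean(lower_area, upper_area) * 100`.
#' Zero means symmetric hemifields; positive values mean a larger lower
#' visual field. Bounded in `[-200, 200]`. Undefined (returned as `NA` with
#' `defined = FALSE`) when both areas are zero.
#'
#' @param upper_area,lower_area hemifield areas in squared degrees.
#' @return A list with `vma` and `defined`.
#' @export
vma_index <- function(upper_area, lower_area) {
  if (upper_area < 0 || lower_area < 0) stop("areas must be non-negative")
  if (upper_area == 0 && lower_area == 0) {
    return(list(vma = NA_real_, defined = FALSE))
  }
  list(vma = (lower_area - upper_area) / mean(c(lower_area, upper_area)) * 100,
       defined = TRUE)
}

#' Read an isopter CSV
#'
#' Columns: `participant_id, eye, isopter, angle_deg, radius_deg`.
#'
#' @param path path to the isopter CSV.
#' @return A `data.frame` of isopter points.
#' @export
read_isopters <- function(path) {
  if (!file.exists(path)) stop("isopter file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("participant_id", "eye", "isopter", "angle_deg", "radius_deg")
  if (!identical(names(df), expected)) {
    stop("unexpected isopter CSV header: ", paste(names(df), collapse = ","))
  }
  df
}

#' Per-participant, per-eye, per-isopter VMA table
#'
#' Computes hemifield areas and the VMA for each (participant, eye, isopter)
#' combination. I1e rows are parsed but excluded from the default analysis
#' set; pass `isopters = .ISOPTERS` equivalents to include them.
#'
#' @param points isopter points (as from [read_isopters()]).
#' @param isopters isopter labels to analyze (default V1e, III1e, II1e).
#' @return A `data.frame`: participant_id, eye, isopter, upper_area,
#'   lower_area, vma.
#' @export
vma_table <- function(points, isopters = .VMA_ISOPTERS) {
  keys <- unique(points[, c("participant_id", "eye", "isopter")])
  keys <- keys[keys$isopter %in% isopters, , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    sub <- points[points$participant_id == keys$participant_id[r] &
                    points$eye == keys$eye[r] &
                    points$isopter == keys$isopter[r], , drop = FALSE]
    ch <- isopter_chart(keys$eye[r], keys$isopter[r], sub$angle_deg, sub$radius_deg)
    ar <- hemifield_areas(ch)
    data.frame(participant_id = keys$participant_id[r], eye = keys$eye[r],
               isopter = keys$isopter[r], upper_area = ar$upper_area,
               lower_area = ar$lower_area,
               vma = vma_index(ar$upper_area, ar$lower_area)$vma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
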