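# Idealized parallel-axis stereo rig.
#
# Both cameras share orientation: optical axes along +y of the cage frame,
# image u along +x, image v along -z (rows grow downward). Camera centers sit
# `standoffMm` in front of the cage (y = -standoffMm) at half cage height,
# horizontally separated by the baseline and centered on the cage midline, so
# depth measured from the camera plane is y + standoffMm.

#' @rdname stereoRig
#' @export
setClass("StereoRig",
  representation(
    focalPx = "numeric", baselineMm = "numeric", principalPoint = "numeric",
    imageSize = "integer", standoffMm = "numeric", cageWidth = "numeric",
    cageHeight = "numeric"
  )
)

setValidity("StereoRig", function(object) {
  msg <- character()
  if (object@focalPx <= 0) msg <- c(msg, "focalPx must be positive")
  if (object@baselineMm <= 0) msg <- c(msg, "baselineMm must be positive")
  if (length(object@principalPoint) != 2) msg <- c(msg, "principalPoint must be (u, v)")
  if (length(object@imageSize) != 2 || any(object@imageSize < 1))
    msg <- c(msg, "imageSize must be two positive pixel counts")
  if (object@standoffMm <= 0) msg <- c(msg, "standoffMm must be positive")
  if (length(msg)) msg else TRUE
})

#' Stereo rig model
#'
#' A rectified parallel-axis pinhole camera pair in front of the cage. For a
#' point at depth Z from the camera plane the horizontal disparity is
#' `focalPx * baselineMm / Z`, which [triangulatePoint()] inverts.
#'
#' @param focalPx Focal length in pixels (shared by both cameras).
#' @param baselineMm Horizontal camera separation in mm.
#' @param principalPoint Principal point `(u, v)` in pixels.
#' @param imageSize Image size `(width, height)` in pixels.
#' @param standoffMm Distance from the camera plane to the cage front
#'   (y = 0 plane), in mm.
#' @param cageWidth,cageHeight Cage extent used to center the rig on the
#'   cage midline.
#' @return A `StereoRig` object.
#' @examples
#' rig <- stereoRig()
#' d <- projectPoint(c(75, 75, 75), rig)
#' triangulatePoint(d, rig)
#' @export
stereoRig <- function(focalPx = 800, baselineMm = 60,
                      principalPoint = c(320, 240), imageSize = c(640L, 480L),
                      standoffMm = 250, cageWidth = 150, cageHeight = 150) {
  new("StereoRig", focalPx = focalPx, baselineMm = baselineMm,
      principalPoint = as.numeric(principalPoint),
      imageSize = as.integer(imageSize), standoffMm = standoffMm,
      cageWidth = cageWidth, cageHeight = cageHeight)
}

setMethod("show", "StereoRig", function(object) {
  cat(sprintf("StereoRig: f = %g px, baseline = %g mm, %dx%d px, standoff %g mm\n",
              object@focalPx, object@baselineMm, object@imageSize[1],
              object@imageSize[2], object@standoffMm))
})

.cameraCenters <- function(rig) {
  cx <- rig@cageWidth / 2
  list(left = c(cx - rig@baselineMm / 2, -rig@standoffMm, rig@cageHeight / 2),
       right = c(cx + rig@baselineMm / 2, -rig@standoffMm, rig@cageHeight / 2))
}

#' Project a cage-frame point into both cameras
#'
#' Standard pinhole projection for each camera of the rig. The returned
#' detection is a list with left/right pixel centroids; for this parallel
#' rig the two v coordinates are identical (the epipolar constraint) and
#' disparity `uL - uR` equals `focalPx * baselineMm / depth`.
#'
#' @param p Length-3 cage-frame position (mm).
#' @param rig A [stereoRig()].
#' @return A list with elements `left` and `right`, each a `(u, v)` pixel pair.
#' @export
projectPoint <- function(p, rig) {
  depth <- p[2] + rig@standoffMm
  if (depth <= 0) stop("domain error: point not in front of the cameras")
  cc <- .cameraCenters(rig)
  proj1 <- function(centre) {
    c(u = rig@principalPoint[1] + rig@focalPx * (p[1] - centre[1]) / depth,
      v = rig@principalPoint[2] + rig@focalPx * (centre[3] - p[3]) / depth)
  }
  list(left = proj1(cc$left), right = proj1(cc$right))
}

#' Triangulate a stereo detection back to a 3D cage-frame point
#'
#' Inverts the parallel-rig pinhole model: depth is
#' `focalPx * baselineMm / disparity`, then the pixel offsets from the
#' principal point are back-projected and transformed into the cage frame.
#'
#' @param d A detection as returned by [projectPoint()] (list with `left`
#'   and `right` `(u, v)` pixel pairs; the mean of the two v's is used).
#' @param rig A [stereoRig()].
#' @return Length-3 cage-frame position (mm).
#' @export
triangulatePoint <- function(d, rig) {
  disparity <- d$left[1] - d$right[1]
  if (disparity <= 0)
    stop("degenerate-geometry error: disparity must be positive")
  depth <- rig@focalPx * rig@baselineMm / disparity
  cc <- .cameraCenters(rig)
  v <- (d$left[2] + d$right[2]) / 2
  x <- cc$left[1] + (d$left[1] - rig@principalPoint[1]) * depth / rig@focalPx
  z <- cc$left[3] - (v - rig@principalPoint[2]) * depth / rig@focalPx
  y <- depth - rig@standoffMm
  c(x = unname(x), y = unname(y), z = unname(z))
}

#' Render a synthetic stereo frame pair
#'
#' Draws the fly as a bright disk on a dark background in each camera image,
#' emulating "a white image in the dark background of the cage". If the
#' projected centroid falls outside the image bounds no blob is drawn and
#' the corresponding element carries an `offFrame` attribute.
#'
#' @param p Length-3 cage-frame position (mm).
#' @param rig A [stereoRig()].
#' @param blobRadius Disk radius in pixels.
#' @param background,blobLevel Background and blob intensities in `[0, 1]`.
#' @return List of two numeric matrices (`left`, `right`), indexed
#'   `[row = v, col = u]`.
#' @export
renderFramePair <- function(p, rig, blobRadius = 3, background = 0.08,
                            blobLevel = 0.9) {
  det <- projectPoint(p, rig)
  w <- rig@imageSize[1]; h <- rig@imageSize[2]
  draw <- function(centroid) {
    img <- matrix(background, nrow = h, ncol = w)
    u <- centroid[1]; v <- centroid[2]
    if (u < 1 || u > w || v < 1 || v > h) {
      attr(img, "offFrame") <- TRUE
      return(img)
    }
    cols <- max(1, floor(u - blobRadius - 1)):min(w, ceiling(u + blobRadius + 1))
    rows <- max(1, floor(v - blobRadius - 1)):min(h, ceiling(v + blobRadius + 1))
    dd <- outer((rows - v)^2, (cols - u)^2, "+")
    img[rows, cols][dd <= blobRadius^2] <- blobLevel
    img
  }
  list(left = draw(det$left), right = draw(det$right))
}

#' Detect the fly centroid in a single-channel image
#'
#' Thresholds the image (Otsu's method via EBImage by default, or a fixed
#' threshold) and returns the intensity-weighted centroid of the
#' above-threshold pixels, or `NULL` when nothing passes.
#'
#' @param img Numeric matrix, intensities in `[0, 1]`, indexed `[v, u]`.
#' @param threshold `"otsu"` or a fixed numeric cutoff.
#' @return `(u, v)` pixel centroid, or `NULL` if no pixel is above threshold.
#' @export
detectFly <- function(img, threshold = "otsu") {
  if (!is.matrix(img) || length(img) == 0)
    stop("validation error: img must be a non-empty numeric matrix")
  thr <- if (identical(threshold, "otsu")) {
    if (diff(range(img)) < .Machine$double.eps) return(NULL)
    EBImage::otsu(EBImage::Image(img), range = range(img))
  } else threshold
  sel <- which(img > thr, arr.ind = TRUE)
  if (nrow(sel) == 0) return(NULL)
  wts <- img[sel]
  c(u = sum(sel[, 2] * wts) / sum(wts), v = sum(sel[, 1] * wts) / sum(wts))
}

#' Render, detect and triangulate a position through the full image pipeline
#'
#' Convenience wrapper chaining [renderFramePair()], [detectFly()] and
#' [triangulatePoint()]; returns `NULL` when the fly is off-frame in either
#' camera (downstream treats such frames as missing data).
#'
#' @inheritParams renderFramePair
#' @param threshold Passed to [detectFly()].
#' @return Recovered length-3 position, or `NULL`.
#' @export
stereoRoundTrip <- function(p, rig, blobRadius = 3, threshold = "otsu") {
  imgs <- renderFramePair(p, rig, blobRadius = blobRadius)
  dl <- detectFly(imgs$left, threshold); dr <- detectFly(imgs$right, threshold)
  if (is.null(dl) || is.null(dr) || isTRUE(attr(imgs$left, "offFrame")) ||
      isTRUE(attr(imgs$right, "offFrame"))) return(NULL)
  triangulatePoint(list(left = dl, right = dr), rig)
}
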