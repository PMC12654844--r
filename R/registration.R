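#' @title Plate image registration
#' @name registration
#'
#' @description
#' Each plate series is quantified on the pixel grid of its reference frame
#' (the last incubation time point). Earlier frames are realigned to that
#' template by a plane-projective transformation (homography) anchored to the
#' four plate corners: four point correspondences determine the homography
#' exactly. Corner anchors are either detected from bright fiducial marks in
#' the image quadrants or supplied in the layout.
NULL

# ---- plane transforms -------------------------------------------------------

#' Construct a plane transform
#'
#' Wraps a 3x3 homogeneous matrix mapping source (x, y) to template (x, y).
#' The matrix is normalized so its bottom-right entry is 1 and the transform
#' kind is classified as `identity`, `affine` or `projective` (within
#' tolerance 1e-9 of the subfamily).
#'
#' @param matrix Invertible 3x3 matrix acting on homogeneous `(x, y, 1)`.
#' @return Object of class `plane_transform`.
#' @export
plane_transform <- function(matrix) {
  m <- as.matrix(matrix)
  stopifnot(all(dim(m) == c(3, 3)))
  if (abs(m[3, 3]) < 1e-12) stop("degenerate homography: H[3,3] ~ 0", call. = FALSE)
  m <- m / m[3, 3]
  if (abs(det(m)) < 1e-12) stop("transform matrix is not invertible", call. = FALSE)
  tol <- 1e-9
  kind <- if (max(abs(m - diag(3))) < tol) "identity"
          else if (max(abs(m[3, 1:2])) < tol) "affine"
          else "projective"
  structure(list(kind = kind, matrix = m), class = "plane_transform")
}

#' @export
print.plane_transform <- function(x, ...) {
  cat(sprintf("plane_transform (%s)\n", x$kind))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Apply a plane transform to point coordinates
#'
#' @param t A `plane_transform`.
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
transform_points <- function(t, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  h <- t$matrix %*% rbind(t(xy), 1)
  out <- t(h[1:2, , drop = FALSE] / rep(h[3, ], each = 2))
  dimnames(out) <- NULL
  out
}

#' Invert a plane transform
#' @param t A `plane_transform`.
#' @return The inverse `plane_transform`.
#' @export
invert_transform <- function(t) plane_transform(solve(t$matrix))

#' Estimate the homography carrying source corners onto template corners
#'
#' Four point correspondences determine a plane-projective map exactly; the
#' 8 unknown entries (with `H[3,3] = 1`) are solved from the 8 linear
#' incidence equations. When the fitted matrix lies within tolerance of the
#' affine or identity subfamily the transform kind is downgraded accordingly.
#'
#' @param source_corners,template_corners 4x2 matrices of corresponding
#'   (x, y) corner coordinates in the same (clockwise) order.
#' @return A `plane_transform` mapping source to template coordinates with
#'   corner residual below 0.5 px (machine precision for exact input).
#' @export
estimate_transform <- function(source_corners, template_corners) {
  s <- as.matrix(source_corners); d <- as.matrix(template_corners)
  stopifnot(all(dim(s) == c(4, 2)), all(dim(d) == c(4, 2)))
  # collinearity of any 3 source points makes the system singular
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    stop("degenerate corner configuration (collinear points?)", call. = FALSE)
  })
  m <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  t <- plane_transform(m)
  res <- sqrt(rowSums((transform_points(t, s) - d)^2))
  if (max(res) > 0.5) {
    stop(sprintf("corner residual %.3g px exceeds 0.5 px", max(res)), call. = FALSE)
  }
  t$corner_residual <- max(res)
  t
}

# ---- image warping ----------------------------------------------------------

#' Resample an image onto the template grid under a plane transform
#'
#' Computes `out(x_t) = image(T^-1(x_t))` by inverse mapping with bilinear
#' interpolation. Pixels mapping outside the source frame are filled with the
#' background value 0 (fill never creates foreground). Images are numeric
#' matrices with intensities in `[0, 1]`; matrix element `[r, c]` is the pixel
#' at 0-based coordinates `x = c - 1`, `y = r - 1`.
#'
#' @param image Numeric intensity matrix.
#' @param t A `plane_transform` mapping source to template coordinates.
#' @param dim_out Output dimensions `c(nrow, ncol)`; defaults to `dim(image)`.
#' @return Warped intensity matrix on the template grid.
#' @export
apply_transform <- function(image, t, dim_out = dim(image)) {
  if (t$kind == "identity") return(image)
  inv <- solve(t$matrix)
  nr <- dim_out[1]; nc <- dim_out[2]
  xt <- rep(seq_len(nc) - 1, each = nr)     # template x per output element
  yt <- rep(seq_len(nr) - 1, times = nc)    # template y
  den <- inv[3, 1] * xt + inv[3, 2] * yt + inv[3, 3]
  xs <- (inv[1, 1] * xt + inv[1, 2] * yt + inv[1, 3]) / den
  ys <- (inv[2, 1] * xt + inv[2, 2] * yt + inv[2, 3]) / den
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  snr <- nrow(image); snc <- ncol(image)
  # gather with zero fill outside the source frame
  px <- function(xi, yi) {
    ok <- xi >= 0 & xi <= snc - 1 & yi >= 0 & yi <= snr - 1
    v <- numeric(length(xi))
    v[ok] <- image[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  v <- (1 - fx) * (1 - fy) * px(x0, y0) +
       fx * (1 - fy)       * px(x0 + 1, y0) +
       (1 - fx) * fy       * px(x0, y0 + 1) +
       fx * fy             * px(x0 + 1, y0 + 1)
  matrix(v, nrow = nr, ncol = nc)
}

# ---- corner acquisition -----------------------------------------------------

#' Detect the four corner fiducial marks of a plate image
#'
#' Searches the outermost region of each image quadrant for a compact bright
#' blob (the rendered fiducial disk) and returns its intensity-weighted
#' centroid. Real photographs without fiducials should instead supply corners
#' in the layout (`corners` argument bypasses detection).
#'
#' @param image Intensity matrix in `[0, 1]`.
#' @param corners Optional manual override: a 4x2 matrix returned unchanged.
#' @param window Side of the square corner search window in pixels (default
#'   110, capped at a third of the smaller image dimension); it must cover
#'   the fiducial without reaching the drop ROIs.
#' @return 4x2 matrix of corner estimates, clockwise from top-left.
#' @export
detect_corners <- function(image, corners = NULL, window = NULL) {
  if (!is.null(corners)) {
    corners <- as.matrix(corners)
    stopifnot(all(dim(corners) == c(4, 2)))
    return(corners)
  }
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(window)) window <- min(110, floor(min(nr, nc) / 3))
  w <- window
  # windows clockwise from top-left, as (row range, col range)
  wins <- list(list(1:w, 1:w),
               list(1:w, (nc - w + 1):nc),
               list((nr - w + 1):nr, (nc - w + 1):nc),
               list((nr - w + 1):nr, 1:w))
  est <- matrix(NA_real_, 4, 2)
  for (i in 1:4) {
    sub <- image[wins[[i]][[1]], wins[[i]][[2]]]
    bg <- stats::median(sub)
    thr <- bg + 0.5 * (max(sub) - bg)
    mask <- sub > thr
    if (max(sub) - bg < 0.1 || sum(mask) < 4) {
      stop(paste("fewer than 4 fiducial marks found;",
                 "supply corner coordinates manually"), call. = FALSE)
    }
    wgt <- (sub - bg) * mask
    rows <- row(sub); cols <- col(sub)
    cy <- sum(rows * wgt) / sum(wgt) - 1 + (wins[[i]][[1]][1] - 1)
    cx <- sum(cols * wgt) / sum(wgt) - 1 + (wins[[i]][[2]][1] - 1)
    est[i, ] <- c(cx, cy)
  }
  est
}

# ---- template construction --------------------------------------------------

#' Build a drop-position template from the reference image
#'
#' Defines the layout on the reference frame's pixel grid from user-picked
#' (or truth-table) drop centers and the four corner anchors.
#'
#' @param reference_image Intensity matrix of the final time point.
#' @param drop_coordinates n x 2 matrix of drop centers (x, y).
#' @param corner_coordinates 4x2 corner matrix, clockwise from top-left.
#' @param plate_id Plate identifier (default `"plate"`).
#' @param roi_radius Common ROI radius in pixels (default 40).
#' @param drops Optional metadata drop table; coordinates are overwritten
#'   from `drop_coordinates`.
#' @return A validated [plate_layout()].
#' @export
build_template <- function(reference_image, drop_coordinates,
                           corner_coordinates, plate_id = "plate",
                           roi_radius = 40, drops = NULL) {
  dc <- as.matrix(drop_coordinates)
  nr <- nrow(reference_image); nc <- ncol(reference_image)
  all_pts <- rbind(dc, as.matrix(corner_coordinates))
  if (any(all_pts[, 1] < 0 | all_pts[, 1] > nc - 1 |
          all_pts[, 2] < 0 | all_pts[, 2] > nr - 1)) {
    stop("coordinates outside image bounds", call. = FALSE)
  }
  if (is.null(drops)) {
    drops <- drop_table(drop_id = sprintf("drop%02d", seq_len(nrow(dc))),
                        cx = dc[, 1], cy = dc[, 2], roi_radius = roi_radius)
  } else {
    drops$cx <- dc[, 1]; drops$cy <- dc[, 2]
    if (!"roi_radius" %in% names(drops) || all(is.na(drops$roi_radius))) {
      drops$roi_radius <- roi_radius
    }
  }
  plate_layout(plate_id, width_px = nc, height_px = nr,
               corners = corner_coordinates, drops = drops)
}

# ---- series containers and registration driver ------------------------------

#' Construct a plate image series
#'
#' @param plate_id Plate identifier.
#' @param days Numeric vector of imaging days, strictly increasing.
#' @param images List of intensity matrices, one per day, sharing one pixel
#'   grid. The last frame is the reference.
#' @return Object of class `plate_image_series`.
#' @export
plate_image_series <- function(plate_id, days, images) {
  stopifnot(length(days) == length(images), length(days) >= 1)
  if (is.unsorted(days, strictly = TRUE)) {
    stop("frame days must be strictly increasing", call. = FALSE)
  }
  structure(list(plate_id = as.character(plate_id), days = as.numeric(days),
                 images = images, reference_index = length(images)),
            class = "plate_image_series")
}

#' @export
print.plate_image_series <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("plate_image_series '%s': %d frames (%s), %d x %d px\n",
              x$plate_id, length(x$days), paste(x$days, collapse = ", "),
              d[2], d[1]))
  invisible(x)
}

#' Convert an RGB array to grayscale luminance
#'
#' @param img Either a matrix (returned unchanged) or an h x w x 3 array.
#' @return Intensity matrix (Rec. 709 luminance).
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    if (ch >= 3) {
      return(0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3])
    }
    return(img[, , 1])
  }
  stop("unsupported image dimensions", call. = FALSE)
}

#' Realign every frame of a series to the layout template
#'
#' For each frame, corners are detected (or taken from the layout when
#' `use_fiducials = FALSE`), the frame-to-template homography is estimated,
#' and the frame is resampled onto the template grid. Drop metadata is never
#' touched by registration.
#'
#' @param series A [plate_image_series()].
#' @param layout The plate's [plate_layout()]; its `corners` are the template
#'   anchors.
#' @param use_fiducials Detect corners from fiducial marks (default `TRUE`);
#'   otherwise frames are assumed already aligned.
#' @return A `plate_image_series` of registered frames with an added
#'   `transforms` element (list of `plane_transform`).
#' @export
register_series <- function(series, layout, use_fiducials = TRUE) {
  tmpl <- layout$corners
  out <- series
  out$transforms <- vector("list", length(series$images))
  for (i in seq_along(series$images)) {
    img <- to_grayscale(series$images[[i]])
    src <- if (use_fiducials) detect_corners(img) else tmpl
    t <- estimate_transform(src, tmpl)
    out$images[[i]] <- if (t$kind == "identity") img else apply_transform(img, t)
    out$transforms[[i]] <- t
  }
  out
}
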