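## Nuclear DNA-damage marker quantification: z-projection, integrated
## nuclear intensity, and focus counting via the h-maxima transform
## (regional maxima with dynamic >= h, obtained by grayscale morphological
## reconstruction of image - h under the image; 8-connectivity).

#' Z-projection of an image stack
#'
#' Collapses a 3-D intensity stack to a 2-D image, per pixel.  Maximum
#' projection is the default; sum projection is available.  A 2-D input is
#' returned unchanged (projection is idempotent).
#'
#' @param stack numeric matrix (2-D) or array (rows x cols x slices).
#' @param method `"max"` (default) or `"sum"`.
#' @return numeric matrix.
#' @export
z_project <- function(stack, method = c("max", "sum")) {
  method <- match.arg(method)
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L || any(dim(stack) == 0L))
    stop("stack must be a non-empty matrix or 3-D array")
  out <- stack[, , 1L]
  if (dim(stack)[3L] > 1L) {
    for (k in 2L:dim(stack)[3L]) {
      out <- if (method == "max") pmax(out, stack[, , k]) else
        out + stack[, , k]
    }
  }
  out
}

#' Grayscale morphological reconstruction by dilation
#'
#' Iteratively dilates `marker` (8-connected) while clamping it under
#' `mask`, to stability.  Exposed mainly as the building block of
#' [count_foci()].
#'
#' @param marker,mask numeric matrices of equal dimension; `marker` is
#'   clamped to `pmin(marker, mask)` before reconstruction.
#' @return numeric matrix, the reconstruction.
#' @export
morph_reconstruct <- function(marker, mask) {
  stopifnot(is.matrix(marker), is.matrix(mask),
            all(dim(marker) == dim(mask)))
  morph_reconstruct_cpp(pmin(marker, mask), mask)
}

# regional maxima (8-connected plateaus with no higher neighbour) of a
# numeric image, as a logical mask
.regional_maxima <- function(image) {
  rng <- max(image) - min(image)
  if (rng == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  delta <- rng * 1e-9
  rec <- morph_reconstruct_cpp(image - delta, image)
  (image - rec) > delta / 2
}

#' Count foci via the h-maxima transform
#'
#' Suppresses every local maximum whose dynamic (height above the
#' surrounding reconstruction) is below `h` by reconstructing `image - h`
#' under `image`, then counts the 8-connected regional maxima of the result
#' that intersect the nucleus mask.  The count is invariant under adding a
#' constant to the image and monotone non-increasing in `h`.
#'
#' @param image 2-D numeric intensity image (z-project stacks first).
#' @param nucleus_mask logical matrix of the same dimension; must contain at
#'   least one `TRUE` pixel.
#' @param h positive dynamic threshold, in intensity units.  There is no
#'   default: `h` must be chosen relative to the spot amplitude and noise of
#'   the data at hand.
#' @return integer focus count.
#' @export
count_foci <- function(image, nucleus_mask, h) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("h must be a single positive number")
  stopifnot(is.matrix(image), all(dim(nucleus_mask) == dim(image)))
  nucleus_mask <- matrix(as.logical(nucleus_mask), nrow(image), ncol(image))
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  if (max(image) == min(image)) return(0L)
  hmax <- morph_reconstruct_cpp(image - h, image)
  peaks <- .regional_maxima(hmax) & nucleus_mask
  max(label_components_cpp(peaks))
}

#' Integrated intensity within a mask
#'
#' @param image 2-D numeric image.
#' @param nucleus_mask logical matrix of the same dimension, non-empty.
#' @return sum of pixel intensities over the mask.
#' @export
integrated_intensity <- function(image, nucleus_mask) {
  stopifnot(is.matrix(image), all(dim(nucleus_mask) == dim(image)))
  nucleus_mask <- matrix(as.logical(nucleus_mask), nrow(image), ncol(image))
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  sum(image[nucleus_mask])
}

#' Normalize measurements to a control group
#'
#' Divides every value by the mean of the control values, so the normalized
#' control mean equals 1 by construction.
#'
#' @param values numeric measurements.
#' @param control_values numeric control measurements with positive mean.
#' @return numeric vector of normalized values.
#' @export
normalize_to_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  values / m
}

#' Simple threshold mask
#'
#' Fixture helper producing a nucleus-style mask by global thresholding;
#' real segmentation is out of scope and masks are normally inputs.
#'
#' @param image 2-D numeric image.
#' @param threshold intensity cutoff; pixels strictly above it are `TRUE`.
#' @return logical matrix.
#' @export
threshold_mask <- function(image, threshold) {
  image > threshold
}

#' Read / write grayscale TIFF stacks
#'
#' Intensities are stored as 16-bit TIFF scaled by `max_value`; reading
#' restores the original scale.  Multi-slice files become 3-D arrays.
#'
#' @param file path to the TIFF.
#' @param max_value intensity corresponding to the top of the 16-bit range.
#' @return `read_image_stack`: matrix or 3-D array.
#' @export
read_image_stack <- function(file, max_value = 65535) {
  sl <- tiff::readTIFF(file, all = TRUE)
  sl <- lapply(sl, function(m) m * max_value)
  if (length(sl) == 1L) return(sl[[1L]])
  array(unlist(sl), dim = c(dim(sl[[1L]]), length(sl)))
}

#' @rdname read_image_stack
#' @param stack matrix or 3-D array of non-negative intensities
#'   `<= max_value`.
#' @return `write_image_stack`: `file`, invisibly.
#' @export
write_image_stack <- function(stack, file, max_value = 65535) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (min(stack) < 0 || max(stack) > max_value)
    stop("intensities must lie in [0, max_value]")
  sl <- lapply(seq_len(dim(stack)[3L]), function(k)
    stack[, , k] / max_value)
  tiff::writeTIFF(sl, file, bits.per.sample = 16L)
  invisible(file)
}
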