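# Electrostatic-surface image handling.
#
# Rendered pHLA surfaces are RGBA rasters in which red marks negatively and
# blue positively charged surface regions. Each image is reduced to a single
# composite matrix (red - blue + transparency) that contrasts the two
# electrostatic extremes; pixels whose composite varies across epitopes more
# than the median pixel, restricted to the central region facing the TCR,
# form the informative-pixel mask. Image-space similarity is the Canberra
# distance over (masked) composite pixels.

#' Decompose a PNG render into channel matrices
#'
#' @param source PNG bytes (raw vector) or a file path.
#' @param epitope_id,perspective Metadata carried on the result.
#' @return A `SurfaceImage`: list with `red`, `green`, `blue`, `alpha`
#'   (width x height matrices in `[0,1]`; images without an alpha channel get
#'   `alpha = 1` everywhere), the derived `composite`, and the metadata.
#' @details Matrices are stored width x height (a 640x480 render gives four
#'   640x480 matrices).
#' @export
decompose_image <- function(source, epitope_id = NA_character_,
                            perspective = NA_character_) {
  arr <- tryCatch(png::readPNG(source),
                  error = function(e) stop("cannot decode PNG: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(arr)) == 2L) {            # greyscale
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  }
  nc <- dim(arr)[3]
  tp <- function(k) t(arr[, , k])          # height x width -> width x height
  red <- tp(1)
  green <- if (nc >= 2) tp(2) else red
  blue <- if (nc >= 3) tp(3) else red
  alpha <- if (nc >= 4) tp(4) else array(1, dim = dim(red))
  img <- structure(
    list(epitope_id = epitope_id, perspective = perspective,
         red = red, green = green, blue = blue, alpha = alpha),
    class = "SurfaceImage"
  )
  img$composite <- composite(img)
  img
}

#' Composite matrix of a surface image: red - blue + transparency
#'
#' @param img A `SurfaceImage` (or a list with `red`, `blue`, `alpha`
#'   matrices).
#' @return Matrix with entries in `[-1, 2]`.
#' @export
composite <- function(img) {
  d <- dim(img$red)
  if (!identical(d, dim(img$blue)) || !identical(d, dim(img$alpha))) {
    stop("channel matrices have mismatched shapes", call. = FALSE)
  }
  img$red - img$blue + img$alpha
}

#' Informative-pixel mask from composite variability
#'
#' Computes the per-pixel standard deviation over the non-excluded composite
#' matrices and keeps pixels whose SD strictly exceeds the median of all
#' per-pixel SDs, intersected with a centered rectangle covering
#' `central_fraction` of each image dimension.
#'
#' @param composites List of equally shaped composite matrices.
#' @param exclude Logical vector marking composites to leave out of the SD
#'   (e.g. synthetic sequence variants that would bias variability).
#' @param central_fraction Fraction of each axis covered by the central
#'   region, in `(0, 1]`.
#' @return A `PixelMask`: list with logical matrix `keep` and
#'   `central_fraction`.
#' @export
variability_mask <- function(composites, exclude = NULL,
                             central_fraction = 0.5) {
  stopifnot(is.list(composites))
  if (is.null(exclude)) exclude <- rep(FALSE, length(composites))
  use <- composites[!exclude]
  if (length(use) < 2L) {
    stop("need at least 2 non-excluded composites", call. = FALSE)
  }
  d <- dim(use[[1]])
  if (!all(vapply(use, function(m) identical(dim(m), d), logical(1)))) {
    stop("composites have mismatched shapes", call. = FALSE)
  }
  if (central_fraction <= 0 || central_fraction > 1) {
    stop("central_fraction must be in (0, 1]", call. = FALSE)
  }
  stack <- array(unlist(use), dim = c(d, length(use)))
  m1 <- apply(stack, c(1, 2), mean)
  m2 <- apply(stack^2, c(1, 2), mean)
  n <- length(use)
  sd_mat <- sqrt(pmax(0, (m2 - m1^2) * n / (n - 1)))
  keep <- sd_mat > stats::median(sd_mat)
  keep <- keep & central_region(d, central_fraction)
  structure(list(keep = keep, central_fraction = central_fraction),
            class = "PixelMask")
}

# Centered axis-aligned rectangle covering `fraction` of each dimension.
central_region <- function(d, fraction) {
  span <- function(n) {
    k <- max(1L, round(n * fraction))
    lo <- floor((n - k) / 2) + 1L
    seq.int(lo, lo + k - 1L)
  }
  out <- matrix(FALSE, d[1], d[2])
  out[span(d[1]), span(d[2])] <- TRUE
  out
}

#' Canberra distance between two composite matrices
#'
#' `sum(|a - b| / (|a| + |b|))` over (masked) pixels; terms with a zero
#' denominator contribute 0.
#'
#' @param a,b Matrices of identical shape.
#' @param mask Optional `PixelMask` (or logical matrix) restricting the sum.
#' @export
image_distance <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b))) {
    stop("matrices have mismatched shapes", call. = FALSE)
  }
  if (!is.null(mask)) {
    keep <- if (inherits(mask, "PixelMask")) mask$keep else mask
    if (!identical(dim(keep), dim(a))) {
      stop("mask shape does not match images", call. = FALSE)
    }
    a <- a[keep]
    b <- b[keep]
  }
  canberra(as.numeric(a), as.numeric(b))
}

# Canberra with the 0/0 -> 0 convention, shared by image and vector callers.
canberra <- function(u, v) {
  num <- abs(u - v)
  den <- abs(u) + abs(v)
  ok <- den > 0
  sum(num[ok] / den[ok])
}

#' Image distance across one or all perspectives
#'
#' With `mode = "single"` computes [image_distance()] on the named
#' perspective; with `mode = "all"` concatenates the masked pixel vectors of
#' every perspective on both sides and computes one Canberra distance on the
#' concatenation.
#'
#' @param images_a,images_b Named lists of composite matrices (names are
#'   perspectives, e.g. `"TOP"`).
#' @param masks Optional named list of `PixelMask`es per perspective.
#' @param mode `"single"` or `"all"`.
#' @param perspective Perspective name, required for `mode = "single"`.
#' @export
multi_perspective_distance <- function(images_a, images_b, masks = NULL,
                                       mode = c("single", "all"),
                                       perspective = "TOP") {
  mode <- match.arg(mode)
  if (mode == "all" &&
      !setequal(names(images_a), names(images_b))) {
    stop("missing perspective(s): ",
         paste(union(setdiff(names(images_a), names(images_b)),
                     setdiff(names(images_b), names(images_a))),
               collapse = ", "), call. = FALSE)
  }
  persp <- if (mode == "single") perspective else names(images_a)
  missing_p <- setdiff(persp, intersect(names(images_a), names(images_b)))
  if (length(missing_p)) {
    stop("missing perspective(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  pull <- function(imgs, p) {
    m <- imgs[[p]]
    if (!is.null(masks) && !is.null(masks[[p]])) {
      keep <- if (inherits(masks[[p]], "PixelMask")) masks[[p]]$keep
              else masks[[p]]
      m[keep]
    } else as.numeric(m)
  }
  u <- unlist(lapply(persp, pull, imgs = images_a), use.names = FALSE)
  v <- unlist(lapply(persp, pull, imgs = images_b), use.names = FALSE)
  if (length(u) != length(v)) stop("pixel vectors differ in length",
                                   call. = FALSE)
  canberra(u, v)
}
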