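#' Decode and preprocess a radiograph image
#'
#' Decodes PNG (or JPEG, when the jpeg package is installed), collapses RGB
#' to luminance (0.299 R + 0.587 G + 0.114 B), bilinearly resizes to
#' `side x side` and scales intensities to `[0, 1]` (8- and 16-bit inputs
#' both decode to `[0, 1]`).
#'
#' @param image a file path, or an already-decoded numeric matrix / array
#' @param side target spatial side (default 224)
#' @return numeric matrix `side x side` with values in `[0, 1]`
#' @export
preprocess_image <- function(image, side = 224L) {
  if (is.character(image)) {
    path <- image
    if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    image <- if (ext == "png") {
      tryCatch(png::readPNG(path),
               error = function(e) stop("undecodable PNG: ", path,
                                        call. = FALSE))
    } else if (ext %in% c("jpg", "jpeg")) {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("JPEG decoding needs the 'jpeg' package: ", path, call. = FALSE)
      }
      tryCatch(jpeg::readJPEG(path),
               error = function(e) stop("undecodable JPEG: ", path,
                                        call. = FALSE))
    } else {
      stop("unsupported image format '", ext, "': ", path, call. = FALSE)
    }
  }
  d <- dim(image)
  if (length(d) == 3L) {
    image <- if (d[3L] >= 3L) {
      0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
    } else {
      image[, , 1L]
    }
  }
  image <- pmin(pmax(image, 0), 1)
  resize_bilinear(image, side, side)
}

# Bilinear resize with half-pixel-centre alignment.
resize_bilinear <- function(m, h2, w2) {
  h1 <- nrow(m); w1 <- ncol(m)
  if (h1 == h2 && w1 == w2) return(m)
  ry <- h1 / h2; rx <- w1 / w2
  y <- pmin(pmax((seq_len(h2) - 0.5) * ry - 0.5, 0), h1 - 1)
  x <- pmin(pmax((seq_len(w2) - 0.5) * rx - 0.5, 0), w1 - 1)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- pmin(y0 + 1, h1 - 1); x1 <- pmin(x0 + 1, w1 - 1)
  wy <- y - y0; wx <- x - x0
  a <- m[y0 + 1, x0 + 1, drop = FALSE]
  b <- m[y0 + 1, x1 + 1, drop = FALSE]
  cc <- m[y1 + 1, x0 + 1, drop = FALSE]
  dd <- m[y1 + 1, x1 + 1, drop = FALSE]
  wym <- matrix(wy, h2, w2)
  wxm <- matrix(wx, h2, w2, byrow = TRUE)
  a * (1 - wym) * (1 - wxm) + b * (1 - wym) * wxm +
    cc * wym * (1 - wxm) + dd * wym * wxm
}

#' Load, preprocess and stack the images of a manifest
#'
#' @param manifest a `cxr_manifest` with a non-NULL `image_dir`
#' @param side target spatial side
#' @return numeric array `(side, side, n)` in manifest record order
#' @export
load_images <- function(manifest, side = 224L) {
  if (is.null(manifest$image_dir)) {
    stop("manifest has no image_dir", call. = FALSE)
  }
  ids <- manifest$records$image_id
  out <- array(0, c(side, side, length(ids)))
  for (i in seq_along(ids)) {
    out[, , i] <- preprocess_image(file.path(manifest$image_dir, ids[i]),
                                   side = side)
  }
  out
}
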