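#' Specification for a synthetic multi-label image dataset
#'
#' Emulates the structure of a multi-label chest-radiograph collection:
#' grayscale `side x side` images, `L` binary finding labels with
#' configurable per-class prevalence and positive label co-occurrence, one
#' fixed class-specific planted pattern per class (present in an image iff
#' the label is 1), and additive Gaussian pixel noise. Fully deterministic
#' given the seed.
#'
#' Label co-occurrence uses a per-image latent severity factor: class `k` of
#' image `i` is Bernoulli with probability
#' `plogis(qlogis(prevalence[k]) + co_occurrence * u_i)`, `u_i ~ N(0, 1)`,
#' so `co_occurrence = 0` gives independent labels and larger values give
#' positively correlated findings (as co-morbid pathologies are).
#'
#' @param n_images number of images
#' @param image_side spatial side (default 224)
#' @param n_classes number of finding classes (default 14)
#' @param prevalence per-class positive rates in `[0, 1]`; default a
#'   decreasing, imbalanced profile from 0.30 to 0.08
#' @param co_occurrence latent-factor strength (>= 0, default 0.75)
#' @param amplitude planted-pattern intensity amplitude (default 0.5)
#' @param background mean background intensity (default 0.25)
#' @param noise_sigma additive Gaussian noise s.d. (default 0.1)
#' @param seed RNG seed
#' @return an object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_images = 200L, image_side = 224L,
                           n_classes = 14L,
                           prevalence = seq(0.30, 0.08,
                                            length.out = n_classes),
                           co_occurrence = 0.75, amplitude = 0.5,
                           background = 0.25, noise_sigma = 0.1,
                           seed = 1L) {
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalence values must lie in [0, 1]", call. = FALSE)
  }
  if (length(prevalence) != n_classes) {
    stop("prevalence must have one entry per class", call. = FALSE)
  }
  stopifnot(n_images >= 1, image_side >= 32, n_classes >= 1,
            co_occurrence >= 0, noise_sigma >= 0)
  structure(list(n_images = as.integer(n_images),
                 image_side = as.integer(image_side),
                 n_classes = as.integer(n_classes),
                 prevalence = prevalence, co_occurrence = co_occurrence,
                 amplitude = amplitude, background = background,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Planted pattern templates, one per class
#'
#' A catalogue of fixed geometric templates (Gaussian blobs, rings, bars,
#' squares, crosses) at distinct locations on the image grid, unit peak
#' amplitude. The templates are what each positive label deposits on an
#' image; they also drive the matched-filter oracle.
#'
#' @param side image side
#' @param n_classes number of classes (max 14)
#' @return list of `side x side` matrices in `[0, 1]`
#' @export
class_templates <- function(side = 224L, n_classes = 14L) {
  stopifnot(n_classes <= 14L)
  gx <- matrix(seq_len(side), side, side)
  gy <- matrix(seq_len(side), side, side, byrow = TRUE)
  blob <- function(cx, cy, s) exp(-((gx - cx * side)^2 + (gy - cy * side)^2) /
                                    (2 * (s * side)^2))
  ring <- function(cx, cy, r, wdt) {
    d <- sqrt((gx - cx * side)^2 + (gy - cy * side)^2)
    exp(-((d - r * side)^2) / (2 * (wdt * side)^2))
  }
  bar <- function(cx, w, vertical = TRUE) {
    d <- if (vertical) abs(gy - cx * side) else abs(gx - cx * side)
    exp(-d^2 / (2 * (w * side)^2)) *
      exp(-((if (vertical) gx else gy) - side / 2)^2 / (2 * (0.3 * side)^2))
  }
  diagbar <- function(off, w) {
    d <- abs(gx - gy + off * side) / sqrt(2)
    exp(-d^2 / (2 * (w * side)^2))
  }
  sq <- function(cx, cy, half) {
    as.numeric(abs(gx - cx * side) < half * side &
                 abs(gy - cy * side) < half * side)
  }
  cross <- function(cx, cy, w, len) {
    v <- exp(-(gx - cx * side)^2 / (2 * (w * side)^2)) *
      (abs(gy - cy * side) < len * side)
    h <- exp(-(gy - cy * side)^2 / (2 * (w * side)^2)) *
      (abs(gx - cx * side) < len * side)
    pmin(v + h, 1)
  }
  cat14 <- list(
    blob(0.20, 0.20, 0.06),
    blob(0.80, 0.20, 0.06),
    blob(0.20, 0.80, 0.06),
    blob(0.80, 0.80, 0.06),
    ring(0.50, 0.50, 0.18, 0.03),
    ring(0.30, 0.55, 0.09, 0.025),
    bar(0.35, 0.03, vertical = TRUE),
    bar(0.65, 0.03, vertical = FALSE),
    diagbar(0.00, 0.03),
    sq(0.50, 0.20, 0.06),
    sq(0.20, 0.50, 0.06),
    cross(0.70, 0.55, 0.02, 0.12),
    ring(0.70, 0.35, 0.06, 0.02),
    blob(0.45, 0.70, 0.09)
  )
  lapply(cat14[seq_len(n_classes)], function(m) m / max(m))
}

#' Generate a synthetic multi-label image dataset
#'
#' Draws labels from the spec's prevalence/co-occurrence model, deposits the
#' class templates of every positive label on a noisy background, quantises
#' to 8-bit grayscale PNG files and writes an NIH-dialect CSV manifest
#' (`manifest.csv`) next to them. Byte-identical across runs for a fixed
#' spec.
#'
#' @param spec a [synthetic_spec()]
#' @param dir output directory (created if missing)
#' @return the generated `cxr_manifest` (invisibly readable back with
#'   [read_manifest()])
#' @export
generate_synthetic <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- synth_arrays(spec)
  ids <- sprintf("synth_%04d.png", seq_len(spec$n_images))
  for (i in seq_len(spec$n_images)) {
    png::writePNG(r$images[, , i], file.path(dir, ids[i]))
  }
  vocab <- utils::head(cxr14_vocabulary(include_sentinel = FALSE),
                       spec$n_classes)
  findings <- lapply(seq_len(spec$n_images), function(i) {
    pos <- vocab[r$labels[i, ] == 1L]
    if (length(pos) == 0L) sentinel else pos
  })
  man <- new_manifest(ids, findings, c(vocab, sentinel), dir)
  write_manifest(man, file.path(dir, "manifest.csv"))
  man
}

# In-memory generation: images (side, side, n) in [0,1] (8-bit quantised so
# written PNGs round-trip exactly), labels n x L.
synth_arrays <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_images; side <- spec$image_side; L <- spec$n_classes
  u <- rnorm(n)
  labels <- matrix(0L, n, L)
  for (k in seq_len(L)) {
    p <- if (spec$prevalence[k] <= 0) rep(0, n)
         else if (spec$prevalence[k] >= 1) rep(1, n)
         else plogis(qlogis(spec$prevalence[k]) + spec$co_occurrence * u)
    labels[, k] <- rbinom(n, 1L, p)
  }
  tmpl <- class_templates(side, L)
  images <- array(0, c(side, side, n))
  for (i in seq_len(n)) {
    img <- matrix(spec$background, side, side)
    for (k in which(labels[i, ] == 1L)) {
      img <- img + spec$amplitude * tmpl[[k]]
    }
    img <- img + rnorm(side * side, sd = spec$noise_sigma)
    img <- pmin(pmax(img, 0), 1)
    images[, , i] <- round(img * 255) / 255
  }
  list(images = images, labels = labels)
}

#' Matched-filter oracle scores for planted-template images
#'
#' Correlates every class template against every image (template-matching),
#' giving a per-class score matrix that upper-bounds how separable the
#' planted classes are. Used to validate synthetic fixtures independently of
#' any trained model.
#'
#' @param images array `(side, side, n)`
#' @param n_classes number of classes
#' @return numeric matrix `n x n_classes` of matched-filter scores
#' @export
matched_filter_scores <- function(images, n_classes = 14L) {
  side <- dim(images)[1L]
  n <- dim(images)[3L]
  tmpl <- class_templates(side, n_classes)
  tm <- vapply(tmpl, function(m) as.vector(m) / sqrt(sum(m^2)),
               numeric(side * side))
  im <- images
  dim(im) <- c(side * side, n)
  crossprod(im, tm)
}
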