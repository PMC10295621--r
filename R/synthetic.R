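# Synthetic lesion-image generator and data handling.
#
# The generator emulates, at desk scale, the appearance statistics the
# network is designed for: bright or dark roughly-elliptical lesions with
# blurred boundaries on textured backgrounds, speckle-like additive noise,
# and optional dark curvilinear hair-like occluders crossing the field.
# The ground-truth mask is the exact pre-blur ellipse union, so boundary
# blur is a property of the image only, as in real dermoscopy.
#
# Samples are lists with `image` (3, H, W) in [0, 1], `mask` (1, H, W) in
# {0, 1}, and `meta` (the generator draw). Everything is a pure function of
# the configuration, including its seed.

#' Generator configuration
#'
#' @param n_samples number of image/mask pairs.
#' @param image_size `c(H, W)` output size.
#' @param lesion_area_range admissible mask foreground fraction `(lo, hi)`.
#' @param contrast_range magnitude range of the lesion intensity offset.
#' @param noise_sigma standard deviation of additive pixel noise.
#' @param hair_occluders maximum number of hair-like strokes per image.
#' @param blur_sigma Gaussian blur (pixels) applied to the lesion layer.
#' @param seed integer seed fixing the whole sample stream.
#' @return a list of class `gen_config`.
#' @export
gen_config <- function(n_samples = 64L, image_size = c(256L, 256L),
                       lesion_area_range = c(0.05, 0.30),
                       contrast_range = c(0.25, 0.55),
                       noise_sigma = 0.05, hair_occluders = 3L,
                       blur_sigma = 2, seed = 1L) {
  stopifnot(n_samples >= 1,
            length(image_size) == 2, all(image_size >= 32),
            lesion_area_range[1] > 0, lesion_area_range[2] < 1,
            lesion_area_range[1] < lesion_area_range[2],
            contrast_range[1] >= 0, noise_sigma >= 0, blur_sigma >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 image_size = as.integer(image_size),
                 lesion_area_range = lesion_area_range,
                 contrast_range = contrast_range,
                 noise_sigma = noise_sigma,
                 hair_occluders = as.integer(hair_occluders),
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "gen_config")
}

# low-frequency texture: coarse Gaussian grid bilinearly upscaled
texture_field <- function(h, w, coarse = 8L, amp = 0.08) {
  g <- matrix(rnorm(coarse * coarse), coarse, coarse)
  up <- EBImage::resize(EBImage::Image(g), w = w, h = h)
  amp * t(EBImage::imageData(up))               # (h, w), row-major
}

ellipse_union_mask <- function(h, w, ellipses) {
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- matrix(FALSE, h, w)
  for (e in ellipses) {
    dx <- xs - e$cx; dy <- ys - e$cy
    u <- (dx * cos(e$theta) + dy * sin(e$theta)) / e$a
    v <- (-dx * sin(e$theta) + dy * cos(e$theta)) / e$b
    m <- m | (u * u + v * v <= 1)
  }
  m
}

draw_lesion_mask <- function(h, w, area_range, max_tries = 60L) {
  for (try in seq_len(max_tries)) {
    target <- runif(1, area_range[1], area_range[2])
    n_ell <- sample.int(3L, 1L)
    r0 <- sqrt(target * h * w / pi / n_ell)
    cx0 <- runif(1, 0.3 * w, 0.7 * w)
    cy0 <- runif(1, 0.3 * h, 0.7 * h)
    ell <- list()
    for (k in seq_len(n_ell)) {
      ecc <- runif(1, 0.6, 1.4)
      ell[[k]] <- list(
        cx = cx0 + if (k == 1) 0 else runif(1, -r0, r0),
        cy = cy0 + if (k == 1) 0 else runif(1, -r0, r0),
        a = r0 * ecc * runif(1, 0.8, 1.2),
        b = r0 / ecc * runif(1, 0.8, 1.2),
        theta = runif(1, 0, pi))
    }
    m <- ellipse_union_mask(h, w, ell)
    frac <- mean(m)
    if (frac >= area_range[1] && frac <= area_range[2])
      return(list(mask = m, ellipses = ell, frac = frac))
  }
  stop("could not satisfy lesion_area_range after ", max_tries, " tries")
}

hair_stroke <- function(h, w) {
  # quadratic Bezier between two border-ish points with a random control
  p0 <- c(runif(1, 1, w), runif(1, 1, h))
  p2 <- c(runif(1, 1, w), runif(1, 1, h))
  p1 <- (p0 + p2) / 2 + c(runif(1, -w / 3, w / 3), runif(1, -h / 3, h / 3))
  t <- seq(0, 1, length.out = 4L * max(h, w))
  bx <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
  keep <- bx >= 1 & bx <= w & by >= 1 & by <= h
  cbind(round(by[keep]), round(bx[keep]))
}

gaussian_blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma)))
}

generate_one <- function(cfg) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  les <- draw_lesion_mask(h, w, cfg$lesion_area_range)
  base <- runif(3, 0.45, 0.75)                   # skin-like background tone
  offset <- runif(1, cfg$contrast_range[1], cfg$contrast_range[2]) *
    sample(c(-1, 1), 1)
  chan_mix <- runif(3, 0.7, 1)                   # lesion colour cast
  soft <- gaussian_blur_mat(les$mask * 1, cfg$blur_sigma)
  img <- array(0, dim = c(3L, h, w))
  for (c in 1:3) {
    layer <- base[c] + texture_field(h, w) + offset * chan_mix[c] * soft
    img[c, , ] <- layer
  }
  n_hair <- if (cfg$hair_occluders > 0) sample.int(cfg$hair_occluders + 1L,
                                                   1L) - 1L else 0L
  if (n_hair > 0) {
    for (k in seq_len(n_hair)) {
      px <- hair_stroke(h, w)
      dark <- runif(1, 0.3, 0.6)
      for (c in 1:3) {
        lay <- img[c, , ]
        lay[px] <- lay[px] - dark
        # 1-pixel thickening for visibility
        px2 <- px; px2[, 1] <- pmin(px2[, 1] + 1L, h)
        lay[px2] <- lay[px2] - dark * 0.6
        img[c, , ] <- lay
      }
    }
  }
  img <- img + array(rnorm(3 * h * w, sd = cfg$noise_sigma),
                     dim = c(3L, h, w))
  img <- pmin(pmax(img, 0), 1)
  list(image = img,
       mask = array(as.double(les$mask), dim = c(1L, h, w)),
       meta = list(area_frac = les$frac, offset = offset,
                   n_ellipses = length(les$ellipses), n_hair = n_hair))
}

#' Generate a synthetic segmentation dataset
#'
#' @param cfg a [gen_config()].
#' @return a list of samples, each with `image` (3, H, W), `mask`
#'   (1, H, W) and `meta`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_samples), function(i) generate_one(cfg))
}

# augmentation -----------------------------------------------------------------

to_ebi <- function(img_chw) {
  EBImage::Image(aperm(img_chw, c(3L, 2L, 1L)), colormode = "Color")
}
from_ebi <- function(im) {
  d <- EBImage::imageData(im)
  if (length(dim(d)) == 2L) dim(d) <- c(dim(d), 1L)
  aperm(d, c(3L, 2L, 1L))
}

# affine matrix mapping input pixel coords to output pixel coords:
# rotate by `angle` (deg) and scale by `zoom` about the image centre, then
# translate by (dx, dy)
centre_affine <- function(h, w, angle, zoom, dx = 0, dy = 0) {
  th <- angle * pi / 180
  r <- zoom * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  # EBImage maps row-vector pixel coordinates forward: p_out = p %*% m[1:2,] + m[3,]
  shift <- c(cx + dx, cy + dy) - as.numeric(c(cx, cy) %*% r)
  rbind(r, shift)
}

apply_affine <- function(img_chw, m, h, w, nearest = FALSE) {
  im <- to_ebi(img_chw)
  out <- EBImage::affine(im, m, filter = if (nearest) "none" else
    "bilinear", output.dim = c(w, h), bg.col = 0)
  from_ebi(out)
}

#' Augment one sample
#'
#' Seeded random rotation (within ±30 degrees), scale zoom (0.8–1.2),
#' random crop-and-resize, and photometric brightness/contrast jitter
#' (image only). The identical geometric transform is applied to image and
#' mask; the mask is resampled nearest-neighbour and re-binarised.
#'
#' @param s a sample (`image`, `mask`).
#' @param seed integer seed for the parameter draw.
#' @param params optional explicit parameter list (`angle`, `zoom`,
#'   `crop_frac`, `crop_cx`, `crop_cy`, `brightness`, `contrast`)
#'   overriding the draw; neutral values give the identity.
#' @return the augmented sample.
#' @export
augment <- function(s, seed = NULL, params = NULL) {
  if (is.null(params)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    params <- list(angle = runif(1, -30, 30), zoom = runif(1, 0.8, 1.2),
                   crop_frac = runif(1, 0.85, 1),
                   crop_cx = runif(1, -0.5, 0.5),
                   crop_cy = runif(1, -0.5, 0.5),
                   brightness = runif(1, -0.2, 0.2),
                   contrast = runif(1, 0.8, 1.2))
  }
  d <- dim(s$image)
  h <- d[2]; w <- d[3]
  # crop window of side crop_frac, recentred, resampled back to (h, w):
  # equivalent to zooming by 1/crop_frac about a shifted centre
  eff_zoom <- params$zoom / params$crop_frac
  max_dx <- (1 - params$crop_frac) * w / 2
  max_dy <- (1 - params$crop_frac) * h / 2
  m <- centre_affine(h, w, params$angle, eff_zoom,
                     dx = params$crop_cx * 2 * max_dx,
                     dy = params$crop_cy * 2 * max_dy)
  img <- apply_affine(s$image, m, h, w)
  msk <- apply_affine(s$mask, m, h, w, nearest = TRUE)
  img <- img * params$contrast + params$brightness
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = array(as.double(msk >= 0.5), dim = dim(s$mask)),
       meta = c(s$meta, list(augment = params)))
}

# folder I/O -------------------------------------------------------------------

#' Save samples as PNG folders
#'
#' Writes `<path>/images/<stem>.png` (8-bit RGB) and
#' `<path>/masks/<stem>.png` (8-bit grayscale, values 0/255). Images are
#' quantised to 8 bits, so a save/load round trip is exact.
#'
#' @param samples list of samples.
#' @param path output folder.
#' @return invisibly, the vector of stems written.
#' @export
save_folder <- function(samples, path) {
  dir.create(file.path(path, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(path, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  stems <- sprintf("sample_%04d", seq_along(samples))
  for (i in seq_along(samples)) {
    img <- round(samples[[i]]$image * 255) / 255
    EBImage::writeImage(to_ebi(img),
                        file.path(path, "images", paste0(stems[i], ".png")))
    msk <- t(samples[[i]]$mask[1, , ])
    EBImage::writeImage(EBImage::Image(msk),
                        file.path(path, "masks", paste0(stems[i], ".png")))
  }
  invisible(stems)
}

#' Load an image/mask folder
#'
#' Expects `<path>/images/*.png` with matching stems under
#' `<path>/masks/`. Images are resized bilinearly to `size` x `size`,
#' masks nearest-neighbour and re-binarised at half intensity.
#'
#' @param path folder with `images/` and `masks/` subfolders.
#' @param size target square size (default 256).
#' @return a list of samples.
#' @export
load_folder <- function(path, size = 256L) {
  imgs <- sort(list.files(file.path(path, "images"), pattern = "\\.png$",
                          full.names = TRUE))
  if (!length(imgs)) stop("no PNG images under ", file.path(path, "images"))
  lapply(imgs, function(f) {
    stem <- sub("\\.png$", "", basename(f))
    mf <- file.path(path, "masks", paste0(stem, ".png"))
    if (!file.exists(mf))
      stop("missing mask for image stem '", stem, "'")
    im <- EBImage::readImage(f)
    if (length(dim(im)) == 2L)
      im <- EBImage::Image(array(rep(EBImage::imageData(im), 3L),
                                 dim = c(dim(im), 3L)), colormode = "Color")
    if (!identical(dim(im)[1:2], as.integer(c(size, size))))
      im <- EBImage::resize(im, w = size, h = size)
    mk <- EBImage::readImage(mf)
    if (length(dim(mk)) == 3L) mk <- mk[, , 1]
    if (!identical(dim(mk)[1:2], as.integer(c(size, size))))
      mk <- EBImage::resize(mk, w = size, h = size, filter = "none")
    img <- from_ebi(im)[1:3, , , drop = FALSE]
    mask <- array(as.double(t(EBImage::imageData(mk)) >= 0.5),
                  dim = c(1L, size, size))
    list(image = img, mask = mask, meta = list(source = stem))
  })
}

#' Train/test split
#'
#' Seed-reproducible disjoint, exhaustive shuffle split.
#'
#' @param samples list of samples (at least 5).
#' @param train_frac fraction assigned to training.
#' @param seed integer seed.
#' @return list with `train` and `test` sample lists.
#' @export
split_samples <- function(samples, train_frac = 0.8, seed = 1L) {
  n <- length(samples)
  if (n < 5L) stop("need at least 5 samples to split")
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  k <- round(train_frac * n)
  list(train = samples[idx[seq_len(k)]],
       test = samples[idx[seq.int(k + 1L, n)]])
}
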