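# Image-level augmentation operators. Images are integer arrays
# height x width x 3 with intensities 0-255 (class "spectrogram_image").

check_image <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3 || d[3] != 3) {
    config_error("image must be a height x width x 3 array.")
  }
  if (min(img) < 0 || max(img) > 255) {
    config_error("image intensities must be in [0, 255].")
  }
  invisible(img)
}

as_image <- function(x, template = NULL) {
  out <- array(as.integer(round(pmin(255, pmax(0, x)))), dim(x))
  attr(out, "colormap") <- attr(template %||% x, "colormap")
  class(out) <- "spectrogram_image"
  out
}

#' Horizontal and vertical image flips
#'
#' `hflip()` mirrors the time axis: the pixel at 0-based column `x` moves to
#' column `width - x - 1`; the frequency axis is untouched. `vflip()`
#' mirrors the frequency axis: row `y` moves to `height - y - 1`. Both are
#' involutions and preserve shape, intensities and label semantics.
#'
#' @param img a `spectrogram_image` (or any H x W x 3 array in 0-255).
#' @return the flipped image.
#' @export
hflip <- function(img) {
  check_image(img)
  as_image(img[, rev(seq_len(dim(img)[2])), , drop = FALSE], img)
}

#' @rdname hflip
#' @export
vflip <- function(img) {
  check_image(img)
  as_image(img[rev(seq_len(dim(img)[1])), , , drop = FALSE], img)
}

#' RGB to HSV conversion
#'
#' The piecewise conversion used by the colour-space augmentations:
#' channels are scaled to \eqn{R' = R/255} etc., \eqn{C_{max}}, \eqn{C_{min}}
#' and \eqn{\Delta = C_{max} - C_{min}} computed, hue assigned by the
#' \eqn{C_{max}} case split (in degrees, \eqn{[0, 360)}), saturation as
#' \eqn{\Delta / C_{max}} (0 when \eqn{C_{max} = 0}) and value as
#' \eqn{C_{max}}. \eqn{\Delta = 0} gives hue 0 by convention.
#'
#' @param r,g,b numeric vectors of equal length with values in 0-255.
#' @return a data frame with columns `h` (degrees), `s`, `v` (fractions).
#' @examples
#' rgb_to_hsv_pixel(255, 0, 0)  # h = 0, s = 1, v = 1
#' @export
rgb_to_hsv_pixel <- function(r, g, b) {
  rp <- r / 255; gp <- g / 255; bp <- b / 255
  cmax <- pmax(rp, gp, bp)
  cmin <- pmin(rp, gp, bp)
  delta <- cmax - cmin
  h <- numeric(length(rp))
  nz <- delta > 0
  is_r <- nz & cmax == rp
  is_g <- nz & !is_r & cmax == gp
  is_b <- nz & !is_r & !is_g
  h[is_r] <- 60 * (((gp[is_r] - bp[is_r]) / delta[is_r]) %% 6)
  h[is_g] <- 60 * ((bp[is_g] - rp[is_g]) / delta[is_g] + 2)
  h[is_b] <- 60 * ((rp[is_b] - gp[is_b]) / delta[is_b] + 4)
  s <- ifelse(cmax == 0, 0, delta / cmax)
  data.frame(h = h, s = s, v = cmax)
}

# Luma grayscale of an image (0-255 double matrix), BT.601 weights.
image_gray <- function(x) {
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

#' Saturation/value perturbation
#'
#' Two sequential blends with the formula
#' `Blending_Image * (1 - alpha) + Original_Image * alpha`: first a
#' brightness pass blending with an all-black image (weight
#' `alpha_brightness`), then a saturation pass blending the result with its
#' own grayscale (weight `alpha_saturation`). With both alphas 1 the image
#' is returned bit-exact. Channels are clipped to \eqn{[0, 255]}.
#'
#' @param img a `spectrogram_image`.
#' @param alpha_brightness blend weight, sampled from \eqn{U(0.5, 2)}.
#' @param alpha_saturation blend weight, sampled from \eqn{U(0.1, 2)}.
#' @return the perturbed image.
#' @export
sv_perturb <- function(img, alpha_brightness, alpha_saturation) {
  check_image(img)
  x <- array(as.numeric(img), dim(img))
  bright <- x * alpha_brightness  # black * (1 - a) + x * a
  g <- image_gray(bright)
  out <- array(0, dim(x))
  for (ch in 1:3) {
    out[, , ch] <- g * (1 - alpha_saturation) + bright[, , ch] * alpha_saturation
  }
  if (alpha_brightness == 1 && alpha_saturation == 1) return(as_image(x, img))
  as_image(out, img)
}

#' @rdname sv_perturb
#' @param seed integer seed.
#' @return `sample_sv_params()`: a list with `alpha_brightness` and
#'   `alpha_saturation`.
#' @export
sample_sv_params <- function(seed = 1L) {
  with_seed(seed, list(
    alpha_brightness = runif(1, 0.5, 2),
    alpha_saturation = runif(1, 0.1, 2)
  ))
}

# Fix eigenvector signs so the operation is well defined: the component of
# largest magnitude in each eigenvector is made positive.
fix_eigen_signs <- function(vectors) {
  for (j in seq_len(ncol(vectors))) {
    k <- which.max(abs(vectors[, j]))
    if (vectors[k, j] < 0) vectors[, j] <- -vectors[, j]
  }
  vectors
}

#' PCA colour augmentation
#'
#' Eigen-decomposes the 3 x 3 covariance of the image's RGB channels
#' (computed over pixels, on the raw 0-255 scale), scales the eigenvalues by
#' a single per-image factor `alpha` drawn from \eqn{N(800, 10^2)}, and adds
#' the resulting shift `V (alpha * lambda)` to every pixel's RGB vector,
#' clipping to \eqn{[0, 255]}. A constant-colour image has zero covariance
#' and is a fixed point for any `alpha`; `alpha = 0` is the identity.
#'
#' @param img a `spectrogram_image`.
#' @param alpha eigenvalue scale factor for this image.
#' @param stats optional pre-computed covariance matrix (3 x 3), e.g. pooled
#'   over a whole training set; default uses the image's own pixels.
#' @return the augmented image.
#' @export
pca_color_augment <- function(img, alpha, stats = NULL) {
  check_image(img)
  x <- array(as.numeric(img), dim(img))
  px <- cbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
  cv <- stats %||% stats::cov(px)
  e <- eigen(cv, symmetric = TRUE)
  vec <- fix_eigen_signs(e$vectors)
  shift <- as.numeric(vec %*% (alpha * pmax(e$values, 0)))
  if (all(shift == 0)) return(as_image(x, img))
  for (ch in 1:3) x[, , ch] <- x[, , ch] + shift[ch]
  as_image(x, img)
}

#' @rdname pca_color_augment
#' @param seed integer seed.
#' @param mu,sigma parameters of the normal draw (defaults 800 and 10).
#' @return `sample_pca_alpha()`: one draw from \eqn{N(\mu, \sigma^2)}.
#' @export
sample_pca_alpha <- function(seed = 1L, mu = 800, sigma = 10) {
  with_seed(seed, rnorm(1, mu, sigma))
}

#' Pooled RGB covariance over a set of images
#'
#' Dataset-wide alternative to the per-image covariance of
#' [pca_color_augment()].
#'
#' @param imgs list of `spectrogram_image`s.
#' @return a 3 x 3 covariance matrix.
#' @export
pca_color_stats <- function(imgs) {
  px <- do.call(rbind, lapply(imgs, function(im) {
    x <- array(as.numeric(im), dim(im))
    cbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
  }))
  stats::cov(px)
}

#' Time and frequency masking of a Mel-spectrogram
#'
#' Applies three frequency masks (row bands `[f0, f0 + f)`) and three time
#' masks (column bands `[t0, t0 + t)`) with widths drawn as integers from
#' the uniform distribution on \eqn{[0, 20]}, starts within the matrix, and
#' independent locations (masks may overlap). Masked cells are set to
#' `fill` - by default 0 dB, the colormap maximum, so masks render as bright
#' bars over the image.
#'
#' @param mel a `mel_spectrogram` with more than 20 rows and columns.
#' @param seed integer seed.
#' @param n_freq_masks,n_time_masks mask counts (defaults 3 and 3).
#' @param max_width maximum mask width (default 20).
#' @param fill dB value written into masked cells (default 0).
#' @return the masked `mel_spectrogram`.
#' @export
time_frequency_mask <- function(mel, seed = 1L, n_freq_masks = 3L,
                                n_time_masks = 3L, max_width = 20L, fill = 0) {
  masks <- sample_mask_params(nrow(mel), ncol(mel), seed,
                              n_freq_masks, n_time_masks, max_width)
  apply_masks(mel, masks, fill)
}

#' @rdname time_frequency_mask
#' @param v,tau matrix dimensions (frequency channels, time steps).
#' @return `sample_mask_params()`: a tibble with columns `domain`
#'   (`"frequency"`/`"time"`), `width` and `start` (0-based).
#' @export
sample_mask_params <- function(v, tau, seed = 1L, n_freq_masks = 3L,
                               n_time_masks = 3L, max_width = 20L) {
  if (v <= max_width || tau <= max_width) {
    degenerate_error("matrix too small for the configured mask bounds.")
  }
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_freq_masks)) {
      f <- sample(0:max_width, 1)
      # f0 drawn from the open interval (0, v - f)
      f0 <- if (v - f - 1 >= 1) sample(seq_len(v - f - 1), 1) else 1L
      rows[[length(rows) + 1L]] <- tibble(domain = "frequency", width = f, start = f0)
    }
    for (i in seq_len(n_time_masks)) {
      t <- sample(0:max_width, 1)
      # t0 drawn from the closed interval [0, tau - t]
      t0 <- sample(0:(tau - t), 1)
      rows[[length(rows) + 1L]] <- tibble(domain = "time", width = t, start = t0)
    }
    bind_rows(rows)
  })
}

#' @rdname time_frequency_mask
#' @param masks a tibble as returned by `sample_mask_params()`.
#' @export
apply_masks <- function(mel, masks, fill = 0) {
  out <- mel
  for (i in seq_len(nrow(masks))) {
    w <- masks$width[i]
    if (w == 0) next
    idx <- masks$start[i] + seq_len(w)  # 0-based [start, start + w)
    if (masks$domain[i] == "frequency") {
      idx <- idx[idx <= nrow(out)]
      out[idx, ] <- fill
    } else {
      idx <- idx[idx <= ncol(out)]
      out[, idx] <- fill
    }
  }
  out
}

#' Compose two image-level augmentation methods
#'
#' Applies `first` then `then`, in that order. The composed arms of the
#' study are PCA-then-horizontal-flip and SV-then-horizontal-flip.
#'
#' @param img a `spectrogram_image`.
#' @param first,then method names among `"hflip"`, `"vflip"`, `"sv"`,
#'   `"pca"`, `"color_filter"`.
#' @param seed integer seed used for whichever methods need sampling.
#' @return the augmented image.
#' @export
compose_method <- function(img, first, then, seed = 1L) {
  image_methods <- c("hflip", "vflip", "sv", "pca", "color_filter")
  if (!first %in% image_methods || !then %in% image_methods) {
    config_error("composition requires two image-level methods.")
  }
  apply_image_method(apply_image_method(img, first, derive_seed(seed, 1)),
                     then, derive_seed(seed, 2))
}

# Dispatch a single image-level method with its sampled parameters.
apply_image_method <- function(img, method, seed) {
  switch(method,
    hflip = hflip(img),
    vflip = vflip(img),
    sv = {
      pars <- sample_sv_params(seed)
      sv_perturb(img, pars$alpha_brightness, pars$alpha_saturation)
    },
    pca = pca_color_augment(img, sample_pca_alpha(seed)),
    color_filter = random_color_filter(img, seed),
    config_error(paste0("unknown image method: ", method))
  )
}
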