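# Random colour filters: a registry of 150 distinct 3-channel colour-space
# conversion mappings. Each entry converts RGB into another colour space
# (with formula-based conversions on the 0-255 scale), optionally chains a
# second conversion, permutes the output channels, and optionally inverts
# intensities; the result is reinterpreted as RGB. All entries keep the
# image shape; entry 1 is the identity.

# ---- colour-space forward transforms: H x W x 3 doubles in, 0-255-scale out

space_rgb <- function(x) x

space_hsv <- function(x) {
  hsv <- rgb_to_hsv_pixel(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
  d <- dim(x)
  array(c(hsv$h * 255 / 360, hsv$s * 255, hsv$v * 255), d)
}

space_hls <- function(x) {
  r <- as.vector(x[, , 1]) / 255; g <- as.vector(x[, , 2]) / 255; b <- as.vector(x[, , 3]) / 255
  cmax <- pmax(r, g, b); cmin <- pmin(r, g, b); delta <- cmax - cmin
  l <- (cmax + cmin) / 2
  s <- ifelse(delta == 0, 0, delta / (1 - abs(2 * l - 1)))
  hsv <- rgb_to_hsv_pixel(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
  array(c(hsv$h * 255 / 360, l * 255, s * 255), dim(x))
}

space_yuv <- function(x) {
  r <- x[, , 1]; g <- x[, , 2]; b <- x[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  array(c(y, 0.492 * (b - y) + 128, 0.877 * (r - y) + 128), dim(x))
}

space_ycrcb <- function(x) {
  r <- x[, , 1]; g <- x[, , 2]; b <- x[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  array(c(y, 0.713 * (r - y) + 128, 0.564 * (b - y) + 128), dim(x))
}

xyz_of <- function(x) {
  m <- rbind(
    c(0.412453, 0.357580, 0.180423),
    c(0.212671, 0.715160, 0.072169),
    c(0.019334, 0.119193, 0.950227)
  )
  px <- rbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3])) / 255
  m %*% px
}

space_xyz <- function(x) {
  array(t(xyz_of(x)) * 255, dim(x))
}

lab_f <- function(t) {
  d <- (6 / 29)^3
  ifelse(t > d, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

space_lab <- function(x) {
  p <- xyz_of(x)
  fx <- lab_f(p[1, ] / 0.950456); fy <- lab_f(p[2, ]); fz <- lab_f(p[3, ] / 1.088754)
  l <- 116 * fy - 16
  array(c(l * 255 / 100, 500 * (fx - fy) + 128, 200 * (fy - fz) + 128), dim(x))
}

space_luv <- function(x) {
  p <- xyz_of(x)
  denom <- p[1, ] + 15 * p[2, ] + 3 * p[3, ]
  up <- ifelse(denom == 0, 0, 4 * p[1, ] / denom)
  vp <- ifelse(denom == 0, 0, 9 * p[2, ] / denom)
  l <- 116 * lab_f(p[2, ]) - 16
  u <- 13 * l * (up - 0.19793943)
  v <- 13 * l * (vp - 0.46831096)
  array(c(l * 255 / 100, (u + 134) * 255 / 354, (v + 140) * 255 / 262), dim(x))
}

space_yiq <- function(x) {
  r <- x[, , 1]; g <- x[, , 2]; b <- x[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  i <- 0.596 * r - 0.274 * g - 0.322 * b
  q <- 0.211 * r - 0.523 * g + 0.312 * b
  array(c(y, (i + 151.98) * 255 / 303.96, (q + 133.365) * 255 / 266.73), dim(x))
}

space_funs <- function() {
  list(
    rgb = space_rgb, hsv = space_hsv, hls = space_hls, yuv = space_yuv,
    ycrcb = space_ycrcb, xyz = space_xyz, lab = space_lab, luv = space_luv,
    yiq = space_yiq
  )
}

#' The colour-filter registry
#'
#' Enumerates the 150 colour-space conversion mappings used by the random
#' colour filter augmentation: 9 colour spaces (RGB, HSV, HLS, YUV, YCrCb,
#' XYZ, LAB, LUV, YIQ) crossed with the 6 channel permutations, each in a
#' normal and an intensity-inverted polarity (108 entries), plus 42 chained
#' two-space conversions. Entry 1 is the identity mapping.
#'
#' @return a tibble with columns `filter_id`, `space`, `space2`, `perm`
#'   (output channel order) and `inverted`.
#' @export
color_filter_registry <- function() {
  spaces <- names(space_funs())
  perms <- c("123", "132", "213", "231", "312", "321")
  base <- tidyr::expand_grid(space = spaces, perm = perms)
  part_a <- mutate(base, space2 = NA_character_, inverted = FALSE)
  part_b <- mutate(base, space2 = NA_character_, inverted = TRUE)
  others <- setdiff(spaces, "rgb")
  pairs <- tidyr::expand_grid(space = others, space2 = others) %>%
    filter(.data$space != .data$space2) %>%
    head(42) %>%
    mutate(perm = "123", inverted = FALSE)
  reg <- bind_rows(part_a, part_b, pairs) %>%
    mutate(filter_id = dplyr::row_number()) %>%
    select("filter_id", "space", "space2", "perm", "inverted")
  if (nrow(reg) != 150) {
    config_error("colour-filter registry must contain exactly 150 conversions.")
  }
  reg
}

#' Apply one registry colour filter
#'
#' @param img a `spectrogram_image`.
#' @param filter_id registry row (1-150).
#' @return the converted image, reinterpreted as RGB (same shape, 0-255).
#' @export
apply_color_filter <- function(img, filter_id) {
  check_image(img)
  reg <- color_filter_registry()
  if (!filter_id %in% reg$filter_id) {
    config_error(paste0("no such colour filter: ", filter_id))
  }
  row <- reg[reg$filter_id == filter_id, ]
  funs <- space_funs()
  x <- array(as.numeric(img), dim(img))
  x <- funs[[row$space]](x)
  if (!is.na(row$space2)) {
    x <- array(pmin(255, pmax(0, x)), dim(x))
    x <- funs[[row$space2]](x)
  }
  ord <- as.integer(strsplit(row$perm, "")[[1]])
  x <- x[, , ord, drop = FALSE]
  if (row$inverted) x <- 255 - x
  out <- as_image(x, img)
  attr(out, "filter_id") <- filter_id
  out
}

#' Random colour filter augmentation
#'
#' Selects one of the 150 registry conversions uniformly at random and
#' applies it.
#'
#' @param img a `spectrogram_image`.
#' @param seed integer seed (a fixed seed selects the same conversion).
#' @return the converted image, with the chosen `filter_id` as an attribute.
#' @export
random_color_filter <- function(img, seed = 1L) {
  id <- with_seed(seed, sample.int(150L, 1L))
  apply_color_filter(img, id)
}
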