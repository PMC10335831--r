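# Internal numeric and geometry helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going up (`0.5 -> 1`), the
#' convention used for all reported percentages (e.g. `70.69 -> 71`,
#' `4.17 -> 4`), as opposed to the banker's rounding of [base::round()].
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @examples
#' round_half_up(c(70.69, 75.68, 4.17, 0.5))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mtk <- function(msg, class) {
  stop(structure(
    class = c(class, "mtk_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_mtk(sprintf("'%s' must be a single probability in [0, 1]", name),
             "mtk_config_error")
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop_mtk(sprintf("'%s' must be a finite %s number", name,
                     if (strict) "positive" else "non-negative"),
             "mtk_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == floor(x) && x >= min
  if (!ok) {
    stop_mtk(sprintf("'%s' must be an integer >= %d", name, min),
             "mtk_config_error")
  }
  invisible(as.integer(x))
}

#' @noRd
#' Bilinear interpolation of image values at fractional pixel positions.
#' `img` is indexed [row (y), col (x)]; x/y are 1-based pixel coordinates.
#' Positions outside the image are clamped to the border.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img)
  w <- ncol(img)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L)
  y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0
  fy <- y - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1L)]
  i10 <- img[cbind(y0 + 1L, x0)]
  i11 <- img[cbind(y0 + 1L, x0 + 1L)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

#' @noRd
#' Resample a polyline (n x 2 matrix, columns x,y in px) at equal arc-length
#' steps. Returns positions, unit tangents and unit normals at each sample.
resample_polyline <- function(poly, step = 1) {
  poly <- unname(as.matrix(poly))
  if (nrow(poly) < 2L) stop_mtk("polyline needs at least 2 points",
                                "mtk_config_error")
  seg <- diff(poly)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  if (!any(keep)) stop_mtk("polyline has zero length", "mtk_config_error")
  poly <- poly[c(TRUE, keep), , drop = FALSE]
  seg <- diff(poly)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  x <- stats::approx(cum, poly[, 1], xout = s)$y
  y <- stats::approx(cum, poly[, 2], xout = s)$y
  # tangent of the segment each sample falls in
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
              nrow(seg))
  tx <- seg[idx, 1] / len[idx]
  ty <- seg[idx, 2] / len[idx]
  list(x = x, y = y, s = s, total = total,
       tangent = cbind(tx, ty), normal = cbind(-ty, tx))
}

#' @noRd
#' Mean image intensity in a band around each arc-length sample of a
#' polyline: `width` evenly spaced normal offsets, bilinearly interpolated.
band_profile <- function(img, poly, width = 1, step = 1) {
  rp <- resample_polyline(poly, step = step)
  width <- max(1L, as.integer(round(width)))
  offs <- if (width == 1L) 0 else seq(-(width - 1) / 2, (width - 1) / 2,
                                      length.out = width)
  acc <- numeric(length(rp$s))
  for (o in offs) {
    acc <- acc + bilinear_sample(img, rp$x + o * rp$normal[, 1],
                                 rp$y + o * rp$normal[, 2])
  }
  list(s = rp$s, intensity = acc / length(offs), geometry = rp)
}

#' @noRd
#' Summed-area table with a zero first row/column so that the sum of
#' img[y0..y0+h-1, x0..x0+w-1] is
#' ii[y0+h, x0+w] - ii[y0, x0+w] - ii[y0+h, x0] + ii[y0, x0].
integral_image <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  ii <- matrix(0, h + 1L, w + 1L)
  ii[-1L, -1L] <- t(apply(apply(img, 2L, cumsum), 1L, cumsum))
  ii
}

#' @noRd
#' Box sums of size p x p at all top-left positions (ys, xs) (vectors),
#' returned as a length(ys) x length(xs) matrix.
patch_sums <- function(ii, ys, xs, p) {
  ii[ys + p, xs + p, drop = FALSE] - ii[ys, xs + p, drop = FALSE] -
    ii[ys + p, xs, drop = FALSE] + ii[ys, xs, drop = FALSE]
}

#' @noRd
#' Draws n integer sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
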