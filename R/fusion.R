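#' Per-pair depth map from an alpha map
#'
#' Element-wise application of [invert_alpha()] to an [alpha_map()];
#' unmatched pixels (`NA`) propagate.
#'
#' @param amap an [alpha_map()].
#' @param curve a [build_depth_curve()] result covering the alpha range.
#' @return numeric matrix of depths `z` (mm), NA where unmatched.
#' @export
pair_depth <- function(amap, curve) {
  stopifnot(inherits(amap, "alpha_map"), inherits(curve, "depth_curve"))
  z <- invert_alpha(curve, as.numeric(amap$alpha))
  matrix(z, nrow(amap$alpha))
}

# direction label of an (axis-aligned or diagonal) deltaD vector
deltaD_direction <- function(deltaD_vec) {
  hat <- deltaD_vec / sqrt(sum(deltaD_vec^2))
  if (abs(hat[2]) < 1e-6) return("x")
  if (abs(hat[1]) < 1e-6) return("y")
  if (abs(hat[1] - hat[2]) < 1e-6) return("+45")
  if (abs(hat[1] + hat[2]) < 1e-6) return("-45")
  stop("deltaD_vec must be axis-aligned or diagonal for weight computation")
}

#' Fusion weight of one detector pair at one pixel
#'
#' The weight of pair `i` in the fused depth average is the mean, over the
#' two detector images, of the absolute directional second derivative of
#' the normalized inverse intensity along the pair's offset direction: at
#' the pixel itself in the `D_plus` image and at the matched (alpha-shifted)
#' location in the `D_minus` image. Pairs whose offset runs along a
#' directional structure thus get low weight.
#'
#' @param deriv_plus,deriv_minus matrices from
#'   [directional_second_derivative()] along the pair's offset direction,
#'   for the `D_plus` and `D_minus` images.
#' @param pixel integer `c(row, col)` in the `D_plus` image.
#' @param alpha matched offset parameter for the pixel (`NA` gives `NA`).
#' @param deltaD_vec length-2 detector offset vector (mm).
#' @param pitch pixel pitch (mm).
#' @return nonnegative weight (second-derivative magnitude units).
#' @export
pair_weight <- function(deriv_plus, deriv_minus, pixel, alpha, deltaD_vec,
                        pitch) {
  if (is.na(alpha)) return(NA_real_)
  dD <- sqrt(sum(deltaD_vec^2))
  hat <- deltaD_vec / dD
  k <- alpha * dD / pitch
  sh <- beta_pixel_shift(k, hat)
  p2 <- pixel + sh
  w1 <- abs(deriv_plus[pixel[1], pixel[2]])
  w2 <- if (p2[1] >= 1L && p2[1] <= nrow(deriv_minus) &&
            p2[2] >= 1L && p2[2] <= ncol(deriv_minus))
    abs(deriv_minus[p2[1], p2[2]]) else w1
  (w1 + w2) / 2
}

#' Weighted fusion of per-pair depth estimates
#'
#' Combines the depths measured by `n` detector pairs at one pixel into
#' `z = sum(w_i z_i) / sum(w_i)` over the pairs with a defined depth. If
#' every available weight is zero the unweighted mean is returned and the
#' result is flagged; if no pair has a depth the result is `NA`.
#'
#' @param z_list per-pair depths (mm), NA for unmatched pairs.
#' @param w_list per-pair nonnegative weights.
#' @return scalar fused depth (mm) with attribute `unweighted = TRUE` when
#'   the zero-weight fallback was taken; `NA` if no depth is defined.
#' @export
fuse_depths <- function(z_list, w_list) {
  z <- as.numeric(z_list); w <- as.numeric(w_list)
  stopifnot(length(z) == length(w))
  ok <- !is.na(z)
  if (!any(ok)) return(NA_real_)
  z <- z[ok]; w <- w[ok]
  w[is.na(w)] <- 0
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) == 0)
    return(structure(mean(z), unweighted = TRUE))
  sum(w * z) / sum(w)
}

#' Fuse the depth estimates of several detector pairs into a depth map
#'
#' Runs [pair_depth()] and [pair_weight()] for every matched pixel of each
#' pair and combines them with [fuse_depths()]. A pixel matched by only
#' some pairs uses those pairs alone. Per-pixel uncertainty intervals are
#' attached from a one-pixel alpha uncertainty through the depth curve
#' (the union of the per-pair intervals).
#'
#' @param pairs list of per-pair lists, each with elements `amap` (an
#'   [alpha_map()]), `deriv_plus` and `deriv_minus` (directional second
#'   derivatives along the pair's offset; see [pair_weight()]).
#' @param curve a [build_depth_curve()] result.
#' @return object of class `depth_map`: `z` (fused, mm), per-pair `z_pairs`
#'   and `w_pairs`, `z_lo`/`z_hi` uncertainty matrices, `unweighted` flag
#'   matrix, `d0` and pixel metadata.
#' @export
fuse_pairs <- function(pairs, curve) {
  stopifnot(length(pairs) >= 1L, inherits(curve, "depth_curve"))
  dims <- dim(pairs[[1]]$amap$alpha)
  pitch <- pairs[[1]]$amap$pitch
  z_pairs <- lapply(pairs, function(p) pair_depth(p$amap, curve))
  w_pairs <- lapply(pairs, function(p) {
    a <- p$amap
    w <- matrix(NA_real_, dims[1], dims[2])
    idx <- which(!is.na(a$alpha), arr.ind = TRUE)
    for (i in seq_len(nrow(idx)))
      w[idx[i, 1], idx[i, 2]] <- pair_weight(
        p$deriv_plus, p$deriv_minus, idx[i, ],
        a$alpha[idx[i, 1], idx[i, 2]], a$deltaD_vec, pitch)
    w
  })
  z <- matrix(NA_real_, dims[1], dims[2])
  unweighted <- matrix(FALSE, dims[1], dims[2])
  any_def <- Reduce(`|`, lapply(z_pairs, function(m) !is.na(m)))
  idx <- which(any_def, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; cc <- idx[i, 2]
    zi <- vapply(z_pairs, function(m) m[r, cc], numeric(1))
    wi <- vapply(w_pairs, function(m) m[r, cc], numeric(1))
    f <- fuse_depths(zi, wi)
    z[r, cc] <- f
    if (isTRUE(attr(f, "unweighted"))) unweighted[r, cc] <- TRUE
  }
  z_lo <- matrix(NA_real_, dims[1], dims[2])
  z_hi <- matrix(NA_real_, dims[1], dims[2])
  for (p in pairs) {
    a <- p$amap$alpha
    ok <- !is.na(a)
    if (!any(ok)) next
    iv <- alpha_uncertainty_to_depth(curve, a[ok], pitch,
                                     sqrt(sum(p$amap$deltaD_vec^2)))
    iv <- matrix(iv, ncol = 2)
    z_lo[ok] <- pmin(z_lo[ok], iv[, 1], na.rm = TRUE)
    z_hi[ok] <- pmax(z_hi[ok], iv[, 2], na.rm = TRUE)
  }
  structure(
    list(z = z, z_pairs = z_pairs, w_pairs = w_pairs,
         z_lo = z_lo, z_hi = z_hi, unweighted = unweighted,
         d0 = curve$d0, pitch = pitch, origin = pairs[[1]]$amap$origin),
    class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  n <- sum(!is.na(x$z))
  cat(sprintf("<depth_map> %d x %d px, %d with depth (d0 = %g mm)\n",
              nrow(x$z), ncol(x$z), n, x$d0))
  if (n > 0)
    cat(sprintf("  depth range %.1f - %.1f mm, median %.1f mm\n",
                min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE),
                median(x$z, na.rm = TRUE)))
  invisible(x)
}

#' Variable-bin depth histogram
#'
#' One bin per attainable alpha quantum (`floor(deltaD/pitch) + 1` bins),
#' with bin edges in z placed at the depth-curve images of the midpoints
#' between adjacent alpha values. Because the depth curve is nonlinear the
#' bins have variable width; the ordinate is therefore the pixel density
#' (pixels per unit depth), so that `sum(count) = sum(density * width)`
#' equals the number of matched pixels.
#'
#' @param depth_map a [fuse_pairs()] result (or a numeric vector/matrix of
#'   depths in mm).
#' @param curve the [build_depth_curve()] used for the inversion.
#' @param pitch pixel pitch of the matching (mm).
#' @param deltaD detector separation (mm).
#' @return object of class `depth_histogram`: data frame with `alpha`,
#'   `z_center`, `z_lo`, `z_hi`, `count`, `density` (1/mm).
#' @export
depth_histogram <- function(depth_map, curve, pitch, deltaD) {
  z <- if (inherits(depth_map, "depth_map")) depth_map$z else depth_map
  z <- as.numeric(z)
  z <- z[!is.na(z)]
  q <- pitch / deltaD
  ks <- 0:floor(deltaD / pitch)
  a <- ks * q
  centers <- invert_alpha(curve, pmin(a, 1))
  edges <- c(invert_alpha(curve, max(0, a[1] - q / 2)),
             invert_alpha(curve, pmin(1, a[-length(a)] + q / 2)),
             invert_alpha(curve, min(1, a[length(a)] + q / 2)))
  z <- pmin(pmax(z, edges[1]), edges[length(edges)])
  cnt <- graphics::hist(z, breaks = edges, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)$counts
  width <- diff(edges)
  structure(
    list(bins = data.frame(alpha = a, z_center = centers,
                           z_lo = edges[-length(edges)], z_hi = edges[-1],
                           count = cnt,
                           density = ifelse(width > 0, cnt / width, 0)),
         n = length(z), d0 = curve$d0),
    class = "depth_histogram")
}

#' @export
print.depth_histogram <- function(x, ...) {
  cat(sprintf("<depth_histogram> %d bins, %d pixels, d0 = %g mm\n",
              nrow(x$bins), x$n, x$d0))
  invisible(x)
}

#' @export
plot.depth_histogram <- function(x, ...) {
  b <- x$bins
  plot(NA, xlim = range(c(b$z_lo, b$z_hi)), ylim = c(0, max(b$density)),
       xlab = "depth z (mm)", ylab = "pixels per unit depth (1/mm)", ...)
  graphics::rect(b$z_lo, 0, b$z_hi, b$density, col = "grey", border = "black")
  invisible(x)
}

#' Fraction of matched pixels per depth class
#'
#' Splits the depths of a depth map into classes at the given edges (e.g.
#' superficial vs deep layers) and reports the pixel fraction per class.
#'
#' @param depth_map a [fuse_pairs()] result or numeric depths (mm).
#' @param edges increasing class edges (mm), including outer bounds.
#' @return data frame with `z_lo`, `z_hi`, `count`, `fraction`.
#' @export
depth_class_fractions <- function(depth_map, edges) {
  z <- if (inherits(depth_map, "depth_map")) depth_map$z else depth_map
  z <- as.numeric(z)
  z <- z[!is.na(z)]
  stopifnot(length(edges) >= 2L, all(diff(edges) > 0))
  cnt <- graphics::hist(pmin(pmax(z, edges[1]), edges[length(edges)]),
                        breaks = edges, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)$counts
  data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1], count = cnt,
             fraction = if (length(z) > 0) cnt / length(z) else NA_real_)
}
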