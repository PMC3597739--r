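#' Extract a square window from a skeleton image
#'
#' Returns the square sub-grid of half-width `half_size` (mm) centered on a
#' pixel, zero-padded where the window extends beyond the image border.
#'
#' @param skel a [skeletonize()] result.
#' @param center integer `c(row, col)` of the center pixel.
#' @param half_size half the window edge (mm); the window spans
#'   `2 * round(half_size / pitch) + 1` pixels per side and must contain at
#'   least 3 x 3 pixels.
#' @return binary integer matrix.
#' @export
extract_window <- function(skel, center, half_size) {
  stopifnot(inherits(skel, "skeleton_image"), length(center) == 2L)
  h <- as.integer(round(half_size / skel$pitch))
  if (h < 1L)
    stop("window must contain at least 3 x 3 pixels; increase the window size")
  v <- skel$values
  side <- 2L * h + 1L
  out <- matrix(0L, side, side)
  rs <- (center[1] - h):(center[1] + h)
  cs <- (center[2] - h):(center[2] + h)
  ok_r <- rs >= 1L & rs <= nrow(v)
  ok_c <- cs >= 1L & cs <= ncol(v)
  out[ok_r, ok_c] <- v[rs[ok_r], cs[ok_c]]
  out
}

# pixel shift (row, col) realizing a displacement of k pixels along the
# unit vector deltaD_hat (nearest-pixel snapping off-axis)
beta_pixel_shift <- function(k, deltaD_hat) {
  c(round(k * deltaD_hat[2]), round(k * deltaD_hat[1]))  # (drow, dcol)
}

# tie-break on the plateau of maximal score: midpoint index of the tied
# set, rounding toward smaller beta
select_beta_index <- function(scores) {
  smax <- max(scores)
  if (smax <= 0) return(NA_integer_)
  ties <- which(scores == smax)
  ties[floor((length(ties) + 1L) / 2L)]
}

#' Offset parameter for one skeleton pixel by inner-product matching
#'
#' For a nonzero pixel of the reference (`D_plus`) skeleton, evaluates the
#' Frobenius inner product between the window centered on the pixel and
#' windows of the other (`D_minus`) skeleton shifted along the detector
#' offset direction by `beta * deltaD`, for `beta` on the quantized grid
#' `{k * pitch / deltaD, k = 0..floor(deltaD / pitch)}`. The returned alpha
#' is the `beta` maximizing the inner product; if the score is 0 for every
#' `beta` the pixel has no match (`NA`).
#'
#' @param skel_ref,skel_other [skeletonize()] results on the same grid
#'   (reference = `D_plus`, shifted windows from `D_minus`).
#' @param pixel integer `c(row, col)`, nonzero in `skel_ref`.
#' @param deltaD_vec length-2 detector offset vector (mm).
#' @param window full window edge (mm), default 4; must be below `deltaD`.
#' @return list with `alpha` (or `NA`), `score` (inner product at the
#'   maximum) and `beta_grid` size.
#' @export
match_alpha <- function(skel_ref, skel_other, pixel, deltaD_vec, window = 4) {
  stopifnot(inherits(skel_ref, "skeleton_image"),
            inherits(skel_other, "skeleton_image"))
  if (!identical(dim(skel_ref$values), dim(skel_other$values)) ||
      skel_ref$pitch != skel_other$pitch)
    stop("skeleton grids mismatched")
  pitch <- skel_ref$pitch
  dD <- sqrt(sum(deltaD_vec^2))
  h <- as.integer(round(window / 2 / pitch))
  if (h < 1L) stop("window must contain at least 3 x 3 pixels")
  if ((2L * h + 1L) * pitch >= dD)
    stop("window edge must be smaller than deltaD")
  if (skel_ref$values[pixel[1], pixel[2]] == 0L)
    stop("pixel is not on the reference skeleton")
  hat <- deltaD_vec / dD
  kmax <- as.integer(floor(dD / pitch))
  wref <- extract_window(skel_ref, pixel, window / 2)
  scores <- vapply(0:kmax, function(k) {
    sh <- beta_pixel_shift(k, hat)
    sum(wref * extract_window(skel_other, pixel + sh, window / 2))
  }, numeric(1))
  idx <- select_beta_index(scores)
  if (is.na(idx))
    return(list(alpha = NA_real_, score = 0L, beta_grid = kmax + 1L))
  list(alpha = (idx - 1L) * pitch / dD, score = as.integer(scores[idx]),
       beta_grid = kmax + 1L)
}

#' Offset-parameter map over a skeleton
#'
#' Applies [match_alpha()] to every nonzero pixel of the reference
#' (`D_plus`) skeleton, producing per-pixel alpha values (NA where no
#' shift produced a nonzero inner product) and scores, plus the fraction
#' of skeleton pixels that found a match.
#'
#' @param skel_plus reference skeleton (`D_plus` image).
#' @param skel_minus other skeleton (`D_minus` image).
#' @param deltaD_vec length-2 detector offset vector (mm).
#' @param window full window edge (mm), default 4 (must be `< deltaD` and
#'   span at least 3 pixels).
#' @param min_score minimum inner product for a match to be kept
#'   (default 1, i.e. any nonzero score).
#' @return object of class `alpha_map`: matrices `alpha` and `score`,
#'   `match_fraction`, grid metadata, `deltaD_vec` and the alpha quantum
#'   `pitch / deltaD`.
#' @export
alpha_map <- function(skel_plus, skel_minus, deltaD_vec, window = 4,
                      min_score = 1L) {
  stopifnot(inherits(skel_plus, "skeleton_image"))
  v <- skel_plus$values
  amat <- matrix(NA_real_, nrow(v), ncol(v))
  smat <- matrix(0L, nrow(v), ncol(v))
  idx <- which(v == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    m <- match_alpha(skel_plus, skel_minus, idx[i, ], deltaD_vec, window)
    if (!is.na(m$alpha) && m$score >= min_score) {
      amat[idx[i, 1], idx[i, 2]] <- m$alpha
      smat[idx[i, 1], idx[i, 2]] <- m$score
    }
  }
  n_skel <- nrow(idx)
  structure(
    list(alpha = amat, score = smat,
         match_fraction = if (n_skel > 0) sum(!is.na(amat)) / n_skel else NA_real_,
         n_skeleton = n_skel, pitch = skel_plus$pitch,
         origin = skel_plus$origin, deltaD_vec = as.numeric(deltaD_vec),
         alpha_quantum = skel_plus$pitch / sqrt(sum(deltaD_vec^2)),
         window = window),
    class = "alpha_map")
}

#' @export
print.alpha_map <- function(x, ...) {
  cat(sprintf(
    "<alpha_map> %d skeleton px, match fraction %.3f, alpha quantum %.4g\n",
    x$n_skeleton, x$match_fraction, x$alpha_quantum))
  invisible(x)
}

#' Number of resolvable alpha (depth) quanta
#'
#' The matching grid quantizes alpha to multiples of `pitch / deltaD`, so a
#' configuration resolves `floor(deltaD / pitch) + 1` distinct alpha values
#' (depth layers).
#'
#' @param deltaD detector separation (mm).
#' @param pitch pixel pitch of the matched images (mm).
#' @return integer count of distinct alpha values.
#' @examples
#' n_alpha_levels(13, 0.5)  # 27 depth layers
#' @export
n_alpha_levels <- function(deltaD, pitch) {
  stopifnot(deltaD > 0, pitch > 0)
  as.integer(floor(deltaD / pitch)) + 1L
}
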