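# shared media and cached curves (build_depth_curve memoizes per session)
m05_5 <- optical_medium(per_cm(0.05), per_cm(5))
m005_5 <- optical_medium(per_cm(0.005), per_cm(5))
curve40 <- function() build_depth_curve(m05_5, 40, 20)

# scan image holding an analytic field (positive values)
field_image <- function(f, xs, ys, pitch = xs[2] - xs[1]) {
  v <- outer(ys, xs, f)
  scan_image(v, pitch = pitch, origin = c(xs[1], ys[1]))
}

# forward-simulated pair for a thin rod along y at depth z (small grid)
rod_pair <- function(z, d0 = 40, deltaD = 20, pitch = 1,
                     xs = seq(-16, 16, by = pitch),
                     ys = seq(-6, 6, by = pitch), angle = 0,
                     medium = m05_5, delta_mu_a = 0.01) {
  geom <- pair_geometry(d0, c(deltaD, 0))
  th <- angle * pi / 180
  dir <- c(sin(th), cos(th))
  rod <- inclusion_cylinder(c(-60 * dir, z), c(60 * dir, z), 3, delta_mu_a)
  simulate_scan(medium, geom, inclusion_set(rod), list(x = xs, y = ys))
}

# number of connected components among skeleton pixels (8-neighborhood)
n_components <- function(skel) {
  idx <- which(skel$values == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  comp <- seq_len(nrow(idx))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(idx))) {
      nb <- which(abs(idx[, 1] - idx[i, 1]) <= 1 & abs(idx[, 2] - idx[i, 2]) <= 1)
      cmin <- min(comp[nb])
      if (any(comp[nb] != cmin)) { comp[nb] <- cmin; changed <- TRUE }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# brute-force inner-product scores over all beta shifts (independent of
# match_alpha): manual zero-padded window extraction
brute_scores <- function(ref, oth, center, half_px, kmax, dcol, drow) {
  win <- function(m, r, c) {
    out <- matrix(0L, 2 * half_px + 1, 2 * half_px + 1)
    rs <- (r - half_px):(r + half_px); cs <- (c - half_px):(c + half_px)
    ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  w0 <- win(ref, center[1], center[2])
  vapply(0:kmax, function(k)
    sum(w0 * win(oth, center[1] + k * drow, center[2] + k * dcol)),
    numeric(1))
}
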