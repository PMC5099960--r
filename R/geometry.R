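# Small 3-D vector helpers shared by the generator, the voxelizer and the
# morphometry code.  All vectors are length-3 numerics in mm, right-handed
# frame, angles in degrees unless suffixed _rad.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Rotate vector v about a unit axis by `deg` degrees (Rodrigues).
rotate_about <- function(v, axis, deg) {
  axis <- unitv(axis)
  th <- deg2rad(deg)
  v * cos(th) + vcross(axis, v) * sin(th) + axis * sum(axis * v) * (1 - cos(th))
}

# Unsigned angle between two vectors, in [0, 180] degrees.
angle_between <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# Component of v orthogonal to a unit axis.
reject_from <- function(v, axis) v - sum(v * axis) * axis

# Arc length of an n x 3 polyline.
polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# Cumulative arc-length positions (length n, starting at 0).
polyline_arcpos <- function(p) {
  if (nrow(p) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))))
}

# Moving-average smoothing of an n x 3 polyline with a centred window
# (endpoints kept fixed so junction/endpoint anchoring is preserved).
smooth_polyline <- function(p, window = 3L) {
  n <- nrow(p)
  if (n <= 2 || window < 2) return(p)
  h <- window %/% 2
  q <- p
  for (i in 2:(n - 1)) {
    j <- max(1, i - h):min(n, i + h)
    q[i, ] <- colMeans(p[j, , drop = FALSE])
  }
  q
}

# Dominant direction of a set of points (first principal axis), oriented so
# that it points from the first towards the last point.
pca_direction <- function(p) {
  if (nrow(p) < 2) stop("need at least 2 points for a direction", call. = FALSE)
  if (nrow(p) == 2) return(unitv(p[2, ] - p[1, ]))
  q <- sweep(p, 2, colMeans(p))
  v <- svd(q, nu = 0, nv = 1)$v[, 1]
  if (sum(v * (p[nrow(p), ] - p[1, ])) < 0) v <- -v
  unitv(v)
}

# Fold an angle (deg) into [-90, 90]: bifurcating planes are defined modulo
# 180 degrees, but the sign of +/-90 (which side the minor daughter grows)
# is meaningful and preserved at the boundary.
fold_plane_angle <- function(deg, tol = 1e-9) {
  while (deg > 90 + tol) deg <- deg - 180
  while (deg < -90 - tol) deg <- deg + 180
  min(max(deg, -90), 90)
}

# Normal of the reference plane projected orthogonal to a pathway direction:
# the normal of the plane that contains `dir` and is closest to the
# reference plane.  Falls back to a fixed axis when `dir` is (numerically)
# parallel to the reference normal.
inplane_normal <- function(dir, ref_normal) {
  n0 <- reject_from(ref_normal, unitv(dir))
  if (vnorm(n0) < 1e-9) n0 <- reject_from(c(1, 0, 0), unitv(dir))
  unitv(n0)
}

# Signed rotation of the bifurcating plane spanned by (parent_dir,
# minor_dir) relative to the reference plane, folded to [-90, 90].  The
# plane normal is taken as parent x minor, so the sign encodes which side
# of the reference plane the minor daughter grows towards.
signed_plane_rotation <- function(parent_dir, minor_dir, ref_normal) {
  p <- unitv(parent_dir)
  n <- vcross(p, unitv(minor_dir))
  if (vnorm(n) < 1e-9) return(NA_real_)  # daughter parallel to parent
  n <- unitv(n)
  n0 <- inplane_normal(p, ref_normal)
  ang <- rad2deg(atan2(sum(vcross(n0, n) * p), sum(n0 * n)))
  fold_plane_angle(ang)
}

# Direction of a polyline near one end, robust to junction artefacts:
# scanning from the requested end towards the middle, return the fit over
# the first window of length w_mm whose points are collinear within
# tol_deg (chord deviations from the window's principal axis).  Skeleton
# centrelines bend inside junction-fusion regions; the first straight
# window just beyond them carries the branch's true local direction.
stable_end_direction <- function(p, end = c("proximal", "distal"),
                                 w_mm = NULL, tol_deg = 8, max_scan = 0.7) {
  end <- match.arg(end)
  s <- polyline_arcpos(p)
  L <- s[length(s)]
  if (is.null(w_mm)) w_mm <- max(2.5, 0.2 * L)
  w_mm <- min(w_mm, 0.9 * L)
  offsets <- s[s <= max_scan * L]
  # straightness = angle between the line fits of the window's two halves
  # (voxel-staircase noise averages out within each half)
  fit_window <- function(a, w) {
    keep <- if (end == "proximal") s >= a & s <= a + w
    else s >= L - a - w & s <= L - a
    if (sum(keep) < 6) return(NULL)
    q <- p[keep, , drop = FALSE]
    dir <- pca_direction(q)
    h <- nrow(q) %/% 2
    d1 <- pca_direction(q[seq_len(h), , drop = FALSE])
    d2 <- pca_direction(q[(h + 1):nrow(q), , drop = FALSE])
    list(dir = dir, spread = angle_between(d1, d2))
  }
  best_a <- NULL
  best_spread <- Inf
  for (a in offsets) {
    f <- fit_window(a, w_mm)
    if (is.null(f)) next
    if (f$spread < best_spread) {
      best_spread <- f$spread
      best_a <- a
    }
    if (f$spread < tol_deg) { best_a <- a; break }
  }
  if (is.null(best_a)) return(pca_direction(p))
  # refit over an extended window anchored at the stable start: longer
  # support averages out the voxel staircase of skeleton centrelines
  f_ext <- fit_window(best_a, max(2 * w_mm, 6))
  f0 <- fit_window(best_a, w_mm)
  if (!is.null(f_ext) && f_ext$spread < max(tol_deg, best_spread + 2))
    f_ext$dir
  else f0$dir
}

# Minimum distance between one segment (P0, P1) and many segments
# (rows of A, B): clamped closest-point computation, vectorised over rows.
segment_distances <- function(P0, P1, A, B) {
  d1 <- P1 - P0
  d2 <- B - A
  r <- sweep(A, 2, P0, `-`)
  a <- sum(d1 * d1)
  e <- rowSums(d2 * d2)
  b <- as.numeric(d2 %*% d1)
  c1 <- -as.numeric(r %*% d1)
  f <- -rowSums(d2 * r)
  denom <- a * e - b^2
  s <- ifelse(denom > 1e-12, pmin(pmax((b * f - c1 * e) / denom, 0), 1), 0)
  t <- ifelse(e > 1e-12, pmin(pmax((b * s + f) / e, 0), 1), 0)
  s <- if (a > 1e-12) pmin(pmax((b * t - c1) / a, 0), 1) else rep(0, length(t))
  px <- P0[1] + s * d1[1] - (A[, 1] + t * d2[, 1])
  py <- P0[2] + s * d1[2] - (A[, 2] + t * d2[, 2])
  pz <- P0[3] + s * d1[3] - (A[, 3] + t * d2[, 3])
  sqrt(px^2 + py^2 + pz^2)
}

# Run RNG-consuming code under a fixed seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal draw by rejection; sd = 0 degenerates to the clamped mean.
rtruncnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  for (i in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal rejection failed; bounds too tight", call. = FALSE)
}
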