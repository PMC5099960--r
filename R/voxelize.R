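# Rasterization of an airway tree into a CT-like binary lumen mask.
#
# The lumen solid is the union of tapered elliptical tubes along the branch
# centrelines: semi-minor axis = nominal radius everywhere, semi-major =
# radius / aspect, with the aspect falling from its outer value to the
# flared end value across the transition zone; branch ends are rounded
# (ellipsoidal caps) so parent and daughters join without gaps, and the
# crotch between the two daughters carries a fillet of the configured
# flow-divider radius.  Voxels are foreground iff their centre lies inside
# the solid (no partial volume), which makes rasterization bit-reproducible.

branch_lumen_spec <- function(branch, is_root = FALSE) {
  m <- branch$meta
  aspect0 <- m$aspect0 %||% 1
  has_event <- length(branch$child_ids) == 2 && !is.null(m$ellipse_axis)
  list(
    centerline = branch$centerline,
    r = branch$diameter_mm / 2,
    aspect0 = aspect0,
    aspect_end = if (has_event) (m$aspect_end %||% aspect0) else aspect0,
    tz_fraction = if (has_event) (m$tz_fraction %||% 0) else 0,
    ellipse_axis = m$ellipse_axis,
    flat_proximal = is_root
  )
}

# Paint one branch into a logical subarray; returns the subarray plus its
# index offsets in the full grid.
paint_branch <- function(spec, dims, spacing, origin) {
  cl <- spec$centerline
  r <- spec$r
  a_min <- min(spec$aspect0, spec$aspect_end)
  margin <- r / a_min + 2 * max(spacing)
  lo_w <- apply(cl, 2, min) - margin
  hi_w <- apply(cl, 2, max) + margin
  i0 <- pmax(1L, as.integer(floor((lo_w - origin) / spacing)) + 1L)
  i1 <- pmin(dims, as.integer(ceiling((hi_w - origin) / spacing)) + 1L)
  if (any(i1 < i0)) return(NULL)
  nsub <- i1 - i0 + 1L

  xs <- origin[1] + (i0[1]:i1[1] - 1) * spacing[1]
  ys <- origin[2] + (i0[2]:i1[2] - 1) * spacing[2]
  zs <- origin[3] + (i0[3]:i1[3] - 1) * spacing[3]
  px <- rep(xs, times = nsub[2] * nsub[3])
  py <- rep(rep(ys, each = nsub[1]), times = nsub[3])
  pz <- rep(zs, each = nsub[1] * nsub[2])

  s_seg <- polyline_arcpos(cl)
  L <- s_seg[length(s_seg)]
  sz <- L * (1 - spec$tz_fraction)   # arc position where the flare begins
  inside <- rep(FALSE, length(px))
  nseg <- nrow(cl) - 1

  for (k in seq_len(nseg)) {
    A <- cl[k, ]; B <- cl[k + 1, ]
    Tv <- B - A
    len <- vnorm(Tv)
    if (len < 1e-9) next
    Tv <- Tv / len
    u <- spec$ellipse_axis
    if (is.null(u)) u <- if (abs(Tv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- reject_from(u, Tv)
    if (vnorm(u) < 1e-6) u <- reject_from(c(1, 0, 0), Tv)
    u <- unitv(u)
    v <- vcross(Tv, u)

    wx <- px - A[1]; wy <- py - A[2]; wz <- pz - A[3]
    t <- wx * Tv[1] + wy * Tv[2] + wz * Tv[3]
    dax <- numeric(length(t))
    if (k == 1) dax <- pmin(t, 0) else t[t < 0] <- 0
    if (k == nseg) dax <- dax + pmax(t - len, 0) else t[t > len] <- len
    tcl <- pmin(pmax(t, 0), len)
    if (spec$flat_proximal && k == 1) dax[t < 0] <- Inf

    dxv <- wx - tcl * Tv[1]; dyv <- wy - tcl * Tv[2]; dzv <- wz - tcl * Tv[3]
    du <- dxv * u[1] + dyv * u[2] + dzv * u[3]
    dv <- dxv * v[1] + dyv * v[2] + dzv * v[3]

    s_arc <- s_seg[k] + tcl
    aspect <- rep(spec$aspect0, length(t))
    if (spec$tz_fraction > 0 && L > sz) {
      f <- pmin(pmax((s_arc - sz) / (L - sz), 0), 1)
      aspect <- spec$aspect0 + f * (spec$aspect_end - spec$aspect0)
    }
    amaj <- r / aspect
    q <- (du / amaj)^2 + (dv / r)^2 + (dax / r)^2
    inside <- inside | (q <= 1)
  }
  list(sub = array(inside, nsub), i0 = i0, i1 = i1)
}

# Fillet at the flow divider: the wedge between the two daughter tubes is
# filled where the summed surface clearances stay below the divider radius,
# rounding the carinal edge at that scale.
paint_fillet <- function(junction, d1, d2, r_fd, dims, spacing, origin) {
  seg <- function(br) {
    cl <- br$centerline
    list(A = cl[1, ], B = cl[2, ], r = br$diameter_mm / 2)
  }
  s1 <- seg(d1); s2 <- seg(d2)
  margin <- max(s1$r, s2$r) + r_fd + 2 * max(spacing)
  reach <- min(3 * max(s1$r, s2$r),
               max(vnorm(s1$B - s1$A), vnorm(s2$B - s2$A)))
  lo_w <- junction - margin - reach
  hi_w <- junction + margin + reach
  i0 <- pmax(1L, as.integer(floor((lo_w - origin) / spacing)) + 1L)
  i1 <- pmin(dims, as.integer(ceiling((hi_w - origin) / spacing)) + 1L)
  if (any(i1 < i0)) return(NULL)
  nsub <- i1 - i0 + 1L
  xs <- origin[1] + (i0[1]:i1[1] - 1) * spacing[1]
  ys <- origin[2] + (i0[2]:i1[2] - 1) * spacing[2]
  zs <- origin[3] + (i0[3]:i1[3] - 1) * spacing[3]
  px <- rep(xs, times = nsub[2] * nsub[3])
  py <- rep(rep(ys, each = nsub[1]), times = nsub[3])
  pz <- rep(zs, each = nsub[1] * nsub[2])

  clearance <- function(s) {
    Tv <- s$B - s$A
    len <- vnorm(Tv)
    Tv <- Tv / len
    wx <- px - s$A[1]; wy <- py - s$A[2]; wz <- pz - s$A[3]
    t <- pmin(pmax(wx * Tv[1] + wy * Tv[2] + wz * Tv[3], 0), len)
    dxv <- wx - t * Tv[1]; dyv <- wy - t * Tv[2]; dzv <- wz - t * Tv[3]
    pmax(sqrt(dxv^2 + dyv^2 + dzv^2) - s$r, 0)
  }
  inside <- (clearance(s1) + clearance(s2)) <= r_fd
  list(sub = array(inside, nsub), i0 = i0, i1 = i1)
}

#' Rasterize an airway tree into a binary lumen mask
#'
#' A voxel is foreground iff its centre lies inside the lumen solid (union
#' of tapered elliptical tubes with rounded ends, transition-zone flaring
#' and flow-divider fillets).  The grid covers the tree with at least two
#' voxels of background padding.
#'
#' @param tree A valid [airway_tree()] (generated trees carry the lumen
#'   shape parameters in their branch metadata; trees without them are
#'   rendered with circular cross-sections).
#' @param spacing_mm Voxel spacing, scalar or length 3 (default CT-like
#'   `c(0.8, 0.8, 1)`).
#' @param pad_mm Background padding added around the tree bounding box.
#' @param max_voxels Safety limit on the array size.
#' @return A [voxel_mask()].
#' @export
voxelize_tree <- function(tree, spacing_mm = c(0.8, 0.8, 1.0),
                          pad_mm = NULL, max_voxels = 6e8) {
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  diag <- validate_tree(tree)
  if (nrow(diag))
    stop("cannot voxelize an invalid tree: ",
         paste(unique(diag$rule), collapse = ", "), call. = FALSE)
  if (is.null(pad_mm)) pad_mm <- 2 * max(spacing_mm)

  br <- tree$branches
  # per-branch margins: nominal radius over the worst-case flare aspect,
  # plus the divider fillet reach
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (b in br) {
    m <- b$diameter_mm / 2 / min(b$meta$aspect_end %||% 1,
                                 b$meta$aspect0 %||% 1) +
      (b$meta$divider_radius_mm %||% 0)
    lo <- pmin(lo, apply(b$centerline, 2, min) - m)
    hi <- pmax(hi, apply(b$centerline, 2, max) + m)
  }
  lo <- lo - pad_mm
  hi <- hi + pad_mm
  dims <- as.integer(ceiling((hi - lo) / spacing_mm)) + 1L
  if (prod(as.numeric(dims)) > max_voxels)
    stop(sprintf("tree needs a %d x %d x %d grid (> max_voxels); coarsen the spacing",
                 dims[1], dims[2], dims[3]), call. = FALSE)
  origin <- lo

  mask <- array(FALSE, dims)
  blit <- function(p) {
    if (is.null(p)) return()
    mask[p$i0[1]:p$i1[1], p$i0[2]:p$i1[2], p$i0[3]:p$i1[3]] <<-
      mask[p$i0[1]:p$i1[1], p$i0[2]:p$i1[2], p$i0[3]:p$i1[3]] | p$sub
  }
  for (b in br) {
    blit(paint_branch(branch_lumen_spec(b, is_root = is.na(b$parent_id)),
                      dims, spacing_mm, origin))
  }
  for (b in br) {
    if (length(b$child_ids) != 2) next
    r_fd <- b$meta$divider_radius_mm %||% 1
    blit(paint_fillet(b$centerline[nrow(b$centerline), ],
                      br[[b$child_ids[1]]], br[[b$child_ids[2]]],
                      r_fd, dims, spacing_mm, origin))
  }
  voxel_mask(mask, spacing_mm = spacing_mm, origin_mm = origin)
}
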