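# Triangulated lumen surface: one closed generalized-cylinder component per
# branch (elliptical rings along the centreline, fan caps at both ends),
# written as binary STL.

mesh_one_branch <- function(spec, n_around = 32, step_mm = 1) {
  cl <- spec$centerline
  s <- polyline_arcpos(cl)
  L <- s[length(s)]
  samp_s <- seq(0, L, by = step_mm)
  if (L - samp_s[length(samp_s)] < 0.25 * step_mm) {
    samp_s[length(samp_s)] <- L       # avoid a near-duplicate final ring
  } else {
    samp_s <- c(samp_s, L)
  }
  tg <- polyline_tangents(cl)
  r <- spec$r
  sz <- L * (1 - spec$tz_fraction)

  rings <- lapply(samp_s, function(si) {
    j <- findInterval(si, s, rightmost.closed = TRUE)
    j <- min(max(j, 1), nrow(cl) - 1)
    f <- (si - s[j]) / max(s[j + 1] - s[j], 1e-12)
    p <- cl[j, ] * (1 - f) + cl[j + 1, ] * f
    tgi <- unitv(tg[j, ] * (1 - f) + tg[j + 1, ] * f)
    u <- spec$ellipse_axis
    if (is.null(u)) u <- if (abs(tgi[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- reject_from(u, tgi)
    if (vnorm(u) < 1e-6) u <- reject_from(c(1, 0, 0), tgi)
    u <- unitv(u)
    v <- vcross(tgi, u)
    aspect <- if (spec$tz_fraction > 0 && si > sz && L > sz) {
      spec$aspect0 + (si - sz) / (L - sz) * (spec$aspect_end - spec$aspect0)
    } else spec$aspect0
    amaj <- r / aspect
    phi <- seq(0, 2 * pi, length.out = n_around + 1)[seq_len(n_around)]
    t(vapply(phi, function(ph) p + amaj * cos(ph) * u + r * sin(ph) * v,
             numeric(3)))
  })

  tris <- list()
  addtri <- function(a, b, cc) tris[[length(tris) + 1]] <<- c(a, b, cc)
  nr <- length(rings)
  for (k in seq_len(nr - 1)) {
    R1 <- rings[[k]]; R2 <- rings[[k + 1]]
    for (j in seq_len(n_around)) {
      j2 <- if (j == n_around) 1L else j + 1L
      addtri(R1[j, ], R1[j2, ], R2[j, ])
      addtri(R1[j2, ], R2[j2, ], R2[j, ])
    }
  }
  # caps: fans to the ring centroids (flat, outward winding)
  c1 <- colMeans(rings[[1]]); c2 <- colMeans(rings[[nr]])
  R1 <- rings[[1]]; R2 <- rings[[nr]]
  for (j in seq_len(n_around)) {
    j2 <- if (j == n_around) 1L else j + 1L
    addtri(c1, R1[j2, ], R1[j, ])
    addtri(c2, R2[j, ], R2[j2, ])
  }
  do.call(rbind, lapply(tris, function(t) matrix(t, 1, 9)))
}

#' Triangulated lumen surface of a tree
#'
#' One closed, consistently wound component per branch (the solid is the
#' union of the per-branch components, as in the voxelizer).
#'
#' @param tree A valid [airway_tree()].
#' @param n_around Vertices per ring (default 32).
#' @param step_mm Ring spacing along the centreline.
#' @return Numeric matrix (n_triangles x 9): the three vertices of each
#'   triangle as `(x1,y1,z1, x2,y2,z2, x3,y3,z3)`.
#' @export
surface_mesh <- function(tree, n_around = 32, step_mm = 1) {
  diag <- validate_tree(tree)
  if (nrow(diag))
    stop("cannot mesh an invalid tree: ",
         paste(unique(diag$rule), collapse = ", "), call. = FALSE)
  do.call(rbind, lapply(tree$branches, function(b)
    mesh_one_branch(branch_lumen_spec(b), n_around, step_mm)))
}

# Each undirected edge of a closed oriented surface must appear exactly
# twice, once per direction.
mesh_is_watertight <- function(tris) {
  key <- function(p) paste(sprintf("%.6f", p), collapse = ",")
  edges <- character(0)
  for (i in seq_len(nrow(tris))) {
    v <- list(tris[i, 1:3], tris[i, 4:6], tris[i, 7:9])
    edges <- c(edges,
               paste(key(v[[1]]), key(v[[2]]), sep = "|"),
               paste(key(v[[2]]), key(v[[3]]), sep = "|"),
               paste(key(v[[3]]), key(v[[1]]), sep = "|"))
  }
  rev_edges <- vapply(strsplit(edges, "|", fixed = TRUE),
                      function(e) paste(e[2], e[1], sep = "|"), character(1))
  all(sort(edges) == sort(rev_edges)) && !anyDuplicated(edges)
}

triangle_areas <- function(tris) {
  a <- tris[, 4:6] - tris[, 1:3]
  b <- tris[, 7:9] - tris[, 1:3]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Export the lumen surface as binary STL
#'
#' Refuses to write a non-manifold surface (every component must be closed
#' with consistent winding).
#'
#' @param tree A valid [airway_tree()].
#' @param path Output `.stl` path.
#' @param n_around,step_mm Passed to [surface_mesh()].
#' @return `path`, invisibly.
#' @export
export_mesh <- function(tree, path, n_around = 32, step_mm = 1) {
  tris <- surface_mesh(tree, n_around, step_mm)
  if (!mesh_is_watertight(tris))
    stop("mesh is not watertight; refusing to write", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(tris)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(tris))) {
    a <- tris[i, 4:6] - tris[i, 1:3]
    b <- tris[i, 7:9] - tris[i, 1:3]
    nrm <- vcross(a, b)
    nn <- vnorm(nrm)
    if (nn > 1e-12) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, tris[i, ])), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}
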