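# Measurement of an airway tree from a binary mask: rooted tree assembly
# from the condensed skeleton graph, EDT-based diameter profiles, and
# cross-sectional caliper measurements.

# Sub-voxel local radius estimate at points p (n x 3) with unit tangents tg
# (n x 3).  Near the medial axis the EDT falls off linearly with offset,
# with direction-dependent slope (slope 1 towards the nearest wall, ~0
# along the major axis of an elliptical section).  For each perpendicular
# direction u the two-sided tent estimate
#   (EDT(p+hu) + EDT(p-hu))/2 + h * slope_u
# with the slope itself estimated from the h and 2h samples is exact on
# the ridge for any slope, and exact off-ridge when u aligns with the
# offset; the maximum over several directions cancels the off-axis bias
# of sampling the EDT at a skeleton voxel directly.
edt_radius <- function(edt_field, dims, spacing, origin, pts, tangents,
                       n_dir = 8) {
  n <- nrow(pts)
  h <- min(spacing)
  angles <- seq(0, pi, length.out = n_dir + 1)[seq_len(n_dir)]
  best <- rep(-Inf, n)
  for (i in seq_len(n)) {
    tg <- tangents[i, ]
    u <- reject_from(c(1, 0, 0), tg)
    if (vnorm(u) < 1e-6) u <- reject_from(c(0, 1, 0), tg)
    u <- unitv(u)
    v <- vcross(tg, u)
    dirs <- t(vapply(angles, function(a) cos(a) * u + sin(a) * v, numeric(3)))
    pp <- pts[rep(i, 4 * n_dir), ] +
      rbind(h * dirs, -h * dirs, 2 * h * dirs, -2 * h * dirs)
    val <- cpp_trilinear(edt_field, dims, spacing, origin, pp)
    f_p1 <- val[seq_len(n_dir)]
    f_m1 <- val[n_dir + seq_len(n_dir)]
    f_p2 <- val[2 * n_dir + seq_len(n_dir)]
    f_m2 <- val[3 * n_dir + seq_len(n_dir)]
    slope <- pmin(pmax(((f_p1 - f_p2) + (f_m1 - f_m2)) / (2 * h), 0), 1)
    best[i] <- max((f_p1 + f_m1) / 2 + h * slope)
  }
  best
}

polyline_tangents <- function(p) {
  n <- nrow(p)
  tg <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- max(1, i - 1); b <- min(n, i + 1)
    d <- p[b, ] - p[a, ]
    if (vnorm(d) < 1e-9) d <- c(0, 0, 1)
    tg[i, ] <- unitv(d)
  }
  tg
}

# Representative diameter: median of 2 * local radius over the middle 60 %
# of the branch (transition zones at both ends excluded), additionally
# stepping over the junction-fusion regions at either end when their
# inscribed radii are known (the lumen there is the union of parent and
# daughters, which inflates the EDT).
branch_diameter_from_edt <- function(cl, edt_field, dims, spacing, origin,
                                     prox_excl_mm = 0, dist_excl_mm = 0) {
  s <- polyline_arcpos(cl)
  L <- s[length(s)]
  lo <- max(0.2 * L, min(prox_excl_mm, 0.45 * L))
  hi <- min(0.8 * L, L - min(dist_excl_mm, 0.2 * L))
  keep <- s >= lo & s <= hi
  if (sum(keep) < 3) keep <- s >= 0.2 * L & s <= 0.8 * L
  if (sum(keep) < 3) keep <- rep(TRUE, nrow(cl))
  pts <- cl[keep, , drop = FALSE]
  tg <- polyline_tangents(cl)[keep, , drop = FALSE]
  2 * median(edt_radius(edt_field, dims, spacing, origin, pts, tg))
}

#' Build a measured airway tree from a skeleton graph and its mask
#'
#' The computational analog of measuring a segmented cast: the condensed
#' skeleton is rooted at the endpoint nearest `root_hint`, each
#' junction-to-junction path becomes a branch whose centreline (junction
#' centroids plus path voxels, moving-average smoothed) gives the length,
#' whose diameter is the median of twice the interpolated distance
#' transform over the middle 60 % of the branch, and whose proximal/distal
#' directions come from line fits.  Junctions with more than two outgoing
#' paths are resolved into a chain of binary events via short intermediate
#' segments (the same modelling device used for the trachea).
#'
#' @param graph A `centerline_graph` from [skeletonize_mask()].
#' @param mask The [voxel_mask()] the graph was extracted from.
#' @param root_hint World point (mm) inside the trachea.
#' @param reference_plane Optional reference plane; when `NULL` it is
#'   estimated as the plane spanned by the trachea direction and the
#'   left-mainstem (minor carina daughter) direction.
#' @param smooth_window Moving-average window (samples) for centreline
#'   smoothing before length/direction estimation.
#' @param on_cycle Cycles in the skeleton graph (lumens of touching
#'   branches fuse into a loop) are an error by default; `"break"` drops
#'   the cycle-closing path with a warning instead.
#' @return An [airway_tree()] with diameters, lengths and role tags set;
#'   generations are left unset (use [assign_generations()]).
#' @export
build_measured_tree <- function(graph, mask, root_hint,
                                reference_plane = NULL, smooth_window = 3L,
                                on_cycle = c("error", "break")) {
  on_cycle <- match.arg(on_cycle)
  stopifnot(inherits(mask, "voxel_mask"))
  dims <- dim(mask$data)
  vi <- pmin(pmax(round((root_hint - mask$origin_mm) / mask$spacing_mm) + 1, 1),
             dims)
  if (!mask$data[vi[1], vi[2], vi[3]])
    stop("root_hint is outside the mask foreground", call. = FALSE)

  cg <- graph$condensed
  if (is.null(cg)) cg <- prune_condensed(condense_graph(graph), 0)
  if (!nrow(cg$vpaths)) stop("skeleton graph has no paths", call. = FALSE)

  edt_field <- graph$edt_field
  if (is.null(edt_field) || length(edt_field) != prod(dims))
    edt_field <- cpp_edt(as.logical(mask$data), dims, mask$spacing_mm)

  verts <- cg$vertices
  vxyz <- as.matrix(verts[, c("x", "y", "z")])
  used_vids <- unique(c(cg$vpaths$from_vid, cg$vpaths$to_vid))
  ep <- verts$vid[verts$kind == "endpoint" & verts$vid %in% used_vids]
  if (!length(ep)) ep <- used_vids
  d2root <- rowSums(sweep(vxyz[match(ep, verts$vid), , drop = FALSE], 2,
                          root_hint)^2)
  root_vid <- ep[which.min(d2root)]

  # orient paths away from the root by BFS over the condensed graph
  vp <- cg$vpaths
  nodes_xyz <- function(rows) {
    cbind(graph$nodes$x[rows], graph$nodes$y[rows], graph$nodes$z[rows])
  }
  vert_xyz <- function(vid) vxyz[match(vid, verts$vid), ]

  env <- new.env(parent = emptyenv())
  env$branches <- list()
  env$counter <- 0L
  new_id <- function() {
    env$counter <- env$counter + 1L
    sprintf("m%04d", env$counter)
  }

  path_used <- rep(FALSE, nrow(vp))
  visited_v <- root_vid

  vert_excl <- function(vid) {
    i <- match(vid, verts$vid)
    if (!is.null(verts$edt) && verts$kind[i] == "junction") verts$edt[i] else 0
  }

  make_branch <- function(pi, from_vid, parent_id) {
    to_vid <- if (vp$from_vid[pi] == from_vid) vp$to_vid[pi] else vp$from_vid[pi]
    rows <- vp$rows[[pi]]
    if (vp$from_vid[pi] != from_vid) rows <- rev(rows)
    cl <- rbind(vert_xyz(from_vid), nodes_xyz(rows), vert_xyz(to_vid))
    cl <- cl[!duplicated(round(cl, 9)), , drop = FALSE]
    if (nrow(cl) < 2) cl <- rbind(vert_xyz(from_vid), vert_xyz(to_vid))
    cl <- smooth_polyline(cl, smooth_window)
    dia <- branch_diameter_from_edt(cl, edt_field, dims, mask$spacing_mm,
                                    mask$origin_mm,
                                    prox_excl_mm = vert_excl(from_vid),
                                    dist_excl_mm = vert_excl(to_vid))
    id <- new_id()
    b <- airway_branch(id, parent_id = parent_id, centerline = cl,
                       diameter_mm = dia, role_tag = "other",
                       meta = list(from_vid = from_vid, to_vid = to_vid))
    env$branches[[id]] <- b
    list(id = id, to_vid = to_vid)
  }

  # depth-first expansion; returns the branch id rooted at (from_vid, path
  # pi), or NA when a cycle-closing path was dropped
  expand <- function(pi, from_vid, parent_id) {
    res <- make_branch(pi, from_vid, parent_id)
    v <- res$to_vid
    if (v %in% visited_v) {
      if (on_cycle == "error")
        stop("cycle in the skeleton graph at vertex ", v,
             " (touching branches?)", call. = FALSE)
      warning("dropping a cycle-closing skeleton path at vertex ", v,
              " (touching branches)", call. = FALSE)
      env$branches[[res$id]] <- NULL
      return(NA_character_)
    }
    visited_v <<- c(visited_v, v)
    kids <- which(!path_used & (vp$from_vid == v | vp$to_vid == v))
    path_used[kids] <<- TRUE
    if (length(kids)) attach_children(res$id, v, kids)
    res$id
  }

  # Attach child paths at vertex v to branch `pid`.  A single child is a
  # degree-2 artefact merged back into its parent; more than two children
  # are chained through short stub segments (largest diameter kept first),
  # the same stacked-binary device used to model the trachea.
  attach_children <- function(pid, v, kids) {
    ids <- vapply(kids, function(pi) expand(pi, v, pid), character(1))
    ids <- ids[!is.na(ids)]
    if (!length(ids)) return(invisible(NULL))
    if (length(ids) == 1) {
      env$branches[[pid]]$child_ids <- ids
      env$branches[[ids]]$parent_id <- pid
      merge_single_child(pid)
      return(invisible(NULL))
    }
    dias <- vapply(ids, function(id) env$branches[[id]]$diameter_mm, numeric(1))
    ids <- ids[order(-dias, ids)]
    p0 <- vert_xyz(v)
    pdir <- branch_direction(env$branches[[pid]], "distal")
    cur <- pid
    while (length(ids) > 2) {
      stub_id <- new_id()
      stub <- airway_branch(
        stub_id, parent_id = cur,
        centerline = rbind(p0, p0 + pdir * 0.5),
        diameter_mm = max(vapply(ids[-1], function(id)
          env$branches[[id]]$diameter_mm, numeric(1))),
        role_tag = "other", meta = list(virtual = TRUE))
      env$branches[[stub_id]] <- stub
      env$branches[[cur]]$child_ids <- c(ids[1], stub_id)
      env$branches[[ids[1]]]$parent_id <- cur
      ids <- ids[-1]
      cur <- stub_id
      p0 <- p0 + pdir * 0.5
    }
    env$branches[[cur]]$child_ids <- ids
    for (id in ids) env$branches[[id]]$parent_id <- cur
  }

  merge_single_child <- function(pid) {
    b <- env$branches[[pid]]
    if (length(b$child_ids) != 1) return(invisible(NULL))
    child <- env$branches[[b$child_ids[1]]]
    cl <- rbind(b$centerline, child$centerline[-1, , drop = FALSE])
    b$centerline <- cl
    b$length_mm <- polyline_length(cl)
    b$diameter_mm <- branch_diameter_from_edt(cl, edt_field, dims,
                                              mask$spacing_mm, mask$origin_mm)
    b$child_ids <- child$child_ids
    env$branches[[pid]] <- b
    for (cid in child$child_ids) env$branches[[cid]]$parent_id <- pid
    env$branches[[child$id]] <- NULL
  }

  # remove "twin leaves": a terminal branch as wide as its parent and
  # shorter than the parent diameter cannot be a real daughter; it is a
  # medial-surface remnant of a fat junction.
  prune_twin_leaves <- function() {
    repeat {
      hit <- NULL
      for (b in env$branches) {
        if (length(b$child_ids) || is.na(b$parent_id)) next
        pb <- env$branches[[b$parent_id]]
        if (b$diameter_mm > 0.95 * pb$diameter_mm &&
            b$length_mm < pb$diameter_mm) { hit <- b$id; break }
      }
      if (is.null(hit)) break
      pid <- env$branches[[hit]]$parent_id
      env$branches[[pid]]$child_ids <-
        setdiff(env$branches[[pid]]$child_ids, hit)
      env$branches[[hit]] <- NULL
      merge_single_child(pid)
    }
  }

  root_paths <- which(vp$from_vid == root_vid | vp$to_vid == root_vid)
  if (length(root_paths) != 1)
    stop("root endpoint touches ", length(root_paths),
         " paths; expected a single trachea", call. = FALSE)
  path_used[root_paths] <- TRUE
  root_id <- expand(root_paths, root_vid, NA_character_)
  env$branches[[root_id]]$parent_id <- NA_character_
  prune_twin_leaves()
  env$branches[[root_id]]$role_tag <- "trachea"

  # role tags: the immediate continuation with a comparable diameter is the
  # distal trachea; its two daughters are the mainstem bronchi.
  root_b <- env$branches[[root_id]]
  last_trachea <- root_id
  kids <- root_b$child_ids
  if (length(kids) == 2) {
    kd <- vapply(kids, function(id) env$branches[[id]]$diameter_mm, numeric(1))
    big <- kids[which.max(kd)]
    if (max(kd) >= 0.85 * root_b$diameter_mm) {
      env$branches[[big]]$role_tag <- "trachea"
      small <- setdiff(kids, big)
      env$branches[[small]]$role_tag <- "tracheal_bronchus"
      last_trachea <- big
    }
  }
  mk <- env$branches[[last_trachea]]$child_ids
  if (length(mk) == 2) {
    md <- vapply(mk, function(id) env$branches[[id]]$diameter_mm, numeric(1))
    env$branches[[mk[which.max(md)]]]$role_tag <- "right_mainstem"
    env$branches[[mk[which.min(md)]]]$role_tag <- "left_mainstem"
  }

  tree <- airway_tree(env$branches, root_id = root_id)
  if (is.null(reference_plane)) {
    lt <- tree$branches[[last_trachea]]
    lm_id <- names(tree$branches)[vapply(tree$branches, function(b)
      b$role_tag == "left_mainstem", logical(1))]
    if (length(lm_id) == 1) {
      tdir <- branch_direction(lt, "distal")
      ldir <- branch_direction(tree$branches[[lm_id]], "proximal",
                               skip_mm = lt$diameter_mm / 2)
      nref <- vcross(tdir, ldir)
      if (vnorm(nref) > 1e-6) {
        tree$reference_plane <- list(
          normal = unitv(nref),
          point = lt$centerline[nrow(lt$centerline), ])
      }
    }
  } else {
    tree$reference_plane <- reference_plane
  }
  tree
}

#' Cross-sectional diameter profile along a centreline
#'
#' At each sample the plane normal to the local tangent is intersected
#' with the mask: rays are cast on a polar fan and the 0.5-level crossing
#' of the trilinearly interpolated mask located by bisection; opposite
#' rays are summed into caliper chords whose minimum and maximum give the
#' local Dmin/Dmax and aspect ratio.
#'
#' @param mask A [voxel_mask()].
#' @param path Centreline polyline (n x 3, mm) inside the foreground.
#' @param n_theta Number of caliper directions per half-turn (default 24).
#' @param step_mm Sample spacing along the path (default one voxel).
#' @return A tibble: `position_mm`, `d_min_mm`, `d_max_mm`, `aspect`.
#' @export
measure_diameter_profile <- function(mask, path, n_theta = 24, step_mm = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  path <- as.matrix(path)
  if (any(rowSums((path[-1, , drop = FALSE] -
                     path[-nrow(path), , drop = FALSE])^2) < 1e-18))
    stop("duplicate consecutive path points; tangent undefined", call. = FALSE)
  dims <- dim(mask$data)
  sp <- mask$spacing_mm
  if (is.null(step_mm)) step_mm <- min(sp)

  # local crop (with margin) converted to double for interpolation
  pad <- 30
  i0 <- pmax(1L, as.integer(floor((apply(path, 2, min) - pad - mask$origin_mm) / sp)) + 1L)
  i1 <- pmin(dims, as.integer(ceiling((apply(path, 2, max) + pad - mask$origin_mm) / sp)) + 1L)
  sub <- mask$data[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
  field <- array(as.double(sub), dim(sub))
  sorig <- mask$origin_mm + (i0 - 1) * sp

  # check the path lies in the foreground
  vi <- round(sweep(path, 2, mask$origin_mm) / rep(sp, each = nrow(path))) + 1
  vi <- pmin(pmax(vi, 1), matrix(dims, nrow(path), 3, byrow = TRUE))
  inside <- mask$data[cbind(vi[, 1], vi[, 2], vi[, 3])]
  if (!all(inside))
    stop("path leaves the mask foreground", call. = FALSE)

  s <- polyline_arcpos(path)
  L <- s[length(s)]
  samp_s <- seq(0, L, by = step_mm)
  samp_pts <- t(vapply(samp_s, function(si) {
    j <- findInterval(si, s, rightmost.closed = TRUE)
    j <- min(max(j, 1), nrow(path) - 1)
    f <- (si - s[j]) / max(s[j + 1] - s[j], 1e-12)
    path[j, ] * (1 - f) + path[j + 1, ] * f
  }, numeric(3)))
  tg <- polyline_tangents(path)
  samp_tg <- t(vapply(samp_s, function(si) {
    j <- findInterval(si, s, rightmost.closed = TRUE)
    unitv(tg[min(max(j, 1), nrow(path)), ])
  }, numeric(3)))

  interp <- function(pts) cpp_trilinear(field, dim(field), sp, sorig, pts)

  thetas <- seq(0, pi, length.out = n_theta + 1)[seq_len(n_theta)]
  out <- vector("list", length(samp_s))
  r_step <- 0.25 * min(sp)
  r_max <- pad - 2
  for (i in seq_along(samp_s)) {
    p <- samp_pts[i, ]
    tgi <- samp_tg[i, ]
    u <- reject_from(c(1, 0, 0), tgi)
    if (vnorm(u) < 1e-6) u <- reject_from(c(0, 1, 0), tgi)
    u <- unitv(u)
    v <- vcross(tgi, u)
    dirs <- t(vapply(thetas, function(a) cos(a) * u + sin(a) * v, numeric(3)))
    dirs <- rbind(dirs, -dirs)
    radius <- apply(dirs, 1, function(d) {
      lo <- 0; hi <- r_step
      while (hi < r_max && interp(matrix(p + hi * d, 1)) >= 0.5) {
        lo <- hi; hi <- hi + r_step
      }
      for (it in 1:8) {
        mid <- (lo + hi) / 2
        if (interp(matrix(p + mid * d, 1)) >= 0.5) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    })
    # least-squares ellipse through the ray endpoints: 1/r(theta)^2 is
    # linear in (cos^2, sin^2, sin*cos), so the fit pools all rays and is
    # robust to the per-ray half-voxel noise that would bias raw
    # min/max caliper statistics
    th2 <- c(thetas, thetas + pi)
    X <- cbind(cos(th2)^2, sin(th2)^2, sin(th2) * cos(th2))
    cf <- tryCatch(solve(crossprod(X), crossprod(X, 1 / radius^2)),
                   error = function(e) NULL)
    if (!is.null(cf)) {
      M <- matrix(c(cf[1], cf[3] / 2, cf[3] / 2, cf[2]), 2)
      ev <- eigen(M, symmetric = TRUE)$values
      if (all(ev > 0)) {
        dmin <- 2 / sqrt(max(ev)); dmax <- 2 / sqrt(min(ev))
      } else cf <- NULL
    }
    if (is.null(cf)) {
      chords <- radius[seq_len(n_theta)] + radius[n_theta + seq_len(n_theta)]
      dmin <- min(chords); dmax <- max(chords)
    }
    out[[i]] <- tibble::tibble(position_mm = samp_s[i],
                               d_min_mm = dmin, d_max_mm = dmax,
                               aspect = dmin / dmax)
  }
  dplyr::bind_rows(out)
}
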