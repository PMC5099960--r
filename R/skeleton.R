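# Centreline extraction: homotopic thinning to a one-voxel-wide skeleton,
# conversion to a voxel graph, condensation into junction-to-junction
# paths, and spur pruning.

#' Skeletonize a binary lumen mask
#'
#' Thins the foreground to a one-voxel-wide 26-connected medial curve
#' skeleton by distance-ordered homotopic thinning (deepest voxels
#' survive), builds the voxel adjacency graph, collapses it into
#' junction-to-junction paths and removes spur branches shorter than
#' `prune_mm` (default 2 mm, safely below the shortest true branch so no
#' real branch is ever pruned).  If the foreground has several connected
#' components, the largest is used with a warning.
#'
#' @param mask A [voxel_mask()].
#' @param prune_mm Spur-pruning length threshold in mm.
#' @return A `centerline_graph`: list with `nodes` (tibble: `voxel` linear
#'   index, `x`, `y`, `z` in mm, `degree`, `kind` =
#'   endpoint/junction/slab), `paths` (list of condensed paths, each a
#'   tibble of ordered voxel rows), `spacing_mm`, `origin_mm`, `dim`.
#' @export
skeletonize_mask <- function(mask, prune_mm = 2) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$data)) stop("mask has empty foreground", call. = FALSE)
  edt <- cpp_edt(as.logical(mask$data), dim(mask$data), mask$spacing_mm)
  sk <- cpp_thin(as.logical(mask$data), dim(mask$data), mask$spacing_mm, edt)
  sk <- array(sk, dim(mask$data))
  g <- voxel_graph(sk, mask$spacing_mm, mask$origin_mm)
  g$nodes$edt <- edt[g$nodes$voxel]
  g$edt_field <- edt

  comp <- graph_components(g)
  if (max(comp) > 1) {
    keep <- which.max(tabulate(comp))
    warning(sprintf("foreground has %d connected components; using the largest",
                    max(comp)), call. = FALSE)
    g <- subset_graph(g, comp == keep)
  }
  ef <- g$edt_field
  g <- prune_spurs(g, prune_mm)
  g$edt_field <- ef
  g$dim <- dim(mask$data)
  g
}

# Build the voxel-level skeleton graph: nodes with coordinates and 26-adjacency.
voxel_graph <- function(sk, spacing, origin) {
  idx <- which(sk)
  n <- length(idx)
  if (!n) stop("skeleton is empty", call. = FALSE)
  dims <- dim(sk)
  lab <- array(0L, dims)
  lab[idx] <- seq_len(n)
  ijk <- arrayInd(idx, dims)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs[k, 1]
    nj <- ijk[, 2] + offs[k, 2]
    nk <- ijk[, 3] + offs[k, 3]
    ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
      nk >= 1 & nk <= dims[3]
    if (!any(ok)) next
    nl <- lab[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- nl > 0
    from <- c(from, which(ok)[hit])
    to <- c(to, nl[hit])
  }
  keep <- from < to
  edges <- cbind(from[keep], to[keep])

  adj <- vector("list", n)
  if (nrow(edges)) {
    sp1 <- split(edges[, 2], edges[, 1])
    sp2 <- split(edges[, 1], edges[, 2])
    for (nm in names(sp1)) adj[[as.integer(nm)]] <- c(adj[[as.integer(nm)]], sp1[[nm]])
    for (nm in names(sp2)) adj[[as.integer(nm)]] <- c(adj[[as.integer(nm)]], sp2[[nm]])
  }
  deg <- lengths(adj)
  xyz <- sweep(sweep(ijk - 1, 2, spacing, `*`), 2, origin, `+`)
  list(
    nodes = tibble::tibble(
      voxel = idx, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      degree = as.integer(deg),
      kind = ifelse(deg >= 3, "junction", ifelse(deg == 1, "endpoint", "slab"))
    ),
    adj = adj,
    spacing_mm = spacing,
    origin_mm = origin
  )
}

graph_components <- function(g) {
  n <- nrow(g$nodes)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      nb <- g$adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      stack <- c(stack, new)
    }
  }
  comp
}

subset_graph <- function(g, keep) {
  map <- integer(length(keep))
  map[keep] <- seq_len(sum(keep))
  adj <- lapply(g$adj[keep], function(nb) map[nb[keep[nb]]])
  deg <- lengths(adj)
  nodes <- g$nodes[keep, ]
  nodes$degree <- as.integer(deg)
  nodes$kind <- ifelse(deg >= 3, "junction", ifelse(deg == 1, "endpoint", "slab"))
  list(nodes = nodes, adj = adj, spacing_mm = g$spacing_mm,
       origin_mm = g$origin_mm)
}

node_xyz <- function(g, i) as.matrix(g$nodes[i, c("x", "y", "z")])

# Condense a voxel graph into junction-cluster / endpoint vertices joined
# by paths of slab voxels.  Returns list(vertices, vpaths):
#   vertices: tibble(vid, kind, x, y, z, members = list of voxel rows)
#   vpaths:   tibble(from_vid, to_vid, length_mm, rows = list of voxel rows
#             interior to the path, ordered from->to)
condense_graph <- function(g) {
  deg <- g$nodes$degree
  n <- length(deg)
  is_j <- deg >= 3

  # junction clusters: 26-connected components of junction voxels
  cl <- integer(n)
  cur <- 0L
  for (s in which(is_j)) {
    if (cl[s]) next
    cur <- cur + 1L
    stack <- s; cl[s] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      nb <- g$adj[[v]]
      new <- nb[is_j[nb] & cl[nb] == 0L]
      cl[new] <- cur
      stack <- c(stack, new)
    }
  }
  n_cl <- cur
  verts <- list()
  for (k in seq_len(n_cl)) {
    rows <- which(cl == k)
    verts[[k]] <- tibble::tibble(
      vid = k, kind = "junction",
      x = mean(g$nodes$x[rows]), y = mean(g$nodes$y[rows]),
      z = mean(g$nodes$z[rows]), members = list(rows))
  }
  ep <- which(deg == 1)
  vid_of <- integer(n)
  vid_of[is_j] <- cl[is_j]
  for (e in ep) {
    cur <- cur + 1L
    vid_of[e] <- cur
    verts[[cur]] <- tibble::tibble(
      vid = cur, kind = "endpoint",
      x = g$nodes$x[e], y = g$nodes$y[e], z = g$nodes$z[e],
      members = list(e))
  }
  # isolated voxels (degree 0) become their own endpoint vertices
  for (e in which(deg == 0)) {
    cur <- cur + 1L
    vid_of[e] <- cur
    verts[[cur]] <- tibble::tibble(
      vid = cur, kind = "endpoint",
      x = g$nodes$x[e], y = g$nodes$y[e], z = g$nodes$z[e],
      members = list(e))
  }
  vertices <- dplyr::bind_rows(verts)

  # trace paths: start at every terminal voxel of every vertex, walk slabs
  used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  paths <- list()
  seeds <- which(vid_of > 0 & deg > 0)
  for (s in seeds) {
    for (nb in g$adj[[s]]) {
      k <- ekey(s, nb)
      if (!is.null(used[[k]])) next
      if (vid_of[nb] > 0 && vid_of[nb] == vid_of[s]) { used[[k]] <- TRUE; next }
      used[[k]] <- TRUE
      rows <- integer(0)
      prev <- s
      curv <- nb
      while (vid_of[curv] == 0L) {
        rows <- c(rows, curv)
        nxt <- setdiff(g$adj[[curv]], prev)
        # slab voxels can touch two path voxels diagonally; take the first
        # unused edge deterministically
        nxt_ok <- nxt[vapply(nxt, function(x) is.null(used[[ekey(curv, x)]]),
                             logical(1))]
        if (!length(nxt_ok)) break
        nxt1 <- nxt_ok[1]
        used[[ekey(curv, nxt1)]] <- TRUE
        prev <- curv
        curv <- nxt1
      }
      if (vid_of[curv] == 0L) next  # dangling (shouldn't happen after thinning)
      pts <- rbind(
        c(vertices$x[vid_of[s]], vertices$y[vid_of[s]], vertices$z[vid_of[s]]),
        as.matrix(g$nodes[rows, c("x", "y", "z")]),
        c(vertices$x[vid_of[curv]], vertices$y[vid_of[curv]],
          vertices$z[vid_of[curv]]))
      paths[[length(paths) + 1]] <- tibble::tibble(
        from_vid = vid_of[s], to_vid = vid_of[curv],
        length_mm = polyline_length(pts), rows = list(rows))
    }
  }
  vpaths <- if (length(paths)) dplyr::bind_rows(paths)
  else tibble::tibble(from_vid = integer(), to_vid = integer(),
                      length_mm = numeric(), rows = list())
  list(vertices = vertices, vpaths = vpaths)
}

# Iteratively clean the condensed graph:
#   (a) remove spur leaf paths -- thinning artefacts of the medial surface
#       at fat junctions.  A leaf path is a spur when it is short relative
#       to the junction's inscribed radius AND its distal half never
#       approaches a wall (its minimum EDT stays comparable to the
#       junction radius); a true branch is either long or gets thin.
#   (b) contract junction-junction paths shorter than the prune length:
#       split junction clusters belonging to one bifurcation.
prune_condensed <- function(cg, prune_mm, vertex_edt = NULL, node_edt = NULL) {
  if (is.null(vertex_edt)) vertex_edt <- setNames(rep(0, nrow(cg$vertices)),
                                                  cg$vertices$vid)
  path_min_distal_edt <- function(rows, endpoint_last) {
    if (is.null(node_edt) || !length(rows)) return(Inf)
    half <- if (endpoint_last) rows[seq(ceiling(length(rows) / 2), length(rows))]
    else rows[seq_len(ceiling(length(rows) / 2))]
    min(node_edt[half])
  }
  repeat {
    changed <- FALSE
    vp <- cg$vpaths
    if (!nrow(vp)) break
    vdeg <- table(factor(c(vp$from_vid, vp$to_vid), levels = cg$vertices$vid))
    endp <- cg$vertices$vid[cg$vertices$kind == "endpoint"]
    at_junction <- function(v) vdeg[as.character(v)] >= 3

    ## (a) spurs
    is_spur <- logical(nrow(vp))
    for (i in seq_len(nrow(vp))) {
      ep_last <- vp$to_vid[i] %in% endp
      ep_first <- vp$from_vid[i] %in% endp
      if (ep_last == ep_first) next
      jv <- if (ep_last) vp$from_vid[i] else vp$to_vid[i]
      if (!at_junction(jv)) next
      ej <- vertex_edt[as.character(jv)]
      short <- vp$length_mm[i] < max(prune_mm, ej + prune_mm)
      fat_short <- vp$length_mm[i] < ej + 2 * prune_mm &&
        path_min_distal_edt(vp$rows[[i]], ep_last) > 0.7 * ej
      is_spur[i] <- short || fat_short
    }
    if (any(is_spur)) {
      cg$vpaths <- vp[!is_spur, ]
      changed <- TRUE
    }

    ## (b) contract short internal junction-junction paths
    vp <- cg$vpaths
    vdeg <- table(factor(c(vp$from_vid, vp$to_vid), levels = cg$vertices$vid))
    jset <- cg$vertices$vid[cg$vertices$kind == "junction"]
    contract_thr <- pmax(prune_mm,
                         0.5 * pmin(vertex_edt[as.character(vp$from_vid)],
                                    vertex_edt[as.character(vp$to_vid)]))
    internal_short <- which(
      vp$from_vid %in% jset & vp$to_vid %in% jset &
        vp$from_vid != vp$to_vid & vp$length_mm < contract_thr &
        vdeg[as.character(vp$from_vid)] >= 3 & vdeg[as.character(vp$to_vid)] >= 3)
    if (length(internal_short)) {
      i <- internal_short[1]
      a <- vp$from_vid[i]; b <- vp$to_vid[i]
      ia <- which(cg$vertices$vid == a); ib <- which(cg$vertices$vid == b)
      mem <- c(cg$vertices$members[[ia]], cg$vertices$members[[ib]],
               vp$rows[[i]])
      cg$vertices$members[[ia]] <- mem
      na <- length(cg$vertices$members[[ia]])
      cg$vertices$x[ia] <- mean(c(cg$vertices$x[c(ia, ib)]))
      cg$vertices$y[ia] <- mean(c(cg$vertices$y[c(ia, ib)]))
      cg$vertices$z[ia] <- mean(c(cg$vertices$z[c(ia, ib)]))
      vertex_edt[as.character(a)] <- max(vertex_edt[as.character(c(a, b))])
      vp <- vp[-i, ]
      vp$from_vid[vp$from_vid == b] <- a
      vp$to_vid[vp$to_vid == b] <- a
      vp <- vp[vp$from_vid != vp$to_vid, ]
      cg$vpaths <- vp
      cg$vertices <- cg$vertices[-ib, ]
      changed <- TRUE
    }
    if (!changed) break
  }
  # dissolve junction vertices of degree 2
  repeat {
    vp <- cg$vpaths
    vdeg <- table(factor(c(vp$from_vid, vp$to_vid), levels = cg$vertices$vid))
    deg2 <- cg$vertices$vid[cg$vertices$kind == "junction" &
                              vdeg[as.character(cg$vertices$vid)] == 2]
    if (!length(deg2)) break
    v <- deg2[1]
    inc <- which(vp$from_vid == v | vp$to_vid == v)
    if (length(inc) != 2) break
    p1 <- vp[inc[1], ]; p2 <- vp[inc[2], ]
    orient <- function(p, endv) {  # rows ordered so the path ENDS at endv
      if (p$to_vid == endv) p$rows[[1]] else rev(p$rows[[1]])
    }
    a <- if (p1$from_vid == v) p1$to_vid else p1$from_vid
    b <- if (p2$from_vid == v) p2$to_vid else p2$from_vid
    vrow <- which(cg$vertices$vid == v)
    newrows <- c(orient(p1, v), cg$vertices$members[[vrow]],
                 rev(orient(p2, v)))
    cg$vpaths <- vp[-inc, ]
    cg$vpaths <- dplyr::bind_rows(cg$vpaths, tibble::tibble(
      from_vid = a, to_vid = b, length_mm = p1$length_mm + p2$length_mm,
      rows = list(newrows)))
  }
  cg
}

# Public wrapper used by skeletonize_mask: prune on the condensed form and
# rebuild the voxel-level graph view.
prune_spurs <- function(g, prune_mm) {
  cg <- condense_graph(g)
  vertex_edt <- vapply(seq_len(nrow(cg$vertices)), function(i) {
    rows <- cg$vertices$members[[i]]
    if (!length(rows) || is.null(g$nodes$edt)) 0 else max(g$nodes$edt[rows])
  }, numeric(1))
  names(vertex_edt) <- cg$vertices$vid
  cg$vertices$edt <- vertex_edt
  cg <- prune_condensed(cg, prune_mm, vertex_edt, node_edt = g$nodes$edt)
  keep_rows <- sort(unique(c(
    unlist(cg$vpaths$rows),
    unlist(cg$vertices$members[cg$vertices$vid %in%
                                 c(cg$vpaths$from_vid, cg$vpaths$to_vid)])
  )))
  if (!length(keep_rows)) keep_rows <- seq_len(nrow(g$nodes))  # single path fallback
  keep <- seq_len(nrow(g$nodes)) %in% keep_rows
  g2 <- subset_graph(g, keep)
  g2$condensed <- recondense_after_subset(cg, keep)
  g2
}

# Map condensed row indices through the subset; vertex coordinates are kept.
recondense_after_subset <- function(cg, keep) {
  map <- integer(length(keep))
  map[keep] <- seq_len(sum(keep))
  cg$vpaths$rows <- lapply(cg$vpaths$rows, function(r) map[r])
  cg$vertices$members <- lapply(cg$vertices$members, function(r) {
    r2 <- map[r[keep[r]]]
    r2
  })
  cg
}
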