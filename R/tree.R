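#' Construct a single airway branch
#'
#' A branch is one airway segment between two branching events (or between
#' a branching event and a terminal end): a 3-D centreline polyline plus a
#' representative lumen diameter.  Branches are assembled into an
#' [airway_tree()].
#'
#' @param id Branch identifier (character scalar, unique within a tree).
#' @param parent_id Identifier of the parent branch, or `NA` for the root.
#' @param child_ids Character vector of child identifiers (major daughter
#'   first by convention); may be empty for terminal branches.
#' @param centerline Numeric matrix (n x 3, n >= 2) of points in mm.
#' @param diameter_mm Representative lumen diameter in mm (conventionally
#'   the median of the diameter profile over the middle 60 % of the branch,
#'   i.e. away from the transition zones at either end).
#' @param generation Non-negative integer airway generation (trachea = 0),
#'   or `NA` if not yet assigned.
#' @param role_tag One of `"trachea"`, `"tracheal_bronchus"`,
#'   `"right_mainstem"`, `"left_mainstem"`, `"other"`.
#' @param meta Optional named list of per-branch metadata (e.g. generator
#'   ground truth).
#'
#' @return A list of class `airway_branch`; `length_mm` is computed as the
#'   arc length of the centreline.
#' @export
airway_branch <- function(id, parent_id = NA_character_, child_ids = character(),
                          centerline, diameter_mm, generation = NA_integer_,
                          role_tag = "other", meta = list()) {
  centerline <- as.matrix(centerline)
  storage.mode(centerline) <- "double"
  dimnames(centerline) <- NULL
  structure(list(
    id = as.character(id),
    parent_id = as.character(parent_id),
    child_ids = as.character(child_ids),
    centerline = centerline,
    diameter_mm = as.numeric(diameter_mm),
    length_mm = polyline_length(centerline),
    generation = as.integer(generation),
    role_tag = as.character(role_tag),
    meta = meta
  ), class = "airway_branch")
}

branch_roles <- c("trachea", "tracheal_bronchus", "right_mainstem",
                  "left_mainstem", "other")

#' Construct an airway tree
#'
#' The central container of the package: a rooted binary tree of airway
#' branches with 3-D centrelines, plus the anatomical reference plane (the
#' plane of the trachea and the two mainstem bronchi) against which
#' bifurcating-plane rotations are measured.
#'
#' The trachea may branch twice (tracheal bronchus before the main carina);
#' it is modelled as two stacked generation-0 segments so that every
#' branching event remains a strict bifurcation.
#'
#' @param branches List of [airway_branch()] objects.
#' @param root_id Identifier of the root branch (the proximal trachea).
#' @param reference_plane List with unit `normal` and `point` (mm) defining
#'   the trachea--mainstem plane.  Defaults to the x--z plane.
#' @param frame Named list of axis-convention metadata.
#'
#' @return An object of class `airway_tree`.
#' @seealso [validate_tree()], [branch_table()], [generate_tree()]
#' @export
airway_tree <- function(branches, root_id,
                        reference_plane = list(normal = c(0, 1, 0),
                                               point = c(0, 0, 0)),
                        frame = list(units = "mm", handedness = "right",
                                     trachea_axis = c(0, 0, -1))) {
  names(branches) <- vapply(branches, function(b) b$id, character(1))
  structure(list(
    branches = branches,
    root_id = as.character(root_id),
    reference_plane = reference_plane,
    frame = frame
  ), class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  nb <- length(x$branches)
  d <- vapply(x$branches, function(b) b$diameter_mm, numeric(1))
  cat(sprintf("<airway_tree> %d branches, root '%s'\n", nb, x$root_id))
  cat(sprintf("  diameters %.2f-%.2f mm, total length %.0f mm\n",
              min(d), max(d),
              sum(vapply(x$branches, function(b) b$length_mm, numeric(1)))))
  invisible(x)
}

n_branches <- function(tree) length(tree$branches)

tree_children <- function(tree, id) tree$branches[[id]]$child_ids

#' Tangent direction of a branch at one end
#'
#' Fits a straight line (first principal axis) to the proximal or distal
#' portion of the centreline and orients it in the flow direction (root to
#' periphery).  Used for bifurcation-angle measurement.
#'
#' @param branch An [airway_branch()].
#' @param end `"proximal"` or `"distal"`.
#' @param frac Fraction of the arc length used for the fit (default 0.3).
#' @param skip_mm Arc length to exclude at the chosen end before fitting
#'   (used on measured trees to step over the junction region, where the
#'   medial skeleton bends inside the parent lumen).
#' @return Unit 3-vector.
#' @export
branch_direction <- function(branch, end = c("distal", "proximal"),
                             frac = 0.3, skip_mm = 0) {
  end <- match.arg(end)
  p <- branch$centerline
  s <- polyline_arcpos(p)
  L <- s[length(s)]
  w <- max(frac * L, 1e-6)
  if (end == "proximal") {
    keep <- s >= skip_mm & s <= min(skip_mm + w, 0.9 * L)
  } else {
    keep <- s <= (L - skip_mm) & s >= max(L - skip_mm - w, 0.1 * L)
  }
  if (sum(keep) < 2) {  # fall back to the whole line
    keep <- rep(TRUE, nrow(p))
  }
  pca_direction(p[keep, , drop = FALSE])
}

#' Validate the structural invariants of an airway tree
#'
#' Checks the tree without modifying it and reports every violation as one
#' row: positive diameters and lengths, centreline consistency, a single
#' trachea root, parent/child link symmetry, acyclicity/connectedness,
#' binary branching at internal nodes, and monotone generations.
#'
#' @param tree An [airway_tree()].
#' @return A tibble with columns `branch_id`, `rule`, `message`; zero rows
#'   if and only if the tree is valid.
#' @export
validate_tree <- function(tree) {
  out <- list()
  bad <- function(id, rule, msg) {
    out[[length(out) + 1]] <<- tibble::tibble(branch_id = id, rule = rule,
                                              message = msg)
  }
  br <- tree$branches
  ids <- names(br)

  for (b in br) {
    if (!is.finite(b$diameter_mm) || b$diameter_mm <= 0)
      bad(b$id, "positive_diameter", "diameter_mm must be > 0")
    if (nrow(b$centerline) < 2)
      bad(b$id, "centerline_points", "centerline needs >= 2 points")
    else {
      if (b$length_mm <= 0)
        bad(b$id, "positive_length", "length_mm must be > 0")
      if (abs(b$length_mm - polyline_length(b$centerline)) > 1e-6)
        bad(b$id, "length_consistency",
            "length_mm must equal centerline arc length within 1e-6 mm")
    }
    if (!b$role_tag %in% branch_roles)
      bad(b$id, "role_tag", paste("unknown role_tag", b$role_tag))
    nch <- length(b$child_ids)
    if (nch != 0 && nch != 2)
      bad(b$id, "internal_degree",
          sprintf("internal branches must have exactly 2 children (has %d)", nch))
  }

  roots <- ids[vapply(br, function(b) is.na(b$parent_id), logical(1))]
  if (length(roots) != 1) {
    bad(paste(roots, collapse = ","), "multiple_roots",
        sprintf("expected exactly 1 root, found %d", length(roots)))
  } else {
    if (roots != tree$root_id)
      bad(roots, "root_id", "root_id does not point at the parentless branch")
    if (br[[roots]]$role_tag != "trachea")
      bad(roots, "root_role", "root branch must be tagged trachea")
  }

  for (b in br) {
    for (cid in b$child_ids) {
      if (!cid %in% ids) {
        bad(b$id, "missing_child", paste("child", cid, "not in tree"))
      } else if (!identical(br[[cid]]$parent_id, b$id)) {
        bad(cid, "parent_link", "child's parent_id does not match")
      }
    }
    if (!is.na(b$parent_id) && !b$parent_id %in% ids)
      bad(b$id, "missing_parent", paste("parent", b$parent_id, "not in tree"))
  }

  # reachability from root (acyclic + connected given the link checks)
  if (length(roots) == 1) {
    seen <- character()
    queue <- roots
    while (length(queue)) {
      id <- queue[[1]]; queue <- queue[-1]
      if (id %in% seen) { bad(id, "cycle", "branch reachable twice"); break }
      seen <- c(seen, id)
      queue <- c(queue, intersect(br[[id]]$child_ids, ids))
    }
    orphan <- setdiff(ids, seen)
    for (id in orphan) bad(id, "unreachable", "branch not reachable from root")
  }

  for (b in br) {
    if (!is.na(b$parent_id) && b$parent_id %in% ids) {
      pg <- br[[b$parent_id]]$generation
      if (!is.na(b$generation) && !is.na(pg) && b$generation < pg)
        bad(b$id, "generation_order",
            "child generation must be >= parent generation")
    }
  }

  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(branch_id = character(), rule = character(),
                      message = character())
}

#' Tabulate the branches of a tree
#'
#' @param tree An [airway_tree()].
#' @return A tibble with one row per branch: `id`, `parent_id`,
#'   `generation`, `diameter_mm`, `length_mm`, `role_tag`.
#' @export
branch_table <- function(tree) {
  br <- tree$branches
  tibble::tibble(
    id = unname(vapply(br, function(b) b$id, character(1))),
    parent_id = unname(vapply(br, function(b) b$parent_id, character(1))),
    generation = unname(vapply(br, function(b) as.integer(b$generation),
                               integer(1))),
    diameter_mm = unname(vapply(br, function(b) b$diameter_mm, numeric(1))),
    length_mm = unname(vapply(br, function(b) b$length_mm, numeric(1))),
    role_tag = unname(vapply(br, function(b) b$role_tag, character(1)))
  )
}

#' Apply a rigid transform (rotation + translation) to a tree
#'
#' Rotates every centreline point and the reference plane; used mainly for
#' invariance testing of the angle measurements.
#'
#' @param tree An [airway_tree()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 offset in mm.
#' @return The transformed tree.
#' @export
transform_tree <- function(tree, rotation = diag(3), translation = c(0, 0, 0)) {
  tree$branches <- lapply(tree$branches, function(b) {
    b$centerline <- sweep(b$centerline %*% t(rotation), 2, -translation)
    if (!is.null(b$meta$ellipse_axis))
      b$meta$ellipse_axis <- as.numeric(rotation %*% b$meta$ellipse_axis)
    b
  })
  rp <- tree$reference_plane
  rp$normal <- as.numeric(rotation %*% rp$normal)
  rp$point <- as.numeric(rotation %*% rp$point) + translation
  tree$reference_plane <- rp
  tree
}
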