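#' Assign airway generations by diameter sorting with a tolerance
#'
#' Reproduces the cast-measurement labelling rule: the trachea is
#' generation 0; all other branches are sorted by diameter in descending
#' order and grouped greedily -- a new group starts at the largest
#' ungrouped branch and every branch within `tol_mm` of that group leader
#' joins it; groups are numbered 1, 2, ... downwards.  Finally each
#' branch's generation is clamped to be at least its parent's, so
#' generations never decrease towards the periphery.  The tolerance
#' mirrors the diameter-measurement uncertainty (0.3 mm).
#'
#' Both stacked trachea segments (role `"trachea"`) are assigned
#' generation 0 and excluded from the grouping.
#'
#' @param tree An [airway_tree()] with all diameters set.
#' @param tol_mm Grouping tolerance in mm (default 0.3).
#' @return A copy of the tree with `generation` set on every branch.
#' @export
assign_generations <- function(tree, tol_mm = 0.3) {
  stopifnot(tol_mm >= 0)
  br <- tree$branches
  d <- vapply(br, function(b) b$diameter_mm, numeric(1))
  if (any(!is.finite(d) | d <= 0)) {
    bad <- names(d)[!is.finite(d) | d <= 0][1]
    stop("branch '", bad, "' has an unset or non-positive diameter",
         call. = FALSE)
  }
  is_trachea <- vapply(br, function(b) b$role_tag == "trachea", logical(1))

  gen <- setNames(rep(NA_integer_, length(br)), names(br))
  gen[is_trachea] <- 0L

  rest <- sort(d[!is_trachea], decreasing = TRUE)
  ids <- names(rest)
  g <- 0L
  i <- 1L
  while (i <= length(ids)) {
    g <- g + 1L
    leader <- rest[i]
    member <- which(rest <= leader & rest >= leader - tol_mm)
    member <- member[member >= i]
    gen[ids[member]] <- g
    i <- max(member) + 1L
  }

  # clamp children to >= parent generation, root-down
  order_ids <- character()
  queue <- tree$root_id
  while (length(queue)) {
    id <- queue[[1]]; queue <- queue[-1]
    order_ids <- c(order_ids, id)
    queue <- c(queue, br[[id]]$child_ids)
  }
  for (id in order_ids) {
    pid <- br[[id]]$parent_id
    if (!is.na(pid)) gen[id] <- max(gen[id], gen[pid])
  }

  for (id in names(br)) tree$branches[[id]]$generation <- gen[[id]]
  tree
}

#' Measure the geometry of every bifurcation in a tree
#'
#' For each internal branch with two daughters: the major daughter is the
#' larger-diameter one (ties broken by branch id); `angle1`/`angle2` are
#' the angles between the parent's distal direction and the major/minor
#' daughter's proximal direction; the bifurcating plane is spanned by the
#' parent and minor-daughter directions, and its signed rotation relative
#' to the tree's reference plane (folded to \[-90, 90\] degrees)
#' classifies the bifurcation as in-plane (|rotation| below the threshold)
#' or out-of-plane with the rotation's sign.
#'
#' @param tree An [airway_tree()] with its reference plane set.
#' @param planarity_threshold_deg Classification threshold (default 45;
#'   measured rotations cluster near 0 and +/-90, so the classifier is
#'   insensitive to the exact value).
#' @param direction_frac Fraction of each branch used for the
#'   direction fits (see [branch_direction()]).
#' @param junction_skip_factor Arc length (in units of the local branch
#'   radius) excluded next to each junction before fitting directions;
#'   keep 0 for exact synthetic trees, use about 0.7 for trees measured
#'   from voxel masks, where the skeleton bends inside the parent lumen.
#'
#' @return A tibble with one row per bifurcation: `parent_id`, `major_id`,
#'   `minor_id`, `generation` (parent's), `D_mm`, `d1_mm`, `d2_mm`,
#'   `d1_ratio`, `d2_ratio`, `angle1_deg`, `angle2_deg`,
#'   `plane_rotation_deg`, `planarity`, `minor_role`.
#' @export
compute_bifurcations <- function(tree, planarity_threshold_deg = 45,
                                 direction_frac = 0.3,
                                 junction_skip_factor = 0) {
  br <- tree$branches
  ref_normal <- unitv(tree$reference_plane$normal)
  rows <- list()
  for (b in br) {
    nch <- length(b$child_ids)
    if (nch == 0) next
    if (nch != 2)
      stop("branch '", b$id, "' has ", nch,
           " children; bifurcation geometry requires exactly 2", call. = FALSE)
    c1 <- br[[b$child_ids[1]]]
    c2 <- br[[b$child_ids[2]]]
    if (c1$diameter_mm < c2$diameter_mm ||
        (c1$diameter_mm == c2$diameter_mm && c2$id < c1$id)) {
      tmp <- c1; c1 <- c2; c2 <- tmp
    }
    # Skip events involving virtual stub segments (binary resolutions of
    # junction clusters): their geometry is a modelling device, not a
    # measurable bifurcation.
    if (isTRUE(b$meta$virtual) || isTRUE(c1$meta$virtual) ||
        isTRUE(c2$meta$virtual)) next
    # On measured trees (junction_skip_factor > 0) the centrelines bend
    # inside the junction-fusion region, so a daughter's direction is
    # fitted to the first locally straight window beyond the point where
    # its centreline leaves the parent lumen (radial distance from the
    # parent's distal axis above junction_skip_factor * parent radius);
    # on exact trees the plain proximal/distal line fits are used.
    if (junction_skip_factor > 0) {
      p_dir <- stable_end_direction(b$centerline, "distal")
      r_p <- b$diameter_mm / 2
      J <- b$centerline[nrow(b$centerline), ]
      daughter_dir <- function(ch) {
        cl <- ch$centerline
        rel <- sweep(cl, 2, J)
        radial <- sqrt(pmax(rowSums(rel^2) - as.numeric(rel %*% p_dir)^2, 0))
        hit <- which(radial > junction_skip_factor * r_p)
        if (length(hit) && nrow(cl) - hit[1] + 1 >= 6) {
          stable_end_direction(cl[hit[1]:nrow(cl), , drop = FALSE],
                               "proximal")
        } else {
          stable_end_direction(cl, "proximal")
        }
      }
      d1_dir <- daughter_dir(c1)
      d2_dir <- daughter_dir(c2)
    } else {
      p_dir <- branch_direction(b, "distal", frac = direction_frac)
      d1_dir <- branch_direction(c1, "proximal", frac = direction_frac)
      d2_dir <- branch_direction(c2, "proximal", frac = direction_frac)
    }
    rot <- signed_plane_rotation(p_dir, d2_dir, ref_normal)
    planarity <- if (is.na(rot)) NA_character_
    else if (abs(rot) < planarity_threshold_deg) "in_plane"
    else if (rot >= 0) "out_of_plane_pos" else "out_of_plane_neg"
    rows[[length(rows) + 1]] <- tibble::tibble(
      parent_id = b$id, major_id = c1$id, minor_id = c2$id,
      generation = as.integer(b$generation),
      D_mm = b$diameter_mm, d1_mm = c1$diameter_mm, d2_mm = c2$diameter_mm,
      d1_ratio = c1$diameter_mm / b$diameter_mm,
      d2_ratio = c2$diameter_mm / b$diameter_mm,
      angle1_deg = angle_between(p_dir, d1_dir),
      angle2_deg = angle_between(p_dir, d2_dir),
      plane_rotation_deg = rot,
      planarity = planarity,
      minor_role = c2$role_tag
    )
  }
  if (!length(rows))
    return(tibble::tibble(parent_id = character(), major_id = character(),
                          minor_id = character(), generation = integer(),
                          D_mm = numeric(), d1_mm = numeric(), d2_mm = numeric(),
                          d1_ratio = numeric(), d2_ratio = numeric(),
                          angle1_deg = numeric(), angle2_deg = numeric(),
                          plane_rotation_deg = numeric(),
                          planarity = character(), minor_role = character()))
  dplyr::bind_rows(rows)
}

#' Bifurcating-plane rotation series along a monopodial pathway
#'
#' Follows major daughters (larger diameter, ties by id) from a mainstem
#' bronchus towards the periphery and reports the signed rotation of each
#' successive bifurcating plane relative to the reference plane, in order
#' from the carina.
#'
#' @param tree An [airway_tree()].
#' @param pathway Branch id to start from, or one of `"right_mainstem"`,
#'   `"left_mainstem"` (resolved through the role tags).
#' @inheritParams compute_bifurcations
#' @return A tibble with columns `index` (1 = first bifurcation beyond the
#'   start branch), `parent_id`, `rotation_deg`, `planarity`; zero rows if
#'   the pathway has no bifurcation.
#' @export
plane_rotation_series <- function(tree, pathway = "right_mainstem",
                                  planarity_threshold_deg = 45) {
  br <- tree$branches
  if (pathway %in% c("right_mainstem", "left_mainstem")) {
    hit <- names(br)[vapply(br, function(b) b$role_tag == pathway, logical(1))]
    if (!length(hit))
      stop("tree has no branch with role '", pathway, "'", call. = FALSE)
    pathway <- hit[1]
  }
  if (!pathway %in% names(br))
    stop("no branch with id '", pathway, "'", call. = FALSE)

  recs <- compute_bifurcations(tree, planarity_threshold_deg)
  out <- list()
  id <- pathway
  k <- 0L
  while (length(br[[id]]$child_ids) == 2) {
    rec <- recs[recs$parent_id == id, ]
    k <- k + 1L
    out[[k]] <- tibble::tibble(index = k, parent_id = id,
                               rotation_deg = rec$plane_rotation_deg,
                               planarity = rec$planarity)
    id <- rec$major_id
  }
  if (!length(out))
    return(tibble::tibble(index = integer(), parent_id = character(),
                          rotation_deg = numeric(), planarity = character()))
  dplyr::bind_rows(out)
}

#' Class-stratified summary of bifurcation morphometry
#'
#' Means and 95 % Student-t confidence intervals of `angle1`, `angle2`,
#' `d1/D` and `d2/D`, stratified by planarity class (out-of-plane pooled
#' over both rotation signs), plus the pooled `d1/D` over all bifurcations
#' and, when a tree with generations is supplied, per-generation diameter
#' and length tables.
#'
#' The pre-carinal tracheal-bronchus event is excluded by default: there
#' the trachea continues undiminished (d1/D = 1), which is a feature of
#' that special structure rather than of ordinary airway bifurcations.
#'
#' @param records Bifurcation tibble from [compute_bifurcations()].
#' @param tree Optional [airway_tree()] for the per-generation tables.
#' @param conf_level Confidence level (default 0.95).
#' @param exclude_tracheal_bronchus Drop records whose minor daughter is
#'   the tracheal bronchus (default `TRUE`).
#'
#' @return An object of class `morphometry_summary`: list with
#'   `$by_class` (tibble: class, n, mean and CI half-width of each
#'   quantity), `$pooled_d1_ratio`, `$n_bifurcations`, and
#'   `$by_generation` (tibble or `NULL`).
#' @export
summarize_morphometry <- function(records, tree = NULL, conf_level = 0.95,
                                  exclude_tracheal_bronchus = TRUE) {
  if (!nrow(records)) stop("no bifurcation records to summarise", call. = FALSE)
  if (exclude_tracheal_bronchus)
    records <- records[records$minor_role != "tracheal_bronchus", ]
  records <- records[!is.na(records$planarity), ]  # degenerate (parallel) events
  if (!nrow(records)) stop("no classifiable bifurcation records", call. = FALSE)
  records$class2 <- ifelse(records$planarity == "in_plane",
                           "in_plane", "out_of_plane")

  ci_half <- function(x) {
    n <- sum(is.finite(x))
    if (n < 2) return(0)
    qt(1 - (1 - conf_level) / 2, df = n - 1) * sd(x) / sqrt(n)
  }
  by_class <- records |>
    dplyr::group_by(.data$class2) |>
    dplyr::summarise(
      n = dplyr::n(),
      angle1_mean = mean(.data$angle1_deg), angle1_ci = ci_half(.data$angle1_deg),
      angle2_mean = mean(.data$angle2_deg), angle2_ci = ci_half(.data$angle2_deg),
      d1_ratio_mean = mean(.data$d1_ratio), d1_ratio_ci = ci_half(.data$d1_ratio),
      d2_ratio_mean = mean(.data$d2_ratio), d2_ratio_ci = ci_half(.data$d2_ratio),
      .groups = "drop") |>
    dplyr::rename(class = "class2")

  by_generation <- NULL
  if (!is.null(tree)) {
    tab <- branch_table(tree)
    if (!all(is.na(tab$generation))) {
      by_generation <- tab |>
        dplyr::filter(!is.na(.data$generation)) |>
        dplyr::group_by(.data$generation) |>
        dplyr::summarise(n = dplyr::n(),
                         diameter_mean_mm = mean(.data$diameter_mm),
                         length_mean_mm = mean(.data$length_mm),
                         length_min_mm = min(.data$length_mm),
                         length_max_mm = max(.data$length_mm),
                         .groups = "drop")
    }
  }

  structure(list(by_class = by_class,
                 pooled_d1_ratio = mean(records$d1_ratio),
                 n_bifurcations = nrow(records),
                 by_generation = by_generation,
                 conf_level = conf_level),
            class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf("<morphometry_summary> %d bifurcations, pooled d1/D = %.3f\n",
              x$n_bifurcations, x$pooled_d1_ratio))
  print(x$by_class)
  invisible(x)
}

#' @rdname summarize_morphometry
#' @param object A `morphometry_summary`.
#' @param ... Unused.
#' @method autoplot morphometry_summary
#' @export
autoplot.morphometry_summary <- function(object, ...) {
  long <- object$by_class |>
    tidyr::pivot_longer(cols = -c("class", "n"),
                        names_to = c("quantity", ".value"),
                        names_pattern = "(angle1|angle2|d1_ratio|d2_ratio)_(mean|ci)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$ci,
                                          ymax = .data$mean + .data$ci)) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean with 95% CI") +
    ggplot2::theme_minimal()
}

#' Fraction of a branch occupied by the transition zone
#'
#' The transition zone is the distal stretch of a parent branch where the
#' cross-section departs from circular as the lumen flares into its two
#' daughters.  Measured as the contiguous fraction of arc length, starting
#' at the distal end, over which the aspect ratio (Dmin/Dmax) stays below
#' the threshold.
#'
#' @param profile Diameter profile tibble from
#'   [measure_diameter_profile()] (columns `position_mm`, `aspect`),
#'   covering the full branch, proximal to distal.
#' @param aspect_threshold Aspect-ratio threshold (default 0.9, the lower
#'   edge of the range observed outside transition zones).
#' @return Fraction in \[0, 1\].
#' @export
transition_zone_fraction <- function(profile, aspect_threshold = 0.9) {
  profile <- as.data.frame(profile)
  stopifnot(all(c("position_mm", "aspect") %in% names(profile)))
  if (nrow(profile) < 3)
    stop("profile needs at least 3 samples", call. = FALSE)
  if (is.unsorted(profile$position_mm, strictly = TRUE))
    stop("profile positions must be strictly increasing", call. = FALSE)
  L <- max(profile$position_mm) - min(profile$position_mm)
  below <- profile$aspect < aspect_threshold
  k <- nrow(profile)
  i <- k
  while (i >= 1 && below[i]) i <- i - 1
  if (i == k) return(0)
  start <- if (i == 0) min(profile$position_mm) else profile$position_mm[i + 1]
  (max(profile$position_mm) - start) / L
}
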