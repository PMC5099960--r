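#' Parameters of the monopodial airway-tree generator
#'
#' Encodes the measured geometry of the domestic-pig bronchial tree: a
#' tracheal bronchus leaving the trachea before the main carina, monopodial
#' mainstem pathways whose major daughters continue close to the parent
#' direction, class-conditional daughter/parent diameter ratios and
#' bifurcation angles (the class being the rotation of the bifurcating
#' plane: in-plane vs. rotated +/-90 degrees out of the trachea--mainstem
#' plane), a repeating 0/+90/-90 plane-rotation schedule, elliptical
#' transition zones near bifurcations and rounded flow dividers.
#'
#' @param trachea_diameter_mm Trachea lumen diameter. The default,
#'   `10^1.3094` (about 20.39 mm), is the generation-0 value of the
#'   steep-segment log-linear diameter model.
#' @param trachea_length_mm Trachea length. Not a measured quantity;
#'   engineering default of 120 mm, configurable.
#' @param tracheal_bronchus_fraction Fraction of the trachea proximal to
#'   the tracheal-bronchus origin (the rest lies between it and the carina).
#' @param ratio_mean,ratio_sd Named numeric vectors
#'   (`in_d1`, `out_d1`, `in_d2`, `out_d2`) giving the mean and sd of the
#'   major (d1/D) and minor (d2/D) daughter/parent diameter ratios per
#'   planarity class. Defaults: means 0.88 / 0.86 / 0.57 / 0.35, sds
#'   0.03 / 0.03 / 0.05 / 0.05.
#' @param angle1_mean,angle1_sd Mean/sd (degrees) of the parent-to-major
#'   angle per class (`in_plane` 14.34, `out_of_plane` 0; sds 5).
#' @param angle2_mean,angle2_sd Mean/sd (degrees) of the parent-to-minor
#'   angle per class (`in_plane` 41.44, `out_of_plane` 41.37; sds 7).
#' @param plane_schedule Repeating pattern of scheduled bifurcating-plane
#'   rotations (degrees, entries in {0, +90, -90}) applied cyclically along
#'   every monopodial pathway. Default `c(0, 90, -90)`.
#' @param length_gen1_mm,length_gen4_mm Branch lengths decrease linearly
#'   from `length_gen1_mm` (generation 1) to `length_gen4_mm`
#'   (generation 4).
#' @param length_gen2_override_mm Generation-2 length override ("short"
#'   right-mainstem effect), default 12 mm.
#' @param length_range_mm Uniform branch-length range for generations >= 5
#'   (default 5--12 mm).
#' @param max_generation,min_diameter_mm Termination rules: no bifurcation
#'   beyond `max_generation` (default 24) and no daughter thinner than
#'   `min_diameter_mm` (default 1 mm).
#' @param transition_zone_fraction_range Fraction of the parent length,
#'   measured from the distal end, over which the cross-section turns
#'   elliptical (default 0.15--0.40).
#' @param flow_divider_radius_range_mm Rounding radius of the flow-divider
#'   edge (default 0.5--1.5 mm).
#' @param aspect_ratio_range Cross-sectional aspect ratio (Dmin/Dmax)
#'   outside the transition zone (default 0.9--0.98).
#' @param aspect_end_range Aspect ratio reached at the distal end of the
#'   transition zone, where the lumen flares into the two daughters.
#' @param left_mainstem_curvature_radius_mm Radius of the circular arc used
#'   for the left mainstem centreline (default 45 mm; all other branches
#'   are straight).
#' @param same_generation_prob Probability that a major daughter is
#'   diameter-indistinguishable from its parent (within 0.3 mm) and keeps
#'   the parent's generation; applied only for parent generations in
#'   `same_generation_range` and only when `sd_scale > 0`.
#' @param same_generation_range Parent-generation window for the
#'   same-generation events (default 5--24).
#' @param sd_scale Global multiplier on all ratio/angle sds; `0` gives the
#'   noise-free limit in which every draw equals its class mean.
#'
#' @return A validated list of class `generator_params`.
#' @seealso [generate_tree()]
#' @export
generator_params <- function(trachea_diameter_mm = 10^1.3094,
                             trachea_length_mm = 120,
                             tracheal_bronchus_fraction = 0.75,
                             ratio_mean = c(in_d1 = 0.88, out_d1 = 0.86,
                                            in_d2 = 0.57, out_d2 = 0.35),
                             ratio_sd = c(in_d1 = 0.03, out_d1 = 0.03,
                                          in_d2 = 0.05, out_d2 = 0.05),
                             angle1_mean = c(in_plane = 14.34, out_of_plane = 0),
                             angle1_sd = c(in_plane = 5, out_of_plane = 5),
                             angle2_mean = c(in_plane = 41.44, out_of_plane = 41.37),
                             angle2_sd = c(in_plane = 7, out_of_plane = 7),
                             plane_schedule = c(0, 90, -90),
                             length_gen1_mm = 40,
                             length_gen4_mm = 15,
                             length_gen2_override_mm = 12,
                             length_range_mm = c(5, 12),
                             max_generation = 24,
                             min_diameter_mm = 1,
                             transition_zone_fraction_range = c(0.15, 0.40),
                             flow_divider_radius_range_mm = c(0.5, 1.5),
                             aspect_ratio_range = c(0.9, 0.98),
                             aspect_end_range = c(0.5, 0.7),
                             left_mainstem_curvature_radius_mm = 45,
                             same_generation_prob = 0.02,
                             same_generation_range = c(5, 24),
                             sd_scale = 1) {
  p <- as.list(environment())
  stopifnot(
    p$trachea_diameter_mm > 0, p$trachea_length_mm > 0,
    p$tracheal_bronchus_fraction > 0, p$tracheal_bronchus_fraction < 1,
    all(p$ratio_mean > 0), all(p$ratio_mean < 1), all(p$ratio_sd >= 0),
    all(p$angle1_sd >= 0), all(p$angle2_sd >= 0),
    all(p$plane_schedule %in% c(0, 90, -90)),
    length(p$plane_schedule) >= 1,
    p$length_range_mm[1] > 0, diff(p$length_range_mm) >= 0,
    p$sd_scale >= 0
  )
  if (p$min_diameter_mm <= 0 && !is.finite(p$max_generation))
    stop("non-terminating growth: need min_diameter_mm > 0 or a finite ",
         "max_generation", call. = FALSE)
  structure(p, class = "generator_params")
}

length_for_generation <- function(params, generation) {
  if (generation == 2 && !is.null(params$length_gen2_override_mm))
    return(params$length_gen2_override_mm)
  if (generation >= 1 && generation <= 4) {
    f <- (generation - 1) / 3
    return(params$length_gen1_mm + f * (params$length_gen4_mm - params$length_gen1_mm))
  }
  runif(1, params$length_range_mm[1], params$length_range_mm[2])
}

# Circular-arc centreline: start point, initial unit direction, signed
# rotation axis (unit), radius and arc length.  Valid for dir _|_ axis.
arc_centerline <- function(start, dir, axis, radius, arc_len, step_mm = 1.5) {
  n <- max(8L, ceiling(arc_len / step_mm))
  th <- seq(0, arc_len / radius, length.out = n + 1)
  perp <- vcross(axis, dir)
  t(vapply(th, function(a) {
    start + radius * (sin(a) * dir + (1 - cos(a)) * perp)
  }, numeric(3)))
}

#' Generate a synthetic monopodial airway tree
#'
#' Grows a binary airway tree under [generator_params()]: the trachea
#' first sheds the tracheal bronchus, then splits at the main carina into
#' the right (monopodially continuing) and left mainstem bronchi; from
#' there every pathway bifurcates with class-conditional diameter ratios
#' and angles, the bifurcating plane following the cyclic 0/+90/-90
#' schedule.  Growth stops when a daughter would fall below
#' `min_diameter_mm` or beyond `max_generation`.
#'
#' Per-branch ground truth (planarity class, drawn ratios and angles,
#' transition-zone fraction, flow-divider radius, aspect ratios) is stored
#' in each branch's `meta` so that downstream measurement code can be
#' checked against the generating values.
#'
#' Random draws come from a single seeded stream in documented order: for
#' every branch at creation (length if generation >= 5, transition-zone
#' fraction, flow-divider radius, outer aspect, end aspect), then for its
#' bifurcation event (same-generation uniform, d1/D, d2/D with rejection
#' until d1 >= d2, angle1, angle2), recursing depth-first, major daughter
#' first.
#'
#' @param params A [generator_params()] object.
#' @param seed Integer seed; the same seed reproduces the tree exactly.
#' @return A valid [airway_tree()].
#' @export
generate_tree <- function(params = generator_params(), seed = 1L) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(seed, build_tree_impl(params))
}

build_tree_impl <- function(params) {
  env <- new.env(parent = emptyenv())
  env$branches <- list()
  env$counter <- 0L
  env$segA <- matrix(numeric(0), 0, 3)
  env$segB <- matrix(numeric(0), 0, 3)
  env$segR <- numeric(0)
  env$segId <- character(0)
  ref_normal <- c(0, 1, 0)
  s0 <- params$sd_scale

  new_id <- function() {
    env$counter <- env$counter + 1L
    sprintf("b%04d", env$counter)
  }
  add_branch <- function(b) {
    env$branches[[b$id]] <- b
    cl <- b$centerline
    n <- nrow(cl)
    env$segA <- rbind(env$segA, cl[-n, , drop = FALSE])
    env$segB <- rbind(env$segB, cl[-1, , drop = FALSE])
    env$segR <- c(env$segR, rep(b$diameter_mm / 2, n - 1))
    env$segId <- c(env$segId, rep(b$id, n - 1))
  }

  ancestor_ids <- function(id) {
    out <- character(0)
    while (!is.na(id)) {
      out <- c(out, id)
      id <- env$branches[[id]]$parent_id
    }
    out
  }

  # TRUE when a candidate daughter capsule (start J, direction dir, length
  # bound L, radius r) would come within `clearance` of any existing branch
  # other than its ancestors: airway branches do not interpenetrate, so
  # growth stops where space runs out.
  collides <- function(J, dir, L, r, excl_ids, clearance = 1.2) {
    keep <- !(env$segId %in% excl_ids)
    if (!any(keep)) return(FALSE)
    d <- segment_distances(J, J + dir * L,
                           env$segA[keep, , drop = FALSE],
                           env$segB[keep, , drop = FALSE])
    any(d < r + env$segR[keep] + clearance)
  }

  draw_lumen <- function() {
    list(
      tz_fraction = runif(1, params$transition_zone_fraction_range[1],
                          params$transition_zone_fraction_range[2]),
      divider_radius_mm = runif(1, params$flow_divider_radius_range_mm[1],
                                params$flow_divider_radius_range_mm[2]),
      aspect0 = runif(1, params$aspect_ratio_range[1],
                      params$aspect_ratio_range[2]),
      aspect_end = runif(1, params$aspect_end_range[1],
                         params$aspect_end_range[2])
    )
  }

  # Create a branch, then (maybe) bifurcate at its distal end.
  # Returns the branch id.
  grow <- function(start, dir, diameter, generation, schedule_pos, sigma,
                   role, parent_id, curvature = NULL) {
    id <- new_id()
    len <- length_for_generation(params, generation)
    if (!is.null(curvature)) {
      cl <- arc_centerline(start, dir, curvature$axis, curvature$radius, len)
    } else {
      cl <- rbind(start, start + dir * len)
    }
    lum <- draw_lumen()
    meta <- c(lum, list(sigma = sigma, schedule_pos = schedule_pos,
                        origin_class = NA_character_))
    b <- airway_branch(id, parent_id = parent_id, centerline = cl,
                       diameter_mm = diameter, generation = generation,
                       role_tag = role, meta = meta)
    add_branch(b)
    bifurcate(id, generation, schedule_pos, sigma)
    id
  }

  # Bifurcation event at the distal end of branch `id`.
  bifurcate <- function(id, generation, schedule_pos, sigma,
                        forced_rho = NULL) {
    parent <- env$branches[[id]]
    D <- parent$diameter_mm
    sched <- params$plane_schedule
    rho <- if (is.null(forced_rho)) {
      sched[(schedule_pos %% length(sched)) + 1]
    } else forced_rho
    inplane <- abs(rho) < 45
    cls <- if (inplane) "in_plane" else "out_of_plane"
    rk <- if (inplane) c("in_d1", "in_d2") else c("out_d1", "out_d2")

    u_same <- runif(1)
    same_ev <- s0 > 0 && u_same < params$same_generation_prob &&
      generation >= params$same_generation_range[1] &&
      generation <= params$same_generation_range[2]
    if (same_ev) {
      d1 <- D - runif(1, 0, 0.29)
      r1 <- d1 / D
    } else {
      r1 <- rtruncnorm1(params$ratio_mean[[rk[1]]],
                        s0 * params$ratio_sd[[rk[1]]], 0.05, 0.99)
    }
    r2 <- rtruncnorm1(params$ratio_mean[[rk[2]]],
                      s0 * params$ratio_sd[[rk[2]]], 0.05, 0.99)
    for (i in 1:100) {
      if (r2 <= r1) break
      r2 <- rtruncnorm1(params$ratio_mean[[rk[2]]],
                        s0 * params$ratio_sd[[rk[2]]], 0.05, 0.99)
    }
    r2 <- min(r2, r1)
    a1 <- rtruncnorm1(params$angle1_mean[[cls]], s0 * params$angle1_sd[[cls]],
                      0, 90)
    a2 <- rtruncnorm1(params$angle2_mean[[cls]], s0 * params$angle2_sd[[cls]],
                      0, 90)

    d1 <- r1 * D
    d2 <- r2 * D
    g_minor <- generation + 1L
    g_major <- if (same_ev) generation else generation + 1L
    if (max(g_minor, g_major) > params$max_generation ||
        min(d1, d2) < params$min_diameter_mm) {
      return(invisible(NULL))  # leaf: no children
    }

    p_hat <- branch_direction(parent, "distal")
    n0 <- inplane_normal(p_hat, ref_normal)
    n_event <- unitv(rotate_about(n0, p_hat, rho))
    l_hat <- vcross(n_event, p_hat)
    sigma_eff <- if (inplane) sigma else 1
    end <- parent$centerline[nrow(parent$centerline), ]
    dir_major <- unitv(cos(deg2rad(a1)) * p_hat -
                         sigma_eff * sin(deg2rad(a1)) * l_hat)
    dir_minor <- unitv(cos(deg2rad(a2)) * p_hat +
                         sigma_eff * sin(deg2rad(a2)) * l_hat)

    excl <- ancestor_ids(id)
    L_gen <- function(g) if (g >= 1 && g <= 4)
      length_for_generation(params, g) else params$length_range_mm[2]
    if (collides(end, dir_major, L_gen(g_major), d1 / 2, excl) ||
        collides(end, dir_minor, L_gen(g_minor), d2 / 2, excl)) {
      return(invisible(NULL))  # no room: terminate this pathway
    }

    id_major <- grow(end, dir_major, d1, g_major, schedule_pos + 1L, sigma,
                     "other", id)
    id_minor <- grow(end, dir_minor, d2, g_minor, schedule_pos + 1L, sigma,
                     "other", id)
    finish_event(id, id_major, id_minor, rho, cls, sigma_eff, l_hat,
                 c(r1 = r1, r2 = r2, a1 = a1, a2 = a2), same_ev)
  }

  finish_event <- function(id, id_major, id_minor, rho, cls, sigma_eff,
                           l_hat, draws, same_ev) {
    b <- env$branches[[id]]
    b$child_ids <- c(id_major, id_minor)
    b$meta$event <- list(
      scheduled_rotation = rho, class = cls, sigma_eff = sigma_eff,
      true_d1_ratio = unname(draws["r1"]), true_d2_ratio = unname(draws["r2"]),
      true_angle1 = unname(draws["a1"]), true_angle2 = unname(draws["a2"]),
      same_generation = same_ev
    )
    b$meta$ellipse_axis <- l_hat
    env$branches[[id]] <- b
    for (cid in c(id_major, id_minor)) {
      cb <- env$branches[[cid]]
      cb$meta$origin_class <- cls
      env$branches[[cid]] <- cb
    }
  }

  ## --- trachea with tracheal bronchus, then the main carina -------------
  D0 <- params$trachea_diameter_mm
  Lt <- params$trachea_length_mm
  L_prox <- params$tracheal_bronchus_fraction * Lt
  down <- c(0, 0, -1)

  id_prox <- new_id()
  prox <- airway_branch(id_prox, NA_character_,
                        centerline = rbind(c(0, 0, 0), c(0, 0, -L_prox)),
                        diameter_mm = D0, generation = 0L,
                        role_tag = "trachea",
                        meta = c(draw_lumen(),
                                 list(sigma = 1, schedule_pos = NA_integer_,
                                      origin_class = NA_character_)))
  add_branch(prox)

  # tracheal-bronchus event: the trachea continues undiminished (d1 = D,
  # angle1 = 0); the minor daughter feeds the right upper lobe.
  u_same_tb <- runif(1)  # consumed for a uniform draw order; never a same-gen event
  r2_tb <- rtruncnorm1(params$ratio_mean[["in_d2"]],
                       s0 * params$ratio_sd[["in_d2"]], 0.05, 0.99)
  a2_tb <- rtruncnorm1(params$angle2_mean[["in_plane"]],
                       s0 * params$angle2_sd[["in_plane"]], 0, 90)
  n0 <- inplane_normal(down, ref_normal)
  l_hat0 <- vcross(n0, down)            # lateral, towards the animal's right

  id_dist <- new_id()
  dist <- airway_branch(id_dist, id_prox,
                        centerline = rbind(c(0, 0, -L_prox),
                                           c(0, 0, -Lt)),
                        diameter_mm = D0, generation = 0L,
                        role_tag = "trachea",
                        meta = c(draw_lumen(),
                                 list(sigma = 1, schedule_pos = NA_integer_,
                                      origin_class = "in_plane")))
  add_branch(dist)

  dir_tb <- unitv(cos(deg2rad(a2_tb)) * down + sin(deg2rad(a2_tb)) * l_hat0)
  id_tb <- grow(c(0, 0, -L_prox), dir_tb, r2_tb * D0, 1L, 0L, 1,
                "tracheal_bronchus", id_prox)

  finish_event(id_prox, id_dist, id_tb, 0, "in_plane", 1, l_hat0,
               c(r1 = 1, r2 = r2_tb, a1 = 0, a2 = a2_tb), FALSE)

  # carina: right mainstem is the monopodial continuation (major), the left
  # mainstem the minor daughter curving around the heart.
  u_same_ca <- runif(1)
  r1_ca <- rtruncnorm1(params$ratio_mean[["in_d1"]],
                       s0 * params$ratio_sd[["in_d1"]], 0.05, 0.99)
  r2_ca <- rtruncnorm1(params$ratio_mean[["in_d2"]],
                       s0 * params$ratio_sd[["in_d2"]], 0.05, 0.99)
  r2_ca <- min(r2_ca, r1_ca)
  a1_ca <- rtruncnorm1(params$angle1_mean[["in_plane"]],
                       s0 * params$angle1_sd[["in_plane"]], 0, 90)
  a2_ca <- rtruncnorm1(params$angle2_mean[["in_plane"]],
                       s0 * params$angle2_sd[["in_plane"]], 0, 90)
  carina <- c(0, 0, -Lt)
  sig_ca <- -1                           # left mainstem grows to the left
  dir_rm <- unitv(cos(deg2rad(a1_ca)) * down - sig_ca * sin(deg2rad(a1_ca)) * l_hat0)
  dir_lm <- unitv(cos(deg2rad(a2_ca)) * down + sig_ca * sin(deg2rad(a2_ca)) * l_hat0)

  id_rm <- grow(carina, dir_rm, r1_ca * D0, 1L, 0L, 1, "right_mainstem",
                id_dist)

  # left mainstem: circular arc in the reference plane, curving back
  # towards the caudal direction.
  R_lm <- params$left_mainstem_curvature_radius_mm
  ax_plus <- ref_normal
  bend_towards_down <- function(ax) {
    angle_between(rotate_about(dir_lm, ax, 5), down)
  }
  ax_lm <- if (bend_towards_down(ax_plus) < bend_towards_down(-ax_plus))
    ax_plus else -ax_plus
  id_lm <- grow(carina, dir_lm, r2_ca * D0, 1L, 0L, -1, "left_mainstem",
                id_dist, curvature = list(axis = ax_lm, radius = R_lm))

  finish_event(id_dist, id_rm, id_lm, 0, "in_plane", sig_ca, sig_ca * l_hat0,
               c(r1 = r1_ca, r2 = r2_ca, a1 = a1_ca, a2 = a2_ca), FALSE)

  airway_tree(env$branches, root_id = id_prox,
              reference_plane = list(normal = ref_normal, point = c(0, 0, 0)))
}
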