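# Small programmatic fixtures shared across the test files.

# A minimal valid tree: trachea with two straight daughters in the x-z
# plane, minor at `angle2_deg`, both leaving from the carina.
make_y_tree <- function(D = 10, d1 = 8.8, d2 = 5.7,
                        angle1_deg = 0, angle2_deg = 41.44,
                        L = 30, Lc = 25, rotate_minor_deg = 0) {
  down <- c(0, 0, -1)
  lat <- c(-1, 0, 0)                      # in-plane lateral direction
  rad <- function(a) a * pi / 180
  dir1 <- cos(rad(angle1_deg)) * down - sin(rad(angle1_deg)) * lat
  dir2 <- cos(rad(angle2_deg)) * down + sin(rad(angle2_deg)) * lat
  if (rotate_minor_deg != 0) {
    rot_about_z <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                                    sin(a) * v[1] + cos(a) * v[2], v[3])
    # rotation about the parent direction (0, 0, -1): flip the sign
    dir2 <- rot_about_z(dir2, -rad(rotate_minor_deg))
  }
  carina <- c(0, 0, -L)
  branches <- list(
    airway_branch("t", NA_character_, c("a", "b"),
                  rbind(c(0, 0, 0), carina), D, 0L, "trachea"),
    airway_branch("a", "t", character(),
                  rbind(carina, carina + dir1 * Lc), d1, 1L, "right_mainstem"),
    airway_branch("b", "t", character(),
                  rbind(carina, carina + dir2 * Lc), d2, 1L, "left_mainstem")
  )
  airway_tree(branches, "t")
}

# A pure chain of branches with the given diameters (first = trachea),
# each child with a single sibling leaf so every internal node bifurcates.
make_chain_tree <- function(diameters, leaf_diameter = 1) {
  n <- length(diameters)
  branches <- list()
  z <- 0
  for (i in seq_len(n)) {
    id <- sprintf("c%02d", i)
    parent <- if (i == 1) NA_character_ else sprintf("c%02d", i - 1)
    kids <- character()
    if (i < n) kids <- c(sprintf("c%02d", i + 1), sprintf("l%02d", i))
    branches[[id]] <- airway_branch(
      id, parent, kids, rbind(c(0, 0, z), c(0, 0, z - 20)),
      diameters[i], NA_integer_, if (i == 1) "trachea" else "other")
    if (i < n) {
      branches[[sprintf("l%02d", i)]] <- airway_branch(
        sprintf("l%02d", i), id, character(),
        rbind(c(0, 0, z - 20), c(10, 0, z - 25)),
        leaf_diameter, NA_integer_, "other")
    }
    z <- z - 20
  }
  airway_tree(branches, "c01")
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)), 3, 3,
    byrow = TRUE)
}
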