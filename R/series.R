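#' Canonical piecewise log-linear diameter model
#'
#' The three-segment semi-log model of airway diameter against generation
#' measured in the pig: a steep early drop (generations 0--11,
#' `log10 D = -0.0438 g + 1.3094`), a shallower middle segment
#' (12--20, `log10 D = -0.0228 g + 1.0979`) and a steeper distal segment
#' (21--24, `log10 D = -0.0418 g + 1.488`).
#'
#' @return A tibble with columns `segment`, `g_min`, `g_max`, `slope`
#'   (log10 mm per generation) and `intercept` (log10 mm).
#' @export
default_diameter_model <- function() {
  tibble::tibble(
    segment = 1:3,
    g_min = c(0L, 12L, 21L),
    g_max = c(11L, 20L, 24L),
    slope = c(-0.0438, -0.0228, -0.0418),
    intercept = c(1.3094, 1.0979, 1.488)
  )
}

#' Generate a diameter-versus-generation series
#'
#' Emits `n_per_generation` diameters for every generation covered by the
#' segment table, following `10^(slope * g + intercept + eps)` with
#' `eps ~ Normal(0, noise_sd_log10)`.  With zero noise the diameters equal
#' the model values exactly.
#'
#' @param segments Data frame with columns `g_min`, `g_max`, `slope`,
#'   `intercept` (see [default_diameter_model()]); ranges must be
#'   non-overlapping.
#' @param noise_sd_log10 Standard deviation of the log10-diameter noise
#'   (>= 0).
#' @param n_per_generation Number of diameters per generation.
#' @param seed Integer seed (ignored when `noise_sd_log10 = 0`).
#'
#' @return A tibble with columns `generation` and `diameter_mm`.
#' @export
generate_diameter_series <- function(segments = default_diameter_model(),
                                     noise_sd_log10 = 0,
                                     n_per_generation = 3L,
                                     seed = 1L) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("g_min", "g_max", "slope", "intercept") %in% names(segments)),
            noise_sd_log10 >= 0, n_per_generation >= 1)
  gens <- unlist(lapply(seq_len(nrow(segments)), function(i)
    segments$g_min[i]:segments$g_max[i]))
  if (anyDuplicated(gens))
    stop("segment generation ranges overlap", call. = FALSE)
  if (any(gens < 0)) stop("generations must be non-negative", call. = FALSE)

  build <- function() {
    rows <- lapply(seq_len(nrow(segments)), function(i) {
      g <- rep(segments$g_min[i]:segments$g_max[i], each = n_per_generation)
      mu <- segments$slope[i] * g + segments$intercept[i]
      eps <- if (noise_sd_log10 > 0) rnorm(length(g), 0, noise_sd_log10) else 0
      tibble::tibble(generation = as.integer(g), diameter_mm = 10^(mu + eps))
    })
    dplyr::bind_rows(rows)
  }
  if (noise_sd_log10 > 0) with_seed(seed, build()) else build()
}
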