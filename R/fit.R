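#' Piecewise log-linear regression of diameter against generation
#'
#' Fits ordinary least squares of `log10(diameter_mm)` on `generation`
#' independently within fixed generation segments (no continuity
#' constraint at the breakpoints, since the three printed equations need
#' not agree there). Default breakpoints 11 and 20 define segments
#' generations 0--11, 12--20 and >= 21 ("up to generation 11" read as
#' inclusive).
#'
#' Segments that the data do not reach are omitted; a segment reached by
#' fewer than 2 points is an error; with fewer than 3 points the fit is
#' returned without confidence intervals and flagged.
#'
#' @param series Data frame with columns `generation`, `diameter_mm`
#'   (see [generate_diameter_series()]).
#' @param breakpoints Increasing integer vector of last generations of all
#'   but the final segment (default `c(11, 20)`).
#' @param conf_level Confidence level for the Student-t intervals
#'   (default 0.95).
#'
#' @return An object of class `loglinear_fit`: a list with `$segments`, a
#'   tibble with one row per fitted segment (`segment`, `g_min`, `g_max`,
#'   `slope`, `intercept`, `ci_slope_halfwidth`, `ci_intercept_halfwidth`,
#'   `r2`, `n`, `flagged`), plus the input series. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
fit_loglinear_segments <- function(series, breakpoints = c(11, 20),
                                   conf_level = 0.95) {
  series <- as.data.frame(series)
  stopifnot(all(c("generation", "diameter_mm") %in% names(series)),
            all(series$diameter_mm > 0), all(series$generation >= 0),
            !is.unsorted(breakpoints, strictly = TRUE))
  lo <- c(0, breakpoints + 1)
  hi <- c(breakpoints, Inf)
  gmax <- max(series$generation)

  rows <- list()
  for (i in seq_along(lo)) {
    sub <- series[series$generation >= lo[i] & series$generation <= hi[i], ]
    n <- nrow(sub)
    if (n == 0) next  # segment not covered by the data: omit
    if (n < 2)
      stop(sprintf("segment %d (generations %s-%s) has %d point(s); need >= 2",
                   i, lo[i], ifelse(is.finite(hi[i]), hi[i], "max"), n),
           call. = FALSE)
    if (length(unique(sub$generation)) < 2)
      stop(sprintf("segment %d has a single distinct generation; slope undefined", i),
           call. = FALSE)
    fit <- lm(log10(diameter_mm) ~ generation, data = sub)
    cf <- coef(fit)
    flagged <- n < 3
    if (flagged) {
      ci <- c(NA_real_, NA_real_)
      r2 <- NA_real_
    } else {
      se <- suppressWarnings(sqrt(diag(vcov(fit))))
      tq <- qt(1 - (1 - conf_level) / 2, df = n - 2)
      ci <- tq * se
      r2 <- suppressWarnings(summary(fit)$r.squared)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      segment = i, g_min = lo[i], g_max = min(hi[i], gmax),
      slope = unname(cf["generation"]), intercept = unname(cf["(Intercept)"]),
      ci_slope_halfwidth = unname(ci[2]),
      ci_intercept_halfwidth = unname(ci[1]),
      r2 = r2, n = n, flagged = flagged
    )
  }
  structure(list(segments = dplyr::bind_rows(rows),
                 series = tibble::as_tibble(series),
                 breakpoints = breakpoints,
                 conf_level = conf_level),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat("<loglinear_fit> log10(diameter_mm) ~ generation, per segment\n")
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat(sprintf("  seg %d (g %g-%g): log10 D = %+.4f g + %.4f  (n = %d%s)\n",
                s$segment, s$g_min, s$g_max, s$slope, s$intercept, s$n,
                if (isTRUE(s$flagged)) ", no CI" else ""))
  }
  invisible(x)
}

#' @rdname fit_loglinear_segments
#' @param x A `loglinear_fit` object.
#' @param ... Unused.
#' @method tidy loglinear_fit
#' @export
tidy.loglinear_fit <- function(x, ...) {
  s <- x$segments
  dplyr::bind_rows(
    dplyr::transmute(s, segment = .data$segment, term = "generation",
                     estimate = .data$slope,
                     conf.low = .data$slope - .data$ci_slope_halfwidth,
                     conf.high = .data$slope + .data$ci_slope_halfwidth),
    dplyr::transmute(s, segment = .data$segment, term = "(Intercept)",
                     estimate = .data$intercept,
                     conf.low = .data$intercept - .data$ci_intercept_halfwidth,
                     conf.high = .data$intercept + .data$ci_intercept_halfwidth)
  ) |> dplyr::arrange(.data$segment, dplyr::desc(.data$term))
}

#' @rdname fit_loglinear_segments
#' @method glance loglinear_fit
#' @export
glance.loglinear_fit <- function(x, ...) {
  tibble::tibble(n_segments = nrow(x$segments),
                 n_points = nrow(x$series),
                 r2_min = suppressWarnings(min(x$segments$r2, na.rm = TRUE)),
                 conf_level = x$conf_level)
}

#' @rdname fit_loglinear_segments
#' @param object A `loglinear_fit` object.
#' @method autoplot loglinear_fit
#' @export
autoplot.loglinear_fit <- function(object, ...) {
  pred <- dplyr::bind_rows(lapply(seq_len(nrow(object$segments)), function(i) {
    s <- object$segments[i, ]
    g <- seq(s$g_min, s$g_max, length.out = 50)
    tibble::tibble(generation = g, diameter_mm = 10^(s$slope * g + s$intercept),
                   segment = factor(s$segment))
  }))
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$generation, y = .data$diameter_mm)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = pred,
                       ggplot2::aes(colour = .data$segment), linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "diameter (mm, log scale)",
                  colour = "segment") +
    ggplot2::theme_minimal()
}
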