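#' Build plot-ready coordinates for one panel
#'
#' Maps the numeric output of an analysis to the coordinates of one of
#' the study's panel types. Coordinates (not pixels) are the testable
#' surface of every figure; [plot_panel()] renders them.
#'
#' Panel kinds and their inputs:
#' \describe{
#'   \item{`os_km`, `ttd_km`}{a list of [km_estimate()] curves (one per
#'     arm); right-continuous step coordinates starting at (0, 1).}
#'   \item{`cif`}{a list of [cif_estimate()] curves *plus* the matching
#'     OS [km_estimate()] curves via `os`: cumulative-incidence panels
#'     are always bundled with the OS Kaplan-Meier series of the same
#'     arms, since a CIF cannot be read without the survival curve.}
#'   \item{`combined_composite`}{a list of [combined_curve()]s; time is
#'     mapped to axis `[0, split]`, QOL to `(split, 1]`.}
#'   \item{`terminal_decline`}{a [backward_trajectory()] tibble; the
#'     x-axis runs backward (months before death, decreasing to 0).}
#'   \item{`qol_trajectory`}{a [survivor_summary()]-shaped tibble
#'     (`visit_month`, `arm`, `mean`, and optionally `sd`, `n`, or an
#'     `se` column), joined by straight segments.}
#' }
#'
#' @param kind One of `"os_km"`, `"ttd_km"`, `"cif"`,
#'   `"combined_composite"`, `"terminal_decline"`, `"qol_trajectory"`.
#' @param x The analysis result(s), as described above.
#' @param os For `kind = "cif"`: list of [km_estimate()] curves per arm.
#' @return An object of class `panel_data`: list with `kind`, `series`
#'   (tibble `arm`, `part`, `x`, `y`, and `native_x` where the axis is
#'   remapped), and `axis` metadata.
#' @export
build_panel <- function(kind = c("os_km", "ttd_km", "cif",
                                 "combined_composite", "terminal_decline",
                                 "qol_trajectory"),
                        x, os = NULL) {
  kind <- match.arg(kind)
  series <- switch(
    kind,
    os_km = ,
    ttd_km = {
      if (inherits(x, "step_curve")) x <- list(x)
      dplyr::bind_rows(lapply(x, function(km) {
        stopifnot(inherits(km, "step_curve"))
        tibble::tibble(arm = km$arm_label %||% NA, part = "km",
                       x = km$curve$time, y = km$curve$estimate)
      }))
    },
    cif = {
      if (inherits(x, "cif_curve")) x <- list(x)
      if (is.null(os)) {
        stop("`cif` panels must bundle the OS Kaplan-Meier curves (`os`)",
             call. = FALSE)
      }
      if (inherits(os, "step_curve")) os <- list(os)
      cif_part <- dplyr::bind_rows(lapply(x, function(cv) {
        stopifnot(inherits(cv, "cif_curve"))
        dplyr::bind_rows(
          tibble::tibble(arm = cv$arm_label %||% NA, part = "cif_deterioration",
                         x = cv$curve$time, y = cv$curve$cif_deterioration),
          tibble::tibble(arm = cv$arm_label %||% NA, part = "cif_death",
                         x = cv$curve$time, y = cv$curve$cif_death)
        )
      }))
      os_part <- dplyr::bind_rows(lapply(os, function(km) {
        tibble::tibble(arm = km$arm_label %||% NA, part = "os_km",
                       x = km$curve$time, y = km$curve$estimate)
      }))
      dplyr::bind_rows(cif_part, os_part)
    },
    combined_composite = {
      if (inherits(x, "combined_curve")) x <- list(x)
      dplyr::bind_rows(lapply(x, function(cc) {
        stopifnot(inherits(cc, "combined_curve"))
        dplyr::bind_rows(
          tibble::tibble(arm = cc$arm_label %||% NA, part = "time",
                         x = cc$left$axis_x, y = cc$left$cumprob,
                         native_x = cc$left$time),
          tibble::tibble(arm = cc$arm_label %||% NA, part = "qol",
                         x = cc$right$axis_x, y = cc$right$cumprob,
                         native_x = cc$right$qol)
        )
      }))
    },
    terminal_decline = {
      df <- x  # keep the input visible while building the x column
      tibble::tibble(arm = df$arm, part = "mean",
                     x = df$backward_time, y = df$mean,
                     se = df$sd / sqrt(pmax(df$n, 1)))
    },
    qol_trajectory = {
      df <- x
      se_col <- if ("se" %in% names(df)) {
        df$se
      } else if (all(c("sd", "n") %in% names(df))) {
        df$sd / sqrt(pmax(df$n, 1))
      } else {
        NA_real_
      }
      tibble::tibble(arm = df$arm, part = "mean",
                     x = df$visit_month, y = df$mean, se = se_col)
    }
  )
  axis <- switch(
    kind,
    os_km = list(xlab = "Months", ylab = "Survival probability"),
    ttd_km = list(xlab = "Months",
                  ylab = "Probability free of death or deterioration"),
    cif = list(xlab = "Months", ylab = "Probability"),
    combined_composite = {
      split <- x[[1]]$split_fraction
      list(xlab = "Time to death, then QOL among survivors",
           ylab = "Cumulative probability",
           split = split, t = x[[1]]$t, qol_range = x[[1]]$qol_range)
    },
    terminal_decline = list(xlab = "Months before death (backward)",
                            ylab = "QOL", reverse_x = TRUE),
    qol_trajectory = list(xlab = "Months since randomization", ylab = "QOL")
  )
  structure(list(kind = kind, series = series, axis = axis),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat("<panel_data>", x$kind, "-", nrow(x$series), "coordinates,",
      length(unique(x$series$arm)), "arm(s)\n")
  invisible(x)
}

#' Render a panel
#'
#' Draws a [build_panel()] object with ggplot2. Step-type panels are
#' drawn right-continuous; trajectory panels join visit means with
#' straight segments and show mean +/- SE bands when available; the
#' terminal-decline x-axis runs backward. The ggplot's `data` slot holds
#' exactly the panel's `series` tibble, so coordinates round-trip.
#'
#' @param panel A `panel_data` object.
#' @return A ggplot object.
#' @export
plot_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  s <- panel$series
  s$group <- interaction(s$arm, s$part, drop = TRUE)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = factor(.data$arm),
                                       linetype = .data$part,
                                       group = .data$group))
  step_kinds <- c("os_km", "ttd_km", "cif", "combined_composite")
  if (panel$kind %in% step_kinds) {
    p <- p + ggplot2::geom_step(direction = "hv")
  } else {
    if ("se" %in% names(s) && !all(is.na(s$se))) {
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$y - .data$se, ymax = .data$y + .data$se,
                     fill = factor(.data$arm)),
        alpha = 0.2, colour = NA
      )
    }
    p <- p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8)
  }
  if (isTRUE(panel$axis$reverse_x)) p <- p + ggplot2::scale_x_reverse()
  if (!is.null(panel$axis$split)) {
    p <- p + ggplot2::geom_vline(xintercept = panel$axis$split,
                                 linetype = "dotted", colour = "grey40")
  }
  p + ggplot2::labs(x = panel$axis$xlab, y = panel$axis$ylab,
                    colour = "Arm", fill = "Arm", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize panel coordinates
#'
#' Writes the series as CSV and the axis metadata as a small JSON file
#' alongside it (requires the jsonlite package for the metadata).
#'
#' @param panel A `panel_data` object.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "panel_data"))
  readr::write_csv(panel$series, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- c(list(kind = panel$kind), panel$axis)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}
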