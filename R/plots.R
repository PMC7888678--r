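#' Plot receiver results
#'
#' `autoplot()` on a `scat_image` draws one of the display planes used to
#' present the model's output: the dechirped threshold-crossing
#' spectrogram (delay x frequency), the range-delay histograms along the
#' delay axis, the glint-delay histograms (raw or energy-normalized), or
#' the triangular network's null/apex zig-zag trace.
#'
#' @param object A `scat_image`.
#' @param type One of `"dechirped"`, `"range"`, `"glint"`, `"network"`.
#' @param level Threshold level(s) shown on the dechirped plane.
#' @param normalized Show energy-normalized glint histograms.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scat_image <- function(object,
                                type = c("dechirped", "range", "glint", "network"),
                                level = 3,
                                normalized = FALSE,
                                ...) {
  type <- match.arg(type)
  switch(type,
    dechirped = {
      d <- object$dechirped |>
        dplyr::filter(.data$level %in% !!level, !is.na(.data$delay))
      ggplot2::ggplot(d, ggplot2::aes(
        x = .data$delay * 1e3, y = .data$cf_khz,
        colour = factor(.data$level)
      )) +
        ggplot2::geom_point(size = 0.4) +
        ggplot2::labs(
          x = "dechirped delay (ms)", y = "frequency (kHz)",
          colour = "threshold"
        ) +
        ggplot2::theme_minimal()
    },
    range = {
      h <- purrr::imap_dfr(object$range, function(r, key) {
        dplyr::mutate(r$histogram, event = as.numeric(key))
      })
      ggplot2::ggplot(h, ggplot2::aes(x = .data$delay * 1e3, y = .data$count)) +
        ggplot2::geom_col(width = 2e-3, fill = "steelblue") +
        ggplot2::facet_wrap(~event, scales = "free_x") +
        ggplot2::labs(x = "range delay (ms)", y = "count") +
        ggplot2::theme_minimal()
    },
    glint = {
      h <- purrr::imap_dfr(object$glint, function(g, key) {
        d <- if (normalized && !is.null(g$normalized)) {
          dplyr::rename(g$normalized, value = "density")
        } else {
          dplyr::rename(g$histogram, value = "count")
        }
        dplyr::mutate(d, event = as.numeric(key))
      })
      ggplot2::ggplot(h, ggplot2::aes(x = .data$delta_t_us, y = .data$value)) +
        ggplot2::geom_line(colour = "firebrick") +
        ggplot2::scale_x_log10() +
        ggplot2::facet_wrap(~event) +
        ggplot2::labs(
          x = "glint delay (us)",
          y = if (normalized) "normalized density" else "count"
        ) +
        ggplot2::theme_minimal()
    },
    network = {
      traces <- purrr::imap_dfr(object$nulls, function(ns, key) {
        if (!nrow(ns$nulls)) return(NULL)
        dplyr::mutate(ns$nulls, event = as.numeric(key))
      })
      if (is.null(traces) || !nrow(traces)) {
        return(ggplot2::ggplot() +
          ggplot2::labs(x = "frequency spacing (kHz)", y = "frequency (kHz)") +
          ggplot2::theme_minimal())
      }
      zig <- traces |>
        dplyr::group_by(.data$event, .data$segment) |>
        dplyr::arrange(.data$center_khz, .by_group = TRUE) |>
        dplyr::mutate(
          apex_df = (dplyr::lead(.data$center_khz) - .data$center_khz),
          apex_y = (.data$center_khz + dplyr::lead(.data$center_khz)) / 2
        ) |>
        dplyr::ungroup()
      ggplot2::ggplot(traces, ggplot2::aes(y = .data$center_khz)) +
        ggplot2::geom_point(ggplot2::aes(x = 0), colour = "red") +
        ggplot2::geom_point(
          data = dplyr::filter(zig, !is.na(.data$apex_df)),
          ggplot2::aes(x = .data$apex_df, y = .data$apex_y),
          shape = 17, colour = "red"
        ) +
        ggplot2::geom_segment(
          data = dplyr::filter(zig, !is.na(.data$apex_df)),
          ggplot2::aes(
            x = 0, y = .data$center_khz,
            xend = .data$apex_df, yend = .data$apex_y
          ),
          colour = "red", linewidth = 0.3
        ) +
        ggplot2::facet_wrap(~event) +
        ggplot2::labs(x = "frequency spacing (kHz)", y = "frequency (kHz)") +
        ggplot2::theme_minimal()
    }
  )
}

#' Render the standard figure set for an image
#'
#' Writes the dechirped-spectrogram plane, range-delay histograms,
#' glint-delay histograms (raw and normalized) and the triangular network
#' trace as static files.  Deterministic given the image and options.
#'
#' @param image A `scat_image`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"svg"`.
#' @param level Threshold level(s) for the dechirped plane.
#' @return Invisibly, the written file paths.
#' @export
render_scat_figures <- function(image, dir, format = "png", level = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    dechirped = autoplot(image, "dechirped", level = level),
    range = autoplot(image, "range"),
    glint = autoplot(image, "glint"),
    glint_normalized = autoplot(image, "glint", normalized = TRUE),
    network = autoplot(image, "network")
  )
  paths <- character()
  for (nm in names(specs)) {
    p <- file.path(dir, paste0(nm, ".", format))
    ggplot2::ggsave(p, specs[[nm]], width = 8, height = 6, dpi = 150)
    paths <- c(paths, p)
  }
  invisible(paths)
}
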