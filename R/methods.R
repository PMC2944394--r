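#' @export
print.restenosis_sim <- function(x, ...) {
  cat(sprintf(
    "<restenosis_sim> %d day(s), termination: %s\n", x$days_run,
    x$termination
  ))
  last <- tail(x$metrics, 1)
  if (nrow(last)) {
    cat(sprintf(
      "  final: %d cSMC, %d sSMC, %d EC", last$n_csmc, last$n_ssmc, last$n_ec
    ))
    if (!is.null(last$lesion_volume)) {
      cat(sprintf(", lesion volume %.4g mm^3", last$lesion_volume))
    }
    cat("\n")
  }
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Tidiers for simulation results
#'
#' `tidy()` returns the per-day metrics tibble; `glance()` a one-row
#' summary of the whole run.
#'
#' @param x a [run_simulation()] result.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.restenosis_sim <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.restenosis_sim
#' @export
glance.restenosis_sim <- function(x, ...) {
  last <- tail(x$metrics, 1)
  tibble(
    days_run = x$days_run,
    termination = x$termination,
    n_cells_final = if (nrow(last)) last$n_cells else NA_integer_,
    n_ec_final = if (nrow(last)) last$n_ec else NA_integer_,
    lesion_volume_final = if (!is.null(x$areas) && nrow(last)) {
      last$lesion_volume
    } else {
      NA_real_
    },
    peak_doubling = if (nrow(last)) {
      suppressWarnings(max(x$metrics$doubling, na.rm = TRUE))
    } else {
      NA_real_
    },
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' Plot a simulation result
#'
#' Time courses of the lesion volume, the cell counts by type, and the
#' daily population doubling.
#'
#' @param object a [run_simulation()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.restenosis_sim <- function(object, ...) {
  m <- object$metrics
  long <- dplyr::bind_rows(
    if (!is.null(m$lesion_volume)) {
      tibble(day = m$day, panel = "lesion volume (mm^3)",
             series = "lesion", value = m$lesion_volume)
    },
    tibble(day = rep(m$day, 3),
           panel = "cells",
           series = rep(c("cSMC", "sSMC", "EC"), each = nrow(m)),
           value = c(m$n_csmc, m$n_ssmc, m$n_ec)),
    tibble(day = m$day, panel = "population doubling (log2 N/N0)",
           series = "doubling", value = m$doubling)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "day", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a lattice cross-section
#'
#' ECM as a filled raster with occupants overlaid, for one axial slice.
#'
#' @param object an artery lattice.
#' @param slice axial slice index `k` (default: middle).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.artery_lattice <- function(object, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(object$dims[3] / 2)
  df <- lattice_sites(object, slices = slice)
  df <- df[df$domain != "outside", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$ecm)) +
    ggplot2::geom_point(
      data = df[df$occupant != "none", ],
      ggplot2::aes(colour = .data$occupant), size = 0.3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey30") +
    ggplot2::scale_colour_manual(
      values = c(cSMC = "#2e7d32", sSMC = "#1565c0", EC = "#c62828")
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)", fill = "ECM",
      title = sprintf("slice k = %d (z = %.2f mm)", slice,
                      (slice - 0.5) * object$dl)
    ) +
    ggplot2::theme_minimal()
}
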