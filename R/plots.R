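#' Plot a fingerprint
#'
#' Pre- and post-contrast halves of the normalized GESFIDSE fingerprint
#' against echo index.
#'
#' @param object a `vmrf_fingerprint`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vmrf_fingerprint <- function(object, ...) {
  df <- tibble(
    echo = rep(seq_len(object$n_echoes), 2),
    phase = factor(rep(c("pre", "post"), each = object$n_echoes),
      levels = c("pre", "post")
    ),
    value = object$values
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$echo, .data$value, colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "echo index", y = "normalized magnitude",
      colour = NULL, title = "GESFIDSE fingerprint (pre / post contrast)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot dictionary parameter coverage
#'
#' Scatter of the measured (BVf, R) plane coloured by sampled SO2, showing
#' how the dictionary covers the vascular parameter space.
#'
#' @param object a `vmrf_dictionary`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vmrf_dictionary <- function(object, ...) {
  ggplot2::ggplot(
    object$params,
    ggplot2::aes(.data$bvf, .data$radius, colour = .data$so2)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(
      x = "BVf (%)", y = "mean radius (um)", colour = "SO2 (%)",
      title = sprintf("Dictionary coverage (%s family, n = %d)",
        object$meta$family, nrow(object$params))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a voxel geometry slice
#'
#' Occupancy of one z-slice (maximum-intensity projection if `project`).
#'
#' @param object a `vmrf_voxel`.
#' @param z slice index (default: middle slice).
#' @param project if `TRUE`, plot the through-plane maximum projection.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vmrf_voxel <- function(object, z = NULL, project = FALSE, ...) {
  occ <- object$occupancy
  sl <- if (project) {
    apply(occ, c(1, 2), max)
  } else {
    occ[, , z %||% max(1L, dim(occ)[3] %/% 2L)]
  }
  df <- tidyr::expand_grid(
    x = seq_len(nrow(sl)), y = seq_len(ncol(sl))
  )
  df$occ <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = factor(.data$occ))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "firebrick")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s voxel, BVf %.2f%%", object$provenance, object$bvf),
      fill = "vessel"
    ) +
    ggplot2::theme_void()
}

#' Plot reconstructed parametric maps
#'
#' Raster panels of the four parameter maps (one z-slice for 3D series).
#'
#' @param object a `vmrf_maps`.
#' @param z slice for 3D maps.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vmrf_maps <- function(object, z = 1L, ...) {
  df <- tidy(object)
  df <- df[df$z == z & df$in_mask, ]
  long <- tidyr::pivot_longer(
    df[c("x", "y", "bvf", "radius", "so2", "t2")],
    cols = c("bvf", "radius", "so2", "t2"),
    names_to = "parameter", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s parametric maps", toupper(object$method))) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of simulated echo trains
#'
#' @param signals tibble from [simulate_gesfidse()] (optionally several,
#'   bound with an id column).
#' @param id optional column distinguishing curves.
#' @return A ggplot object.
#' @export
plot_echo_train <- function(signals, id = NULL) {
  aes <- if (is.null(id)) {
    ggplot2::aes(.data$echo_ms, .data$signal)
  } else {
    ggplot2::aes(.data$echo_ms, .data$signal, colour = factor(.data[[id]]))
  }
  ggplot2::ggplot(signals, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "echo time (ms)", y = "|signal|", colour = id) +
    ggplot2::theme_minimal()
}
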