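# ggplot2 views of the main result types.

#' Plot a face profile
#'
#' Azimuth-versus-axial-position map of side-chain centroids coloured
#' by hydrophobicity and shaped by face assignment, the flattened-out
#' cylinder view of a filament surface.
#'
#' @param object A `face_profile` from [assign_faces()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot face_profile
#' @export
autoplot.face_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$azimuth, y = .data$axial_z,
                                       colour = .data$hydrophobicity,
                                       shape = .data$face)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "boundary_azimuth"),
                        linetype = "dashed") +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey85",
                                    high = "darkorange") +
    ggplot2::labs(x = "azimuth about filament axis (deg)",
                  y = "axial position (Å)",
                  colour = "hydrophobicity", shape = "face") +
    ggplot2::theme_minimal()
}

#' Plot a clustered localization field
#'
#' Localizations coloured by DBSCAN cluster; noise in grey.
#'
#' @param locs A clustered tibble from [cluster_localizations()].
#' @return A ggplot.
#' @export
plot_clusters <- function(locs) {
  locs$label <- ifelse(locs$cluster == -1L, NA_character_,
                       as.character(locs$cluster))
  ggplot2::ggplot(locs, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, na.rm = TRUE) +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot an assay trace
#'
#' Time course coloured by phase, with plateau levels overlaid when the
#' trace has the three dithionite-quench phases.
#'
#' @param trace A trace tibble (`time`, `signal`, optionally `phase`).
#' @return A ggplot.
#' @export
plot_trace <- function(trace) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time, y = .data$signal))
  if ("phase" %in% names(trace)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$phase))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot classified coupling pairs
#'
#' Intra- versus inter-subunit CA distance for each analysed pair,
#' with the exclusion cutoff and the intra = inter diagonal.
#'
#' @param classified Output of [classify_pairs()].
#' @param max_dist Cutoff drawn as dashed lines (default 12 Angstrom).
#' @return A ggplot.
#' @export
plot_pair_classification <- function(classified, max_dist = 12) {
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data$d_intra, y = .data$d_inter_min,
                               colour = .data$label, size = .data$score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = max_dist, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = max_dist, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "intra-subunit Cα distance (Å)",
                  y = "min inter-subunit Cα distance (Å)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
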