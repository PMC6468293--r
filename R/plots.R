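#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_col geom_segment labs theme_minimal scale_colour_manual
NULL

#' Plot a packing-angle report
#'
#' Interior-helix turn-packing angles along the solenoid, coloured by label
#' (ABA at B helices, BAB at A helices), with the two label means as dashed
#' guides; anomalous helices are circled.
#'
#' @param object An `angle_report` from [packing_angles()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.angle_report <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(x = .data$helix, y = .data$angle, colour = .data$label)) +
    geom_line(aes(group = .data$label), linewidth = 0.3, alpha = 0.5) +
    geom_point(size = 2.5) +
    geom_hline(yintercept = object$mean_ABA, linetype = "dashed",
               colour = "#00688B", alpha = 0.6) +
    geom_hline(yintercept = object$mean_BAB, linetype = "dashed",
               colour = "#8B3A06", alpha = 0.6) +
    scale_colour_manual(values = c(ABA = "#00688B", BAB = "#8B3A06")) +
    labs(
      x = "helix index", y = "packing angle (deg)",
      title = paste0("Solenoid curvature: ", object$curvature),
      subtitle = sprintf("mean BAB - mean ABA = %.2f deg",
                         object$mean_BAB - object$mean_ABA)
    ) +
    theme_minimal()
  if (any(d$anomaly)) {
    p <- p + geom_point(data = d[d$anomaly, ], shape = 1, size = 5, stroke = 1)
  }
  p
}

#' Plot per-residue accessible surface area
#'
#' @param object A `sasa_result` from [shrake_rupley()].
#' @param ... Unused.
#' @return A ggplot of summed per-residue areas along the chain.
#' @export
autoplot.sasa_result <- function(object, ...) {
  d <- tidy(object) |>
    group_by(.data$chain, .data$resno) |>
    summarise(area = sum(.data$area), .groups = "drop")
  ggplot(d, aes(x = .data$resno, y = .data$area)) +
    geom_col(fill = "#4682B4") +
    labs(x = "residue", y = expression("SASA (" * ring(A)^2 * ")")) +
    theme_minimal()
}

#' Plot residue-pair distances against a feasibility threshold
#'
#' @param report A `distance_report` (ideally after
#'   [disulfide_feasibility()]).
#' @param threshold Optional threshold line, angstrom; defaults to the one
#'   in the report, if present.
#' @return A ggplot.
#' @export
plot_distances <- function(report, threshold = NULL) {
  d <- as_tibble(report)
  d$pair <- paste0(d$chain_a, d$resno_a, "-", d$chain_b, d$resno_b)
  threshold <- threshold %||% if ("threshold" %in% names(d)) d$threshold[1] else NULL
  p <- ggplot(d, aes(x = .data$pair, y = .data$distance)) +
    geom_segment(aes(xend = .data$pair, y = 0, yend = .data$distance),
                 colour = "grey60") +
    geom_point(size = 3, aes(colour = if ("feasible" %in% names(d)) .data$feasible else NULL)) +
    labs(x = NULL, y = "distance (Å)", colour = "feasible") +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
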