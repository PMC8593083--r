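#' @exportS3Method ggplot2::autoplot
autoplot.loopgate_dccm <- function(object, thresholded = TRUE, ...) {
  df <- tidy(object)
  use_thr <- thresholded && "thresholded" %in% names(df)
  df$value <- if (use_thr) df$thresholded else df$correlation
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resid_i, y = .data$resid_j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "correlation") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue", y = "residue",
                  title = if (use_thr)
                    sprintf("DCCM (|c| <= %.2f shown as 0)",
                            object$threshold %||% 0.3)
                  else "DCCM") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.loopgate_contact_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resid_i, y = .data$resid_j,
                                   fill = .data$occupancy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 1), name = "occupancy") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue", y = "residue",
                  title = sprintf("Contact map (cutoff %.1f A)",
                                  object$distance_cutoff)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.lock_series <- function(object, ...) {
  ggplot2::ggplot(object$states,
                  ggplot2::aes(x = .data$time_ns, y = .data$distance,
                               colour = .data$engaged)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$engage_cutoff,
                        linetype = "dashed") +
    ggplot2::facet_grid(lock_id ~ run,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (ns)", y = "lock distance (A)",
                  colour = "engaged") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mm_fit <- function(object, ...) {
  s_grid <- seq(0, max(object$data$substrate_nM), length.out = 200)
  curve <- tibble(substrate_nM = s_grid,
                  rate = object$vmax * s_grid / (object$km + s_grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$substrate_nM, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(
      x = "[nucleosome] (nM)", y = "initial rate (nM/min)",
      title = sprintf("%s: kcat = %.3g min^-1, KM = %.3g nM",
                      ifelse(is.na(object$condition), "Michaelis-Menten",
                             object$condition),
                      object$kcat, object$km)) +
    ggplot2::theme_minimal()
}
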