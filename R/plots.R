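#' Scatter of effect pairs with a fitted bias slope
#'
#' Plots the conditional outcome effects against the covariate effects,
#' overlaying the fitted regression line(s). The slope of this cloud *is*
#' the collider bias; a method that estimates it well passes through the
#' backbone formed by SNPs without direct outcome effects.
#'
#' @param pairs A harmonised pair tibble.
#' @param ... One or more `slope_estimate` objects (named arguments become
#'   legend labels).
#' @param alpha_point Point transparency.
#' @return A ggplot object.
#' @export
plot_slope_fit <- function(pairs, ..., alpha_point = 0.3) {
  ests <- list(...)
  ests <- ests[vapply(ests, inherits, logical(1), "slope_estimate")]
  labels <- names(ests)
  if (is.null(labels) || any(labels == "")) {
    labels <- vapply(ests, `[[`, character(1), "method")
  }
  lines <- if (length(ests)) {
    tibble::tibble(
      method = labels,
      slope = vapply(ests, `[[`, numeric(1), "b"),
      intercept = vapply(ests, `[[`, numeric(1), "intercept")
    )
  } else NULL

  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_point(alpha = alpha_point, size = 0.6) +
    ggplot2::labs(
      x = expression(hat(beta)[GX]),
      y = expression(hat(beta)[GY]^C)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(lines)) {
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method),
      linewidth = 0.8
    ) +
      ggplot2::labs(colour = "method")
  }
  p
}

#' @rdname autoplot-colliderbias
#' @method autoplot slopehunter_fit
#' @export
autoplot.slopehunter_fit <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) {
    stop("supply the pair tibble the mixture was fitted on", call. = FALSE)
  }
  kept <- threshold_by_x_pvalue(pairs,
                                p_max = 1)  # caller passes kept pairs
  n <- length(object$mixture$responsibilities)
  if (nrow(kept) != n) {
    stop("pairs do not match the fitted SNP set (", n, " SNPs)",
         call. = FALSE)
  }
  kept$responsibility <- object$mixture$responsibilities
  ggplot2::ggplot(kept, ggplot2::aes(x = .data$beta_x, y = .data$beta_y,
                                     colour = .data$responsibility)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.7) +
    ggplot2::geom_abline(slope = object$estimate$b, intercept = 0,
                         linetype = 2) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = expression(hat(beta)[GX]),
                  y = expression(hat(beta)[GY]^C),
                  colour = "P(valid IV)") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for colliderbias result objects
#'
#' `autoplot.error_rate_report()` shows Type-1 error and power per method
#' with Monte-Carlo error bars; `autoplot.slope_report()` shows mean slope
#' estimates with empirical spread against the analytic truth;
#' `autoplot.slopehunter_fit()` shows the mixture's responsibilities over
#' the effect-pair cloud (pass the thresholded pair tibble via `pairs`).
#'
#' @param object A result object.
#' @param pairs For the mixture fit: the pair tibble it was fitted on
#'   (after p-value thresholding).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-colliderbias
NULL

#' @rdname autoplot-colliderbias
#' @method autoplot error_rate_report
#' @export
autoplot.error_rate_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("method", "type1", "power",
                                "mc_se_type1", "mc_se_power")],
    cols = c("type1", "power"),
    names_to = "rate", values_to = "value"
  )
  long$mc_se <- ifelse(long$rate == "type1", long$mc_se_type1,
                       long$mc_se_power)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$rate)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - 2 * .data$mc_se,
                   ymax = .data$value + 2 * .data$mc_se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = attr(object, "alpha") %||% 0.05,
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = "rejection rate", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-colliderbias
#' @method autoplot slope_report
#' @export
autoplot.slope_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$rho_shared),
                               y = .data$mean_b, colour = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_b - .data$empirical_sd,
                   ymax = .data$mean_b + .data$empirical_sd),
      position = ggplot2::position_dodge(width = 0.4), width = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$b_true), colour = "black",
                        shape = 4, size = 3) +
    ggplot2::labs(x = "shared-effect correlation",
                  y = "estimated bias slope (x = truth)") +
    ggplot2::theme_minimal()
}
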