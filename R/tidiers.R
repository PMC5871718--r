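# broom-style accessors and plots for fitted objects

#' @exportS3Method generics::tidy
tidy.melting_fit <- function(x, ...) {
  tibble(
    term = c("a", "b", "plateau"),
    estimate = c(x$a, x$b, x$plateau)
  )
}

#' @exportS3Method generics::glance
glance.melting_fit <- function(x, ...) {
  tibble(
    a = x$a, b = x$b, plateau = x$plateau, tm = x$tm,
    min_slope = x$min_slope, r_squared = x$r_squared, converged = x$converged
  )
}

#' @export
print.melting_fit <- function(x, ...) {
  cat("<melting_fit>\n")
  if (!x$converged) {
    cat("  not converged\n")
  } else {
    cat(sprintf("  Tm = %.2f degC, plateau = %.3f, min slope = %.4f, R^2 = %.3f\n",
                x$tm, x$plateau, x$min_slope, x$r_squared))
  }
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.melting_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature, y = .data$fold_change)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (°C)", y = "Fraction non-denatured")
  if (object$converged) {
    grid <- tibble(temperature = seq(min(df$temperature), max(df$temperature),
                                     length.out = 200))
    grid$fold_change <- melt_curve(grid$temperature, object$a, object$b, object$plateau)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
    if (is.finite(object$tm)) {
      p <- p + ggplot2::geom_vline(xintercept = object$tm, linetype = "dashed")
    }
  }
  p
}

#' @exportS3Method generics::tidy
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("logec50", "slope"), estimate = c(x$logec50, x$slope))
}

#' @exportS3Method generics::glance
glance.dose_response_fit <- function(x, ...) {
  tibble(
    direction = x$direction, logec50 = x$logec50, slope = x$slope,
    r_squared = x$r_squared, pec50 = x$pec50, pec50_valid = x$pec50_valid,
    accepted = x$accepted, converged = x$converged
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit>\n")
  if (!x$converged) {
    cat(sprintf("  direction = %s, not fitted\n", x$direction))
  } else {
    cat(sprintf("  direction = %s, pEC50 = %.2f (%s), slope = %.2f, R^2 = %.3f\n",
                x$direction, x$pec50, if (x$pec50_valid) "valid" else "invalid",
                x$slope, x$r_squared))
  }
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.dose_response_fit <- function(object, ...) {
  df <- filter(object$data, .data$concentration > 0)
  df$x <- log10(df$concentration)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log10 concentration (M)", y = "Apparent stability (0-1)")
  if (object$converged) {
    grid <- tibble(x = seq(min(df$x) - 0.5, max(df$x) + 0.5, length.out = 200))
    grid$y <- dose_response_curve(grid$x, object$logec50, object$slope)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$logec50, linetype = "dashed")
  }
  p
}

#' Replicate scatterplot of mPDP fold changes with significance highlighting
#'
#' Plots replicate 2 versus replicate 1 log2 fold changes per condition and
#' pool; significantly regulated proteins are drawn in red, the dashed
#' diagonal is the equality line.
#'
#' @param significance Output of [mpdp_significance()].
#' @return A ggplot object faceted by condition and pool.
#' @export
plot_replicate_scatter <- function(significance) {
  check_columns(significance,
                c("log2_fc_rep1", "log2_fc_rep2", "significant", "condition", "pool"),
                "significance table")
  ggplot2::ggplot(significance,
                  ggplot2::aes(x = .data$log2_fc_rep1, y = .data$log2_fc_rep2,
                               colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::facet_grid(pool ~ condition) +
    ggplot2::labs(x = "log2 FC replicate 1", y = "log2 FC replicate 2")
}
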