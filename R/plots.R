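#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_errorbar geom_hline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot the probability mass function of a distribution specification
#'
#' @param object A [count_dist()] or [binary_dist()].
#' @param xmax Largest outcome shown (counts default to the 0.9999
#'   quantile region; binary families to `size`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.count_dist <- function(object, xmax = NULL, ...) {
  if (is.null(xmax)) {
    mm <- dist_moments(object)
    xmax <- ceiling(mm$mean + 6 * sqrt(mm$variance))
  }
  x <- 0:xmax
  df <- tibble(x = x, probability = dist_pmf(object, x))
  ggplot(df, aes(x = .data$x, y = .data$probability)) +
    geom_col(width = 0.8) +
    labs(x = "count", y = "probability",
         title = sprintf("%s (mu = %g%s%s)", object$family, object$mu,
                         if (!is.null(object$dispersion))
                           sprintf(", dispersion = %g", object$dispersion)
                         else "",
                         if (object$delta > 0)
                           sprintf(", delta = %g", object$delta) else "")) +
    theme_minimal()
}

#' @rdname autoplot.count_dist
#' @export
autoplot.binary_dist <- function(object, xmax = NULL, ...) {
  x <- 0:(xmax %||% object$size)
  df <- tibble(x = x, probability = dist_pmf(object, x))
  ggplot(df, aes(x = .data$x, y = .data$probability)) +
    geom_col(width = 0.8) +
    labs(x = "number present", y = "probability", title = object$family) +
    theme_minimal()
}

#' Plot a Monte-Carlo power curve
#'
#' Power against replication level with pointwise Monte-Carlo standard
#' error bars and a reference line at the target power.
#'
#' @param object A `power_curve` from [estimate_power()].
#' @param target Reference power line (default 0.80).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_curve <- function(object, target = 0.80, ...) {
  ggplot(object, aes(x = .data$n_replicates, y = .data$power)) +
    geom_hline(yintercept = target, linetype = 2, colour = "grey50") +
    geom_errorbar(aes(ymin = pmax(0, .data$power - .data$se),
                      ymax = pmin(1, .data$power + .data$se)), width = 0.5) +
    geom_line() + geom_point() +
    labs(x = "replications N", y = "rejection fraction",
         title = unique(object$analysis)) +
    theme_minimal()
}

#' Per-variety response summary plot of a simulated dataset
#'
#' @param ds A dataset from [simulate_dataset()].
#' @return A ggplot object: response distributions by variety (faceted by
#'   time point when repeated measures are present).
#' @export
plot_trial_counts <- function(ds) {
  p <- ggplot(ds, aes(x = .data$variety, y = .data$response)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    labs(x = NULL, y = "response") + theme_minimal()
  if ("time" %in% names(ds) && length(unique(ds$time)) > 1)
    p <- p + facet_wrap(~time)
  p
}
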