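#' @export
print.soarhmm_fit <- function(x, ...) {
  cat(sprintf("<soarhmm fit: %d states, features %s%s>\n",
              x$params$n_states, paste(x$feature_set, collapse = "/"),
              if (!is.null(x$covariate))
                paste0(", covariate on transitions (",
                       paste(x$cov_levels, collapse = ", "), ")") else ""))
  cat(sprintf("  loglik %.2f | AIC %.2f | %d free parameters | n = %d\n",
              x$loglik, x$aic, x$n_par, x$n_obs))
  cat(sprintf("  %d/%d restarts within 1e-3 of the optimum\n",
              x$n_stable, nrow(x$restarts)))
  print(x$params)
  invisible(x)
}

#' Tidy a fitted HMM
#'
#' One row per state, feature, and Weibull parameter plus the implied state
#' mean (`scale * gamma(1 + 1/shape)`), broom-style.
#'
#' @param x a [fit_hmm()] result.
#' @param ... unused.
#' @return Tibble with `state`, `feature`, `shape`, `scale`, `mean`.
#' @export
tidy.soarhmm_fit <- function(x, ...) {
  p <- x$params
  tidyr::expand_grid(state = p$state_names, feature = p$features) |>
    dplyr::mutate(
      shape = as.numeric(t(p$shape)),
      scale = as.numeric(t(p$scale)),
      mean = .data$scale * gamma(1 + 1 / .data$shape)
    )
}

#' One-line model summary
#'
#' @param x a [fit_hmm()] result.
#' @param ... unused.
#' @return One-row tibble: `n_states`, `n_features`, `n_par`, `n_obs`,
#'   `loglik`, `aic`, `n_stable`, `n_restarts`.
#' @export
glance.soarhmm_fit <- function(x, ...) {
  tibble::tibble(
    n_states = x$params$n_states, n_features = length(x$feature_set),
    n_par = x$n_par, n_obs = x$n_obs, loglik = x$loglik, aic = x$aic,
    n_stable = x$n_stable, n_restarts = nrow(x$restarts)
  )
}

#' State-dependent feature densities over the data
#'
#' The standard HMM diagnostic figure: per-feature histograms of the
#' observed windows overlaid with the fitted per-state Weibull densities
#' weighted by state occupancy.
#'
#' @param object a [fit_hmm()] result.
#' @param features the feature tibble the model was fitted to.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.soarhmm_fit <- function(object, features, ...) {
  p <- object$params
  obs <- features |>
    dplyr::select(dplyr::all_of(p$features)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "feature",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  occ <- prop.table(table(factor(
    viterbi_decode(features, p,
                   covariate = object$covariate)$state,
    levels = p$state_names
  )))
  dens <- dplyr::bind_rows(lapply(seq_along(p$features), function(fi) {
    f <- p$features[fi]
    v <- obs$value[obs$feature == f]
    x <- seq(max(min(v), 1e-6), max(v), length.out = 300)
    dplyr::bind_rows(lapply(seq_len(p$n_states), function(s) {
      tibble::tibble(
        feature = f, x = x, state = p$state_names[s],
        density = as.numeric(occ[s]) *
          dweibull(x, p$shape[s, fi], p$scale[s, fi])
      )
    }))
  }))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey85", color = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    color = .data$state),
                       linewidth = 0.8) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "density", color = "state") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object a [confusion_matrix()] result.
#' @param ... unused.
#' @return A ggplot object (tiles of column percentages).
#' @export
autoplot.soarhmm_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(object$col_pct))
  names(df) <- c("assigned", "true", "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$assigned,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(
      x = "true state", y = "assigned state", fill = "%",
      subtitle = sprintf("overall accuracy %.1f%% (%.1f, %.1f)",
                         object$accuracy, object$ci[1], object$ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Activity-budget bar chart per individual
#'
#' @param budgets an [activity_budget()] tibble.
#' @return A ggplot object.
#' @export
plot_budgets <- function(budgets) {
  ggplot2::ggplot(budgets,
                  ggplot2::aes(x = .data$individual_id, y = .data$pct,
                               fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of windows", fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
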