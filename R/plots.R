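#' Plot per-arm error rates with confidence intervals
#'
#' Error-bar chart of mean replicate test error per experimental arm, the
#' standard way to compare the entropy selection against the direct and
#' control arms.
#'
#' @param object An `ms_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_experiment <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$arm, y = .data$mean_error)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      width = 0.2
    ) +
    ggplot2::labs(
      x = NULL, y = "Mean test error rate",
      title = "Classification error by CpG-selection arm",
      subtitle = sprintf(
        "l = %d prefiltered CpGs, q = %d selected; 95%% t-intervals over replicates",
        object$sizes$l, object$sizes$q
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an ROC curve
#'
#' @param object An `ms_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of a per-CpG entropy profile
#'
#' Shows the distribution of Shannon entropies (bits) across CpGs, with the
#' top-fraction selection threshold marked when a fraction is given.
#'
#' @param profile A `cpg_entropy` tibble from [cpg_entropy()].
#' @param fraction Optional selection fraction whose entropy cutoff is drawn.
#' @return A ggplot object.
#' @export
plot_entropy_profile <- function(profile, fraction = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$entropy)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::labs(
      x = "Shannon entropy (bits)", y = "CpG count",
      title = "Per-CpG discretized Shannon entropy"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fraction)) {
    sel <- select_top_fraction(profile, fraction)
    cutoff <- min(sel$entropy)
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  }
  p
}

#' @export
tidy.ms_net <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::expand_grid(
      layer = "hidden",
      unit = seq_along(x$b1),
      feature = c(x$feature_names, "(bias)")
    ) |>
      dplyr::mutate(weight = as.numeric(t(cbind(x$W1, x$b1)))),
    tibble(
      layer = "output", unit = 1L,
      feature = c(paste0("hidden_", seq_along(x$w2)), "(bias)"),
      weight = c(x$w2, x$b2)
    )
  )
}

#' @export
glance.ms_net <- function(x, ...) {
  tibble(
    n_inputs = ncol(x$W1),
    hidden_units = length(x$b1),
    trainer = x$config$trainer,
    n_epochs = x$n_epochs,
    converged = x$converged,
    final_loss = x$final_loss
  )
}
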