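#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated quantity,
#' `glance()` a one-row model summary.
#'
#' @param x,object A fitted object.
#' @param ... Unused.
#'
#' @return A tibble.
#' @name posembed-tidiers
NULL

#' @rdname posembed-tidiers
#' @method tidy dirichlet_mixture_fit
#' @export
tidy.dirichlet_mixture_fit <- function(x, ...) {
  mix <- x$mixture
  ab <- if (ncol(mix$alpha) == 20) as.character(alphabet("3Di")) else
    as.character(seq_len(ncol(mix$alpha)))
  tibble(
    component = rep(seq_len(mix$K), each = ncol(mix$alpha)),
    weight = rep(mix$q, each = ncol(mix$alpha)),
    symbol = rep(ab, times = mix$K),
    alpha = as.vector(t(mix$alpha)),
    mean = as.vector(t(mix$alpha / rowSums(mix$alpha)))
  )
}

#' @rdname posembed-tidiers
#' @method glance dirichlet_mixture_fit
#' @export
glance.dirichlet_mixture_fit <- function(x, ...) {
  tibble(K = x$K, n_columns = x$n_columns, logLik = x$loglik,
         iterations = length(x$trace), converged = x$converged)
}

#' @rdname posembed-tidiers
#' @method tidy threedi_head_fit
#' @export
tidy.threedi_head_fit <- function(x, ...) {
  x$history
}

#' @rdname posembed-tidiers
#' @method glance threedi_head_fit
#' @export
glance.threedi_head_fit <- function(x, ...) {
  n <- nrow(x$history)
  tibble(n_batches = n,
         final_loss = x$history$loss[n],
         final_accuracy = x$history$accuracy[n],
         final_learning_rate = x$history$learning_rate[n],
         n_parameters = n_parameters(x$model))
}

#' @rdname posembed-tidiers
#' @method autoplot threedi_head_fit
#' @export
autoplot.threedi_head_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                           names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(.data$batch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "batch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname posembed-tidiers
#' @method autoplot sensitivity_summary
#' @export
autoplot.sensitivity_summary <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$s, .data$n_queries,
                               colour = .data$level)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "sensitivity to first false positive",
                  y = "queries attaining at least this sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot identity-binned top-hit accuracy
#'
#' @param x A [tophit_accuracy()] table (or several row-bound together with
#'   a `method` column).
#' @param ... Unused.
#'
#' @return A ggplot.
#' @export
plot_tophit_accuracy <- function(x, ...) {
  mapping <- if ("method" %in% names(x)) {
    ggplot2::aes(.data$bin, .data$accuracy, colour = .data$method,
                 group = .data$method)
  } else {
    ggplot2::aes(.data$bin, .data$accuracy, group = 1)
  }
  ggplot2::ggplot(x, mapping) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = "percent identity to nearest training sequence",
                  y = "top-hit accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
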