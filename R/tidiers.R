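# broom-style accessors for the fitted objects

#' Tidy a structured-component fit
#'
#' One row per integration set with the set effect on the unit-variance
#' component scale, the direct miRNA weight and the target count.
#'
#' @param x a `mimi_surv_fit`.
#' @param ... unused.
#' @return tibble with columns `miRNA`, `beta`, `gamma0`, `n_mRNAs`.
#' @method tidy mimi_surv_fit
#' @export
tidy.mimi_surv_fit <- function(x, ...) {
  nm <- x$w |> count(.data$miRNA, name = "n_mRNAs")
  tibble(miRNA = names(x$beta), beta = as.numeric(x$beta)) |>
    left_join(x$gamma0, by = "miRNA") |>
    left_join(nm, by = "miRNA")
}

#' Glance at a structured-component fit
#'
#' @param x a `mimi_surv_fit`.
#' @param ... unused.
#' @return one-row tibble with the objective, dimensions and convergence
#'   information.
#' @method glance mimi_surv_fit
#' @export
glance.mimi_surv_fit <- function(x, ...) {
  tibble(objective = tail(x$objective_trace, 1),
         n_sets = length(x$beta), n_pairs = nrow(x$w),
         nobs = x$nobs, nevent = x$nevent,
         iterations = x$iterations, converged = x$converged,
         penalty_w = x$penalty_w$kind, lambda_w = x$penalty_w$lambda,
         penalty_b = x$penalty_b$kind, lambda_b = x$penalty_b$lambda)
}

#' @rdname tidy.mimi_surv_fit
#' @method tidy cox_pen_fit
#' @export
tidy.cox_pen_fit <- function(x, ...) {
  tibble(term = names(x$coef) %||% paste0("x", seq_along(x$coef)),
         estimate = as.numeric(x$coef))
}

#' @rdname glance.mimi_surv_fit
#' @method glance cox_pen_fit
#' @export
glance.cox_pen_fit <- function(x, ...) {
  tibble(loglik = x$loglik, objective = x$objective,
         penalty = x$penalty$kind, lambda = x$penalty$lambda,
         nobs = x$nobs, nevent = x$nevent,
         iterations = x$iterations, converged = x$converged,
         separation = x$separation)
}

#' Tidy a permutation test result
#'
#' @param x a `mimi_surv_test`.
#' @param ... unused.
#' @return the results tibble (one row per miRNA and penalty).
#' @method tidy mimi_surv_test
#' @export
tidy.mimi_surv_test <- function(x, ...) x$results

#' Glance at a permutation test result
#'
#' @param x a `mimi_surv_test`.
#' @param ... unused.
#' @return one-row tibble with test dimensions and discovery counts.
#' @method glance mimi_surv_test
#' @export
glance.mimi_surv_test <- function(x, ...) {
  tibble(n_sets = length(x$mirnas), B = x$B,
         q_threshold = x$q_threshold,
         n_significant = sum(x$results$significant))
}

#' Plot the objective trace and set effects of a fit
#'
#' Left panel: penalized objective after each half-step (non-decreasing by
#' construction). Right panel: set effects on the unit-variance component
#' scale.
#'
#' @param object a `mimi_surv_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mimi_surv_fit
#' @export
autoplot.mimi_surv_fit <- function(object, ...) {
  df <- tibble(half_step = seq_along(object$objective_trace),
               objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$half_step, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "ALS half-step", y = "penalized objective",
                  title = "Block-ascent objective trace") +
    ggplot2::theme_minimal()
}

#' Plot per-set effects and permutation p-values
#'
#' @param object a `mimi_surv_test`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mimi_surv_test
#' @export
autoplot.mimi_surv_test <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(.data$miRNA, .data$beta,
                               fill = -log10(.data$p))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~penalty) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "set effect (unit-variance component scale)",
                  fill = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Plot rejection rates from a simulation study
#'
#' @param x output of [estimate_type1_error()].
#' @param alpha nominal level drawn as a reference line.
#' @return a ggplot object.
#' @export
plot_rejection_rates <- function(x, alpha = 0.05) {
  ggplot2::ggplot(x, ggplot2::aes(.data$method, .data$rate)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - .data$mc_sd,
                                        ymax = .data$rate + .data$mc_sd),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::labs(y = "rejection rate") +
    ggplot2::theme_minimal()
}
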