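#' Tidy an LDG solution into per-coefficient rows
#'
#' @param x an `"ldg_solution"`.
#' @param ... unused.
#' @return a tibble with one row per (element, basis degree): columns
#'   `element`, `node_left`, `node_right`, `basis_index`, `alpha`, `beta`.
#' @export
tidy.ldg_solution <- function(x, ...) {
  r <- x$control$r
  J <- x$mesh$J
  tibble::tibble(
    element = rep(seq_len(J), each = r + 1L),
    node_left = rep(x$mesh$nodes[seq_len(J)], each = r + 1L),
    node_right = rep(x$mesh$nodes[seq_len(J) + 1L], each = r + 1L),
    basis_index = rep(0:r, J),
    alpha = as.vector(x$alpha),
    beta = as.vector(x$beta))
}

#' One-row summary of an LDG solution
#'
#' @param x an `"ldg_solution"`.
#' @param ... unused.
#' @return a tibble with the configuration, the downwind value
#'   \eqn{Z_0(T^-)}, the absolute error against the exact reference when
#'   one exists (`NA` otherwise), and the worst-element Newton iteration
#'   count.
#' @export
glance.ldg_solution <- function(x, ...) {
  p <- x$problem
  dw <- sum(x$alpha[, x$mesh$J])
  err <- tryCatch(absolute_error(p, dw, p$T), error = function(e) NA_real_)
  tibble::tibble(model = p$model, nu = p$nu, sigma = p$sigma, x0 = p$x0,
                 T = p$T, r = x$control$r, J = x$mesh$J,
                 nonlinear = if (p$model == "logistic") x$control$nonlinear
                 else NA_character_,
                 downwind = dw, abs_error = err,
                 max_newton_iterations = max(x$newton_iterations))
}

#' Plot an LDG solution
#'
#' Dense-sampled \eqn{Z_0(t)} per element (drawn piecewise so interface
#' jumps stay visible), with the exact reference overlaid when available.
#'
#' @param object an `"ldg_solution"`.
#' @param n sample points per element.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ldg_solution <- function(object, n = 50L, ...) {
  grid <- solution_grid(object, n = n)
  grid$element <- rep(seq_len(object$mesh$J), each = n)
  pl <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$Z0,
                                           group = .data$element)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "t", y = "X(t)",
                  title = sprintf("LDG solution (%s model, nu = %g, r = %d, J = %d)",
                                  object$problem$model, object$problem$nu,
                                  object$control$r, object$mesh$J)) +
    ggplot2::theme_minimal()
  ex <- tryCatch(exact_solution(object$problem, grid$t),
                 error = function(e) NULL)
  if (!is.null(ex))
    pl <- pl + ggplot2::geom_line(
      data = tibble::tibble(t = grid$t, Z0 = ex, element = 0L),
      linetype = "dashed", colour = "grey30")
  pl
}

#' Plot a convergence study
#'
#' Log-log error-versus-step plot; the slope is the estimated order of
#' convergence.
#'
#' @param object an `"ldg_convergence"` tibble from [convergence_study()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ldg_convergence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h, y = .data$error)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step h", y = "absolute error at T",
                  title = sprintf("%s convergence", attr(object, "solver"))) +
    ggplot2::theme_minimal()
}
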