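#' Exact reference value for a problem
#'
#' Dispatches to the Mittag-Leffler closed form for the linear model (any
#' order) or the logistic closed form (classical order only).
#'
#' @param problem an [fle_problem()].
#' @param t times (vectorised).
#' @return numeric vector of exact solution values.
#' @export
exact_solution <- function(problem, t) {
  stopifnot(inherits(problem, "fle_problem"))
  if (problem$model == "linear")
    exact_linear_solution(problem$nu, problem$sigma, problem$x0, t)
  else if (problem$nu == 1)
    exact_logistic_solution(problem$sigma, problem$x0, t)
  else
    stop("no exact reference for the logistic model with nu < 1.",
         call. = FALSE)
}

#' Absolute error against the exact reference
#'
#' @inheritParams exact_solution
#' @param approx_value numerical value(s) at time `t`.
#' @return `|X(t) - approx_value|`.
#' @export
absolute_error <- function(problem, approx_value, t) {
  abs(exact_solution(problem, t) - approx_value)
}

#' Estimated order of convergence under mesh halving
#'
#' For errors \eqn{E_a(h), E_a(h/2), \dots} on successively halved steps,
#' the estimated order is \eqn{\mathrm{EOC} = \log_2(E_a(h)/E_a(h/2))};
#' element `k` of the result is `log2(errors[k]/errors[k+1])`.
#'
#' @param errors positive absolute errors, ordered from coarsest mesh.
#' @return numeric vector one shorter than `errors`.
#' @export
eoc <- function(errors) {
  if (length(errors) < 2L) return(numeric(0))
  if (any(!is.finite(errors) | errors <= 0))
    stop("all errors must be positive to form an EOC.", call. = FALSE)
  log2(errors[-length(errors)] / errors[-1L])
}

solver_value_at_T <- function(problem, solver, r, J, nonlinear, history) {
  if (solver == "ldg") {
    sol <- ldg_solve(problem, ldg_control(r = r, J = J, nonlinear = nonlinear,
                                          history = history))
    sum(sol$alpha[, J])
  } else if (solver == "pece") {
    traj <- pece_abm(problem, J)
    traj$X[nrow(traj)]
  } else {
    traj <- l1_scheme(problem, J)
    traj$X[nrow(traj)]
  }
}

#' Convergence study under mesh doubling
#'
#' Runs a solver over a sequence of element/step counts and tabulates the
#' value at the horizon, its absolute error against the exact reference,
#' and the estimated order of convergence.
#'
#' @param problem an [fle_problem()] with an exact reference (linear any
#'   order; logistic classical order only).
#' @param J element/step counts, ordered and doubling for meaningful EOC.
#' @param solver `"ldg"`, `"pece"` or `"l1"`.
#' @param r LDG polynomial degree (ignored for the step methods).
#' @param nonlinear,history passed to [ldg_control()].
#' @return a tibble with columns `J`, `h`, `value`, `error`, `eoc` (first
#'   row `NA`), carrying the run metadata as attributes; class
#'   `"ldg_convergence"` for [autoplot()].
#' @export
convergence_study <- function(problem, J = 2^(0:4), solver = c("ldg", "pece", "l1"),
                              r = 2, nonlinear = "dc", history = "literal") {
  solver <- match.arg(solver)
  vals <- vapply(J, function(Jl)
    solver_value_at_T(problem, solver, r, Jl, nonlinear, history), numeric(1))
  errs <- absolute_error(problem, vals, problem$T)
  out <- tibble::tibble(J = as.integer(J), h = problem$T / J, value = vals,
                        error = errs, eoc = c(NA_real_, eoc(errs)))
  attr(out, "solver") <- solver
  attr(out, "problem") <- problem
  attr(out, "r") <- r
  class(out) <- c("ldg_convergence", class(out))
  out
}

#' Reproduce the headline convergence tables
#'
#' Re-runs the four benchmark configurations from scratch:
#' * `"table1"` -- linear model, classical order (`nu = 1`, `sigma = 1`,
#'   `X0 = 0.75`, `T = 2`): LDG with `r = 2` versus PECE, `J = 1..128`
#'   doubling, with absolute errors and EOC for each.
#' * `"table2"` -- linear model at `nu = 0.75` and `nu = 0.5` on `[0, 1]`:
#'   single-element LDG with `r = 5` versus the L1 scheme at `h = 1/1000`,
#'   evaluated at `t = 0.2, 0.4, ..., 1.0`, with the Mittag-Leffler exact
#'   column.
#' * `"table3"` / `"table4"` -- logistic model (`nu = 1`, `sigma = 0.5`,
#'   `X0 = 0.5`, `T = 1`): LDG with `r = 1` / `r = 2`, product
#'   approximation versus direct computation, `J = 1, 2, 4`.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return a tibble (layout depends on the table).
#' @export
reproduce_table <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  switch(name,
    table1 = {
      prob <- fle_problem("linear", nu = 1, sigma = 1, x0 = 0.75, T = 2)
      Js <- 2^(0:7)
      ldg <- convergence_study(prob, Js, solver = "ldg", r = 2)
      pec <- convergence_study(prob, Js, solver = "pece")
      tibble::tibble(J = Js,
                     ldg_value = ldg$value, ldg_error = ldg$error,
                     ldg_eoc = ldg$eoc,
                     pece_value = pec$value, pece_error = pec$error,
                     pece_eoc = pec$eoc)
    },
    table2 = {
      ts <- seq(0.2, 1, by = 0.2)
      out <- lapply(c(0.75, 0.5), function(nu) {
        prob <- fle_problem("linear", nu = nu, sigma = 1, x0 = 0.75, T = 1)
        sol <- ldg_solve(prob, ldg_control(r = 5, J = 1))
        traj <- l1_scheme(prob, 1000L)
        tibble::tibble(nu = nu, t = ts,
                       ldg = evaluate_solution(sol, ts, side = "left"),
                       l1 = traj$X[match(round(ts * 1000), round(traj$t * 1000))],
                       exact = exact_solution(prob, ts))
      })
      do.call(rbind, out)
    },
    table3 = logistic_table(r = 1),
    table4 = logistic_table(r = 2))
}

logistic_table <- function(r) {
  prob <- fle_problem("logistic", nu = 1, sigma = 0.5, x0 = 0.5, T = 1)
  Js <- c(1L, 2L, 4L)
  pa <- convergence_study(prob, Js, solver = "ldg", r = r, nonlinear = "pa")
  dc <- convergence_study(prob, Js, solver = "ldg", r = r, nonlinear = "dc")
  tibble::tibble(J = Js,
                 pa_value = pa$value, pa_error = pa$error, pa_eoc = pa$eoc,
                 dc_value = dc$value, dc_error = dc$error, dc_eoc = dc$eoc)
}
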