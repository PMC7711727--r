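#' Define a fractional growth/logistic problem
#'
#' Bundles the continuous problem: the Liouville-Caputo initial-value
#' problem \eqn{D^\nu X = \sigma^\nu X} (`model = "linear"`, the
#' fractional Malthus model) or \eqn{D^\nu X = \sigma X (1 - X)}
#' (`model = "logistic"`, the fractional Verhulst model with population
#' normalised to carrying capacity 1), with \eqn{X(0) = X_0} on
#' \eqn{[0, T]}.
#'
#' The linear model carries the rate as \eqn{\sigma^\nu} and the logistic
#' model as plain \eqn{\sigma}, matching the form in which each equation is
#' posed; the two coincide for \eqn{\sigma = 1}.  For a negative rate with
#' fractional order the linear model uses
#' \eqn{\mathrm{sign}(\sigma)|\sigma|^\nu} (decay branch).
#'
#' @param model `"linear"` or `"logistic"`.
#' @param nu fractional order in (0, 1].
#' @param sigma growth rate (1/time).
#' @param x0 initial value; for the logistic model values outside \[0, 1\]
#'   trigger a warning (the closed-form reference assumes the normalised
#'   range).
#' @param T time horizon, `T > 0`.
#' @return an object of class `"fle_problem"`.
#' @examples
#' fle_problem("linear", nu = 1, sigma = 1, x0 = 0.75, T = 2)
#' @export
fle_problem <- function(model = c("linear", "logistic"), nu = 1, sigma = 1,
                        x0 = 0.5, T = 1) {
  model <- match.arg(model)
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu > 1)
    stop("`nu` must lie in (0, 1].", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("`T` must be positive.", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma))
    stop("`sigma` must be a finite scalar.", call. = FALSE)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0))
    stop("`x0` must be a finite scalar.", call. = FALSE)
  if (model == "logistic" && (x0 < 0 || x0 > 1))
    warning("logistic model with x0 outside [0, 1]; the normalised model ",
            "assumes 0 <= x0 <= 1.", call. = FALSE)
  structure(list(model = model, nu = nu, sigma = sigma, x0 = x0, T = T),
            class = "fle_problem")
}

#' @export
print.fle_problem <- function(x, ...) {
  cat(sprintf("<fle_problem> %s model: D^%g X = %s, X(0) = %g on [0, %g]\n",
              x$model, x$nu,
              if (x$model == "linear") sprintf("%g^%g X", x$sigma, x$nu)
              else sprintf("%g X (1 - X)", x$sigma),
              x$x0, x$T))
  invisible(x)
}

#' Solver configuration for the LDG scheme
#'
#' @param r polynomial degree per element, `0 <= r <= 12` (monomial
#'   conditioning is unacceptable beyond 12).
#' @param J number of mesh elements, `J >= 1`.
#' @param nonlinear treatment of the logistic square: `"dc"` (direct
#'   computation through the triple-product tensor, exact Galerkin
#'   integrals) or `"pa"` (product approximation: the expansion with
#'   squared coefficients).  Ignored for the linear model.
#' @param history anchoring of the fractional integral across elements:
#'   `"literal"` (globally anchored element matrices, no history load --
#'   the local system as printed) or `"corrected"` (locally anchored
#'   matrices plus explicit convolution history from earlier elements).
#'   The two coincide when `nu = 1` or `J = 1`.
#' @param newton_tol max-norm residual tolerance of the per-element Newton
#'   iteration (logistic model).
#' @param newton_max_iter Newton iteration cap.
#' @return an object of class `"ldg_control"`.
#' @export
ldg_control <- function(r = 2, J = 1, nonlinear = c("dc", "pa"),
                        history = c("literal", "corrected"),
                        newton_tol = 1e-13, newton_max_iter = 50L) {
  nonlinear <- match.arg(nonlinear)
  history <- match.arg(history)
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r != round(r) || r > 12)
    stop("`r` must be an integer in 0..12.", call. = FALSE)
  if (!is.numeric(J) || length(J) != 1L || J < 1 || J != round(J))
    stop("`J` must be a positive integer.", call. = FALSE)
  if (!is.numeric(newton_tol) || newton_tol <= 0)
    stop("`newton_tol` must be positive.", call. = FALSE)
  structure(list(r = as.integer(r), J = as.integer(J), nonlinear = nonlinear,
                 history = history, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter)),
            class = "ldg_control")
}

#' Mesh of the time interval
#'
#' Partition \eqn{0 = t_0 < t_1 < \dots < t_J = T}.  Uniform by default
#' (`h = T/J`); arbitrary strictly increasing node vectors are accepted.
#'
#' @param T horizon (ignored when `nodes` is given).
#' @param J number of elements (ignored when `nodes` is given).
#' @param nodes optional full node vector starting at 0.
#' @return an object of class `"ldg_mesh"` with fields `nodes`, `J`, `h`
#'   (element lengths) and `hmax`.
#' @export
ldg_mesh <- function(T = 1, J = 1, nodes = NULL) {
  if (is.null(nodes)) nodes <- seq(0, T, length.out = J + 1L)
  if (nodes[1] != 0 || any(diff(nodes) <= 0))
    stop("mesh nodes must start at 0 and be strictly increasing.",
         call. = FALSE)
  h <- diff(nodes)
  structure(list(nodes = nodes, J = length(h), h = h, hmax = max(h)),
            class = "ldg_mesh")
}

## ---- local element solves -------------------------------------------------

## operators shared by linear and Newton element solves
element_operators <- function(problem, control, element, inflow,
                              need_tensor = FALSE) {
  r <- control$r
  mode <- if (control$history == "literal") "paper_literal" else
    "history_corrected"
  fl <- flux_operators(r, inflow)
  list(M = mass_matrix(r, element),
       S = stiffness_matrix(r, element),
       E = fl$E, b = fl$b,
       D = fractional_matrix(r, element, problem$nu, mode),
       T3 = if (need_tensor) triple_product_tensor(r, element))
}

#' Assemble the local element system
#'
#' Builds the coupled \eqn{2(r+1)} algebraic system of one element: the
#' flux block \eqn{M\beta + (S - E)\alpha = b} and the fractional block
#' \eqn{D\beta = \lambda M \alpha} (linear model, \eqn{\lambda =
#' \mathrm{sign}(\sigma)|\sigma|^\nu}) or \eqn{D\beta + H = \sigma(M\alpha
#' - n(\alpha))} (logistic model), where \eqn{n(\alpha)} is the Galerkin
#' square by direct computation or product approximation and \eqn{H} is
#' the history load (zero in `"literal"` history mode and on the first
#' element).  Returned as the operator list plus a residual closure; mainly
#' useful for inspection and testing -- [ldg_solve()] drives it.
#'
#' @param problem an [fle_problem()].
#' @param control an [ldg_control()].
#' @param element numeric `c(lower, upper)`.
#' @param inflow_value upwind trace from the previous element.
#' @param history_load optional length `r+1` vector \eqn{H}.
#' @return list with the operator matrices (`M`, `S`, `E`, `D`, `b`,
#'   optionally `T3`), the rate `lambda`/`sigma`, and `residual(alpha,
#'   beta)`.
#' @export
assemble_local_system <- function(problem, control, element, inflow_value,
                                  history_load = NULL) {
  r <- control$r
  if (is.null(history_load)) history_load <- numeric(r + 1L)
  ops <- element_operators(problem, control, element, inflow_value,
                           need_tensor = problem$model == "logistic" &&
                             control$nonlinear == "dc")
  if (problem$model == "linear") {
    lam <- sign(problem$sigma) * abs(problem$sigma)^problem$nu
    ops$lambda <- lam
    ops$residual <- function(alpha, beta)
      c(ops$M %*% beta + (ops$S - ops$E) %*% alpha - ops$b,
        ops$D %*% beta + history_load - lam * ops$M %*% alpha)
  } else {
    sg <- problem$sigma
    nfun <- nonlinear_term(ops, control)
    ops$sigma <- sg
    ops$nonlinear <- nfun
    ops$residual <- function(alpha, beta)
      c(ops$M %*% beta + (ops$S - ops$E) %*% alpha - ops$b,
        ops$D %*% beta + history_load -
          sg * (ops$M %*% alpha - nfun$value(alpha)))
  }
  ops$history_load <- history_load
  ops
}

## Galerkin square of the expansion and its Jacobian
nonlinear_term <- function(ops, control) {
  if (control$nonlinear == "pa") {
    list(value = function(a) drop(ops$M %*% (a * a)),
         jacobian = function(a) ops$M %*% diag(2 * a, length(a)))
  } else {
    T3 <- ops$T3
    n1 <- dim(T3)[1]
    list(value = function(a)
           vapply(1:n1, function(j) drop(crossprod(a, T3[, , j] %*% a)),
                  numeric(1)),
         jacobian = function(a) {
           Jn <- matrix(0, n1, n1)
           for (j in 1:n1) Jn[j, ] <- 2 * drop(T3[, , j] %*% a)
           Jn
         })
  }
}

## direct dense solve of the linear element system
solve_element_linear <- function(problem, control, element, inflow,
                                 history_load = NULL) {
  r <- control$r
  if (is.null(history_load)) history_load <- numeric(r + 1L)
  ops <- element_operators(problem, control, element, inflow)
  lam <- sign(problem$sigma) * abs(problem$sigma)^problem$nu
  A <- rbind(cbind(ops$S - ops$E, ops$M),
             cbind(-lam * ops$M, ops$D))
  rhs <- c(ops$b, -history_load)
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular local system on element [", element[1], ", ", element[2],
         "]: ", conditionMessage(e), call. = FALSE))
  list(alpha = sol[1:(r + 1L)], beta = sol[(r + 2L):(2L * r + 2L)],
       iterations = 0L, residuals = numeric(0))
}

## Newton iteration with analytic Jacobian for the logistic element system
solve_element_newton <- function(problem, control, element, inflow,
                                 history_load = NULL, initial_guess = NULL) {
  r <- control$r
  if (is.null(history_load)) history_load <- numeric(r + 1L)
  ops <- element_operators(problem, control, element, inflow,
                           need_tensor = control$nonlinear == "dc")
  sg <- problem$sigma
  nfun <- nonlinear_term(ops, control)
  ## inflow-constant start is an O(h)-accurate predictor keeping Newton in
  ## its quadratic basin; beta from the fractional block linearised there
  if (is.null(initial_guess)) {
    alpha <- c(inflow, numeric(r))
    beta <- drop(solve(ops$D, sg * (ops$M %*% alpha - nfun$value(alpha)) -
                         history_load))
  } else {
    alpha <- initial_guess$alpha
    beta <- initial_guess$beta
  }
  res_hist <- numeric(0)
  for (it in seq_len(control$newton_max_iter)) {
    Fv <- c(ops$M %*% beta + (ops$S - ops$E) %*% alpha - ops$b,
            ops$D %*% beta + history_load -
              sg * (ops$M %*% alpha - nfun$value(alpha)))
    res <- max(abs(Fv))
    res_hist <- c(res_hist, res)
    if (res < control$newton_tol)
      return(list(alpha = alpha, beta = beta, iterations = it - 1L,
                  residuals = res_hist))
    Jac <- rbind(cbind(ops$S - ops$E, ops$M),
                 cbind(-sg * (ops$M - nfun$jacobian(alpha)), ops$D))
    step <- tryCatch(solve(Jac, -Fv), error = function(e)
      stop("singular Newton system on element [", element[1], ", ",
           element[2], "]", call. = FALSE))
    alpha <- alpha + step[1:(r + 1L)]
    beta <- beta + step[(r + 2L):(2L * r + 2L)]
  }
  stop(sprintf(
    "Newton did not converge in %d iterations on element [%g, %g]; final residual %.3e",
    control$newton_max_iter, element[1], element[2],
    res_hist[length(res_hist)]), call. = FALSE)
}

## history load for element l in "corrected" mode:
##   H_j = < (1/Gamma(1-nu)) sum_{k<l} int_{L_k} (t-p)^{-nu} Z1|_{L_k}(p) dp,
##         L_j >_l
## Fully closed form: the inner convolution over element k reduces (u = t-p,
## binomial expansion) to powers (t - t_{k-1})^(q+1-nu) - (t - t_k)^(q+1-nu),
## and each outer integral int t^a L_j(t) (t-c)^pw dt is binomial-shifted to
## exact power integrals.  A Gauss outer rule is NOT usable here: the
## adjacent element contributes a weak (t - t_{l-1})^(1-nu) endpoint
## singularity that fixed-order quadrature only resolves to ~1e-4.
history_load_vector <- function(problem, control, mesh, l, beta_list) {
  r <- control$r
  nu <- problem$nu
  if (nu == 1 || l == 1L) return(numeric(r + 1L))
  tl0 <- mesh$nodes[l]
  tl1 <- mesh$nodes[l + 1L]
  el <- c(tl0, tl1)
  ## global monomial coefficients of L_j on element l
  Ljc <- lapply(0:r, monomial_coefficients, element = el, origin = "global")
  ## I(c, a, pw, j) = int_{tl0}^{tl1} t^a L_j(t) (t - c)^pw dt, exact
  outer_int <- function(c0, a, pw, j) {
    bj <- Ljc[[j + 1L]]
    deg <- a + j
    p <- numeric(deg + 1L)                  # coefficients of t^a * L_j
    p[a + seq_along(bj)] <- bj
    acc <- 0
    for (b in 0:deg) {                      # shift to powers of (t - c0)
      db <- 0
      for (n in b:deg)
        if (p[n + 1L] != 0)
          db <- db + p[n + 1L] * choose(n, b) * c0^(n - b)
      if (db == 0) next
      e <- b + pw + 1
      acc <- acc + db * ((tl1 - c0)^e - (tl0 - c0)^e) / e
    }
    acc
  }
  H <- numeric(r + 1L)
  for (k in seq_len(l - 1L)) {
    ek <- c(mesh$nodes[k], mesh$nodes[k + 1L])
    ## Z1 on element k as a global-coordinate monomial
    cz <- numeric(r + 1L)
    for (i in 0:r) {
      mc <- monomial_coefficients(i, ek, origin = "global")
      cz[seq_along(mc)] <- cz[seq_along(mc)] + beta_list[[k]][i + 1L] * mc
    }
    for (m in 0:r) {
      cm <- cz[m + 1L]
      if (cm == 0) next
      for (q in 0:m) {
        pw <- q + 1 - nu
        A <- cm * choose(m, q) * (-1)^q / pw
        for (j in 0:r)
          H[j + 1L] <- H[j + 1L] + A *
            (outer_int(ek[1], m - q, pw, j) - outer_int(ek[2], m - q, pw, j))
      }
    }
  }
  H / gamma(1 - nu)
}

#' Solve a fractional growth/logistic problem with the LDG scheme
#'
#' Marches the local discontinuous Galerkin discretization element by
#' element over the mesh: the equation is first rewritten as the
#' first-order system \eqn{z_1 = z_0'}, \eqn{I^{1-\nu} z_1 = \sigma z_0
#' g(z_0)}, both unknowns are expanded in shifted Legendre polynomials of
#' degree `r` per element, and upwind numerical fluxes couple an element
#' only to the downwind trace of its predecessor -- so each step inverts
#' (or Newton-solves) a local \eqn{2(r+1)} system rather than a global one.
#' Linear-model elements are solved by a direct dense solve; logistic
#' elements by Newton with analytic Jacobian.
#'
#' @param problem an [fle_problem()].
#' @param control an [ldg_control()].
#' @param mesh optional [ldg_mesh()]; defaults to a uniform mesh with
#'   `control$J` elements on `[0, problem$T]`.
#' @return an object of class `"ldg_solution"`: the mesh, per-element
#'   Legendre coefficient matrices `alpha` and `beta` (rows = degree 0..r,
#'   columns = elements), problem/control echoes, and per-element Newton
#'   diagnostics.  Evaluate it with [evaluate_solution()] or
#'   [solution_grid()], summarise with [tidy()]/[glance()], plot with
#'   [autoplot()].
#' @examples
#' prob <- fle_problem("linear", nu = 1, sigma = 1, x0 = 0.75, T = 2)
#' sol <- ldg_solve(prob, ldg_control(r = 2, J = 1))
#' evaluate_solution(sol, 2, side = "left")   # 5.625
#' @export
ldg_solve <- function(problem, control = ldg_control(), mesh = NULL) {
  stopifnot(inherits(problem, "fle_problem"), inherits(control, "ldg_control"))
  if (is.null(mesh)) mesh <- ldg_mesh(problem$T, control$J)
  stopifnot(inherits(mesh, "ldg_mesh"))
  if (abs(mesh$nodes[length(mesh$nodes)] - problem$T) > 1e-12 * problem$T)
    stop("mesh horizon does not match the problem horizon.", call. = FALSE)
  r <- control$r
  J <- mesh$J
  alpha <- matrix(0, r + 1L, J)
  beta <- matrix(0, r + 1L, J)
  iters <- integer(J)
  resids <- vector("list", J)
  inflow <- problem$x0
  beta_list <- list()
  for (l in seq_len(J)) {
    el <- c(mesh$nodes[l], mesh$nodes[l + 1L])
    H <- if (control$history == "corrected")
      history_load_vector(problem, control, mesh, l, beta_list)
    else numeric(r + 1L)
    sol <- tryCatch(
      if (problem$model == "linear")
        solve_element_linear(problem, control, el, inflow, H)
      else
        solve_element_newton(problem, control, el, inflow, H),
      error = function(e)
        stop("element ", l, ": ", conditionMessage(e), call. = FALSE))
    alpha[, l] <- sol$alpha
    beta[, l] <- sol$beta
    iters[l] <- sol$iterations
    resids[[l]] <- sol$residuals
    beta_list[[l]] <- sol$beta
    inflow <- sum(sol$alpha)   # Z0(t_l^-): all L_i equal 1 at the right node
  }
  structure(list(mesh = mesh, alpha = alpha, beta = beta,
                 problem = problem, control = control,
                 newton_iterations = iters, newton_residuals = resids),
            class = "ldg_solution")
}

#' Evaluate an LDG solution
#'
#' Piecewise-polynomial evaluation of the approximations \eqn{Z_0 \approx
#' X} (and optionally \eqn{Z_1 \approx X'}) by the Legendre recurrence.
#' The solution is discontinuous at interior nodes; `side` selects the
#' one-sided limit there (the left/downwind limit is the superconvergent
#' one and the value reported in all error tables).
#'
#' @param solution an `"ldg_solution"`.
#' @param t times in `[0, T]` (vectorised).
#' @param side `"left"` or `"right"` limit at mesh nodes.
#' @param which `"Z0"` or `"Z1"`.
#' @return numeric vector of solution values.
#' @export
evaluate_solution <- function(solution, t, side = c("left", "right"),
                              which = c("Z0", "Z1")) {
  stopifnot(inherits(solution, "ldg_solution"))
  side <- match.arg(side)
  which <- match.arg(which)
  nodes <- solution$mesh$nodes
  Tend <- nodes[length(nodes)]
  if (any(t < -1e-12 | t > Tend * (1 + 1e-12)))
    stop("`t` outside [0, ", Tend, "].", call. = FALSE)
  coef <- if (which == "Z0") solution$alpha else solution$beta
  vapply(t, function(tt) {
    l <- if (side == "left") findInterval(tt, nodes, left.open = TRUE)
    else findInterval(tt, nodes, rightmost.closed = TRUE)
    l <- min(max(l, 1L), solution$mesh$J)
    el <- c(nodes[l], nodes[l + 1L])
    s <- (2 * tt - el[1] - el[2]) / (el[2] - el[1])
    sum(vapply(0:solution$control$r,
               function(i) legendre_recurrence(i, s), numeric(1)) * coef[, l])
  }, numeric(1))
}

#' Monomial form of the solution on one element
#'
#' Collapses the Legendre expansion of \eqn{Z_0} (or \eqn{Z_1}) on an
#' element into dense monomial coefficients in global \eqn{t} (ascending
#' powers), e.g. for reporting the polynomial solution in closed form.
#'
#' @inheritParams evaluate_solution
#' @param element element index (1-based).
#' @return numeric vector `c0, c1, ..., cr` with
#'   \eqn{Z(t) = \sum_m c_m t^m} on the element.
#' @export
monomial_form <- function(solution, element = 1L, which = c("Z0", "Z1")) {
  stopifnot(inherits(solution, "ldg_solution"))
  which <- match.arg(which)
  r <- solution$control$r
  el <- c(solution$mesh$nodes[element], solution$mesh$nodes[element + 1L])
  coef <- if (which == "Z0") solution$alpha[, element] else
    solution$beta[, element]
  out <- numeric(r + 1L)
  for (i in 0:r) {
    mc <- monomial_coefficients(i, el, origin = "global")
    out[seq_along(mc)] <- out[seq_along(mc)] + coef[i + 1L] * mc
  }
  out
}

#' Dense sampling of an LDG solution
#'
#' @inheritParams evaluate_solution
#' @param n number of sample points per element.
#' @return a tibble with columns `t`, `Z0`, `Z1` (points are strictly
#'   interior to elements, so side selection does not arise).
#' @export
solution_grid <- function(solution, n = 50L) {
  stopifnot(inherits(solution, "ldg_solution"))
  nodes <- solution$mesh$nodes
  tt <- unlist(lapply(seq_len(solution$mesh$J), function(l) {
    a <- nodes[l]; b <- nodes[l + 1L]
    a + (b - a) * (seq_len(n) - 0.5) / n
  }))
  tibble::tibble(t = tt,
                 Z0 = evaluate_solution(solution, tt, which = "Z0"),
                 Z1 = evaluate_solution(solution, tt, which = "Z1"))
}

#' @export
print.ldg_solution <- function(x, ...) {
  p <- x$problem
  dw <- sum(x$alpha[, x$mesh$J])
  cat(sprintf("<ldg_solution> %s model, nu = %g, r = %d, J = %d (%s%s)\n",
              p$model, p$nu, x$control$r, x$mesh$J,
              if (p$model == "logistic")
                paste0(toupper(x$control$nonlinear), " nonlinear term, ")
              else "",
              paste0(x$control$history, " history")))
  cat(sprintf("  downwind value Z0(%g^-) = %.12g\n", p$T, dw))
  if (p$model == "logistic")
    cat(sprintf("  Newton iterations per element: %s\n",
                paste(x$newton_iterations, collapse = " ")))
  invisible(x)
}
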