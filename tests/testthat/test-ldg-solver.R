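lin_prob <- fle_problem("linear", nu = 1, sigma = 1, x0 = 0.75, T = 2)
log_prob <- fle_problem("logistic", nu = 1, sigma = 0.5, x0 = 0.5, T = 1)

test_that("problem and control constructors validate their inputs", {
  expect_error(fle_problem("linear", nu = 1.2), "\\(0, 1\\]")
  expect_error(fle_problem("linear", T = -1), "positive")
  expect_warning(fle_problem("logistic", x0 = 1.4), "\\[0, 1\\]")
  expect_error(ldg_control(r = 13), "0..12")
  expect_error(ldg_control(J = 0), "positive integer")
  expect_error(ldg_mesh(nodes = c(0, 0.5, 0.4)), "increasing")
  m <- ldg_mesh(2, 4)
  expect_equal(m$h, rep(0.5, 4))
})

test_that("single linear element reproduces the hand-eliminated system", {
  # r = 1 on [0, 2]: elimination of the 2x2 reduced system gives
  # alpha = (3/2, 9/4), downwind 15/4
  sol <- ldg_solve(lin_prob, ldg_control(r = 1, J = 1))
  expect_equal(sol$alpha[, 1], c(1.5, 2.25), tolerance = 1e-13)
  expect_equal(downwind(sol), 3.75, tolerance = 1e-13)
  # classical order: the fractional block collapses to beta = alpha scaled
  # by the rate, since D = M
  expect_equal(sol$beta[, 1], sol$alpha[, 1], tolerance = 1e-13)
})

test_that("quadratic and cubic single-element solves match the printed
          polynomial solutions", {
  expect_equal(downwind(ldg_solve(lin_prob, ldg_control(r = 2, J = 1))),
               5.625, tolerance = 1e-12)
  mono <- monomial_form(ldg_solve(lin_prob, ldg_control(r = 3, J = 1)))
  expect_equal(mono,
               c(0.7016129032, 1.0887096774, -0.1814516129, 0.4233870968),
               tolerance = 1e-10)
})

test_that("local system assembly exposes the documented nonlinear blocks", {
  el <- c(0, 2)
  ctl_pa <- ldg_control(r = 1, J = 1, nonlinear = "pa")
  ctl_dc <- ldg_control(r = 1, J = 1, nonlinear = "dc")
  prob <- fle_problem("logistic", nu = 1, sigma = 0.5, x0 = 0.5, T = 2)
  sys_pa <- assemble_local_system(prob, ctl_pa, el, 0.5)
  sys_dc <- assemble_local_system(prob, ctl_dc, el, 0.5)
  a <- c(0.3, -0.2)
  # product approximation: squared coefficients through the mass matrix
  expect_equal(sys_pa$nonlinear$value(a), drop(mass_matrix(1, el) %*% a^2),
               tolerance = 1e-14)
  # direct computation, h = 2: n_0 = 2 a0^2 + (2/3) a1^2, n_1 = (4/3) a0 a1
  expect_equal(sys_dc$nonlinear$value(a),
               c(2 * a[1]^2 + 2 / 3 * a[2]^2, 4 / 3 * a[1] * a[2]),
               tolerance = 1e-13)
  # residual closure vanishes at the solved coefficients
  sol <- solve_element_linear(lin_prob, ldg_control(r = 2, J = 1), el, 0.75)
  sys <- assemble_local_system(lin_prob, ldg_control(r = 2, J = 1), el, 0.75)
  expect_lt(max(abs(sys$residual(sol$alpha, sol$beta))), 1e-12)
})

test_that("logistic Newton elements hit the certified roots of the local
          nonlinear system", {
  # independently certified (exact symbolic elimination / 30-digit
  # polishing of the discrete system)
  certified <- list(
    list(r = 1, nl = "dc", value = 0.6224742371411923),
    list(r = 1, nl = "pa", value = 0.6234038972386975),
    list(r = 2, nl = "dc", value = 0.6224593540388232),
    list(r = 2, nl = "pa", value = 0.6233820130920716))
  for (cs in certified) {
    sol <- ldg_solve(log_prob, ldg_control(r = cs$r, J = 1,
                                           nonlinear = cs$nl))
    expect_equal(downwind(sol), cs$value, tolerance = 1e-12,
                 label = sprintf("r=%d %s", cs$r, cs$nl))
  }
})

test_that("Newton converges quadratically and handles the degenerate
          zero-rate problem", {
  sol <- ldg_solve(log_prob, ldg_control(r = 2, J = 1, nonlinear = "dc"))
  res <- sol$newton_residuals[[1]]
  n <- length(res)
  expect_gte(n, 3)
  # at least quadratic contraction over the final two steps
  expect_lt(res[n], res[n - 1]^2 * 10)
  expect_lt(res[n - 1], res[n - 2]^2 * 10)
  # sigma = 0: no growth, solution stays at x0 with zero derivative
  still <- fle_problem("logistic", nu = 1, sigma = 0, x0 = 0.5, T = 1)
  sol0 <- ldg_solve(still, ldg_control(r = 2, J = 2))
  expect_equal(downwind(sol0), 0.5, tolerance = 1e-13)
  expect_lt(max(abs(sol0$beta)), 1e-13)
})

test_that("element-by-element marching reproduces the two-element table
          values", {
  sol <- ldg_solve(lin_prob, ldg_control(r = 2, J = 2))
  expect_equal(downwind(sol), 5.543701171875, tolerance = 1e-12)
  expect_equal(absolute_error(lin_prob, downwind(sol), 2), 1.9091e-3,
               tolerance = 5e-5)
  sol <- ldg_solve(log_prob, ldg_control(r = 2, J = 2, nonlinear = "dc"))
  expect_equal(downwind(sol), 0.6224593321, tolerance = 5e-10)
})

test_that("history anchoring modes coincide where they must", {
  # J = 1: no history exists, so the two modes are identical
  frac <- fle_problem("linear", nu = 0.6, sigma = 1, x0 = 0.75, T = 1)
  a <- ldg_solve(frac, ldg_control(r = 3, J = 1, history = "literal"))
  b <- ldg_solve(frac, ldg_control(r = 3, J = 1, history = "corrected"))
  expect_equal(a$alpha, b$alpha, tolerance = 1e-12)
  # nu = 1: the fractional integral is local, so marching is invariant
  a <- ldg_solve(log_prob, ldg_control(r = 2, J = 4, history = "literal"))
  b <- ldg_solve(log_prob, ldg_control(r = 2, J = 4, history = "corrected"))
  expect_equal(a$alpha, b$alpha, tolerance = 1e-12)
})

test_that("corrected-history marching converges on a fractional problem", {
  frac <- fle_problem("linear", nu = 0.75, sigma = 1, x0 = 0.75, T = 1)
  errs <- vapply(c(2L, 8L), function(J) {
    s <- ldg_solve(frac, ldg_control(r = 2, J = J, history = "corrected"))
    absolute_error(frac, downwind(s), 1)
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 4)
  expect_lt(errs[2], 5e-6)
})

test_that("solution evaluation: one-sided limits, monomial cross-check,
          domain checks", {
  sol <- ldg_solve(lin_prob, ldg_control(r = 3, J = 1))
  # left limit at T is the coefficient sum; right limit at 0 shows the
  # weak-imposition jump (constant term of the printed cubic, not x0)
  expect_equal(evaluate_solution(sol, 2, side = "left"), sum(sol$alpha[, 1]),
               tolerance = 1e-13)
  expect_equal(evaluate_solution(sol, 0, side = "right"), 0.7016129032,
               tolerance = 1e-10)
  # interior point agrees with the monomial form
  mono <- monomial_form(sol)
  expect_equal(evaluate_solution(sol, 1.3), polyval_asc(mono, 1.3),
               tolerance = 1e-10)
  expect_error(evaluate_solution(sol, 2.5), "outside")
  # interior node side selection on a 2-element run
  sol2 <- ldg_solve(lin_prob, ldg_control(r = 2, J = 2))
  left <- evaluate_solution(sol2, 1, side = "left")
  right <- evaluate_solution(sol2, 1, side = "right")
  expect_equal(left, sum(sol2$alpha[, 1]), tolerance = 1e-13)
  expect_false(isTRUE(all.equal(left, right)))
})

test_that("solution differences are contractive for decaying problems", {
  # classical order, various degrees and meshes
  for (r in 1:4) for (J in c(1, 4, 16)) {
    p1 <- fle_problem("linear", nu = 1, sigma = -1, x0 = 0.75, T = 2)
    p2 <- fle_problem("linear", nu = 1, sigma = -1, x0 = 0.80, T = 2)
    d <- abs(downwind(ldg_solve(p2, ldg_control(r = r, J = J))) -
               downwind(ldg_solve(p1, ldg_control(r = r, J = J))))
    expect_lte(d, 0.05 + 1e-12)
  }
  # fractional orders on a single element
  for (nu in c(0.5, 0.75)) {
    p1 <- fle_problem("linear", nu = nu, sigma = -1, x0 = 0.75, T = 2)
    p2 <- fle_problem("linear", nu = nu, sigma = -1, x0 = 0.80, T = 2)
    d <- abs(downwind(ldg_solve(p2, ldg_control(r = 3, J = 1))) -
               downwind(ldg_solve(p1, ldg_control(r = 3, J = 1))))
    expect_lte(d, 0.05 + 1e-12)
  }
})

test_that("downwind errors superconverge at order 2r+1 for the classical
          problems", {
  for (r in 1:2) {
    for (prob in list(lin_prob, log_prob)) {
      st <- convergence_study(prob, J = c(1, 2, 4, 8), solver = "ldg", r = r,
                              nonlinear = "dc")
      measured <- st$eoc[nrow(st)]
      expect_lt(abs(measured - (2 * r + 1)), 0.35,
                label = sprintf("%s model, r=%d (EOC %.2f)",
                                prob$model, r, measured))
    }
  }
})

test_that("product approximation converges at order 2 on the logistic
          problem", {
  st <- convergence_study(log_prob, J = c(1, 2, 4), solver = "ldg", r = 1,
                          nonlinear = "pa")
  expect_equal(st$eoc[2], 1.99, tolerance = 0.05)
  expect_lt(abs(st$eoc[3] - 2), 0.1)
})

test_that("tidiers and plots expose the solution", {
  sol <- ldg_solve(log_prob, ldg_control(r = 1, J = 2))
  td <- tidy(sol)
  expect_equal(nrow(td), 4)
  expect_named(td, c("element", "node_left", "node_right", "basis_index",
                     "alpha", "beta"))
  gl <- glance(sol)
  expect_equal(gl$downwind, downwind(sol))
  expect_lt(gl$abs_error, 1e-4)
  grid <- solution_grid(sol, n = 10)
  expect_equal(nrow(grid), 20)
  expect_s3_class(autoplot(sol), "ggplot")
  st <- convergence_study(log_prob, J = c(1, 2), solver = "ldg", r = 1)
  expect_s3_class(autoplot(st), "ggplot")
  expect_output(print(sol), "downwind value")
})
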