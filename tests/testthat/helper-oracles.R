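## Independent oracles used across the suite.

## dense Gauss-Legendre quadrature of f over [a, b], exact for polynomials
## of degree <= 2n-1
gauss_quad <- function(f, a, b, n = 30L) {
  g <- pracma::gaussLegendre(n, a, b)
  sum(g$w * f(g$x))
}

## bilinear Gram oracle <f, g> over an element
gram_oracle <- function(f, g, element, n = 30L)
  gauss_quad(function(x) f(x) * g(x), element[1], element[2], n)

## polynomial evaluation from ascending monomial coefficients
polyval_asc <- function(coef, x) {
  out <- numeric(length(x))
  for (k in seq_along(coef)) out <- out + coef[k] * x^(k - 1)
  out
}

## derivative coefficients of an ascending monomial polynomial
polyderiv_asc <- function(coef) {
  if (length(coef) == 1L) return(0)
  coef[-1L] * seq_len(length(coef) - 1L)
}

## derivative of the shifted Legendre basis via the analytic relation
## P'_i(s) = i (s P_i - P_{i-1}) / (s^2 - 1) (valid off the endpoints;
## quadrature nodes are interior), chained with ds/dt = 2/h
shifted_legendre_deriv <- function(i, element, x) {
  if (i == 0L) return(rep(0, length(x)))
  h <- element[2] - element[1]
  s <- (2 * x - element[1] - element[2]) / h
  pi_ <- shifted_legendre_eval(i, element, x)
  pim <- shifted_legendre_eval(i - 1L, element, x)
  (i * (s * pi_ - pim) / (s^2 - 1)) * (2 / h)
}

## classical full-memory rectangle-predictor / single-trapezoid-corrector
## PECE for X' = f(X) on [0, T]; the order-1 collapse of the fractional
## scheme, written independently from first principles
classical_pece <- function(f, x0, T, N) {
  h <- T / N
  X <- numeric(N + 1L)
  fv <- numeric(N + 1L)
  X[1] <- x0
  fv[1] <- f(x0)
  for (n in 0:(N - 1L)) {
    xp <- x0 + h * sum(fv[1:(n + 1L)])                  # rectangle memory
    w <- rep(2, n + 1L)
    w[1] <- 1                                           # trapezoid ends
    X[n + 2L] <- x0 + h / 2 * (f(xp) + sum(w * fv[1:(n + 1L)]))
    fv[n + 2L] <- f(X[n + 2L])
  }
  X
}

## downwind value of an LDG run, as used in all error tables
downwind <- function(solution) {
  J <- solution$mesh$J
  sum(solution$alpha[, J])
}
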