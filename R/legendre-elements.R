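## Shifted Legendre bases on mesh elements and the per-element operator
## matrices of the LDG discretization.  An "element" throughout is the
## closed interval [t_{l-1}, t_l], passed as a length-2 numeric c(lower,
## upper); the basis L_i is the Legendre polynomial P_i composed with the
## affine map s = (2 t - t_{l-1} - t_l) / h_l onto [-1, 1], so that
## L_i(t_l) = 1 and L_i(t_{l-1}) = (-1)^i.

check_element <- function(element) {
  if (!is.numeric(element) || length(element) != 2L ||
      !all(is.finite(element)) || element[2] <= element[1])
    stop("`element` must be c(lower, upper) with upper > lower.",
         call. = FALSE)
  invisible(element)
}

## monomial coefficient vectors (in s, ascending powers) of P_0..P_r via the
## three-term recurrence applied to coefficients
legendre_reference_coefficients <- function(r) {
  out <- vector("list", r + 1L)
  out[[1L]] <- 1
  if (r >= 1L) out[[2L]] <- c(0, 1)
  if (r >= 2L) {
    for (i in 1:(r - 1L)) {
      a <- c(0, out[[i + 1L]]) * (2 * i + 1)   # (2i+1) s P_i
      b <- numeric(length(a))
      b[seq_along(out[[i]])] <- out[[i]] * i   # i P_{i-1}
      out[[i + 2L]] <- (a - b) / (i + 1)
    }
  }
  out
}

## evaluate P_i(s) by the stable three-term recurrence; s vectorised
legendre_recurrence <- function(i, s) {
  if (i == 0L) return(rep(1, length(s)))
  p0 <- rep(1, length(s))
  p1 <- s
  if (i == 1L) return(p1)
  for (k in 1:(i - 1L)) {
    p2 <- ((2 * k + 1) * s * p1 - k * p0) / (k + 1)
    p0 <- p1
    p1 <- p2
  }
  p1
}

#' Evaluate a shifted Legendre basis polynomial on an element
#'
#' Computes \eqn{L_i(t) = P_i(s(t))} with the affine element map
#' \eqn{s = (2t - t_{l-1} - t_l)/h_l}, using the three-term Legendre
#' recurrence (numerically stable for all degrees in scope).  By
#' construction \eqn{L_i = 1} at the right node and \eqn{(-1)^i} at the
#' left node.
#'
#' @param i basis degree index, `i >= 0`.
#' @param element numeric `c(lower, upper)`.
#' @param t evaluation times inside the closed element (vectorised).
#' @return numeric vector of basis values.
#' @export
shifted_legendre_eval <- function(i, element, t) {
  check_element(element)
  if (!is.numeric(i) || length(i) != 1L || i < 0 || i != round(i))
    stop("`i` must be a non-negative integer.", call. = FALSE)
  tol <- 1e-12 * max(1, abs(element[2]))
  if (any(t < element[1] - tol | t > element[2] + tol))
    stop("`t` outside the element [", element[1], ", ", element[2], "].",
         call. = FALSE)
  s <- (2 * t - element[1] - element[2]) / (element[2] - element[1])
  legendre_recurrence(as.integer(i), s)
}

#' Monomial coefficients of a shifted Legendre basis polynomial
#'
#' Expands \eqn{L_i} on an element into a dense monomial coefficient vector
#' (ascending powers, length `i + 1`).  With `origin = "global"` the powers
#' are of \eqn{t} itself; with `origin = "local"` they are powers of the
#' local coordinate \eqn{\tau = t - t_{l-1}}.  The expansion is built by
#' explicit binomial composition of the reference-interval coefficients
#' with the affine element map (conditioning degrades beyond degree ~12,
#' which is the enforced solver bound).
#'
#' @inheritParams shifted_legendre_eval
#' @param origin `"global"` (powers of t) or `"local"` (powers of
#'   t - lower).
#' @return numeric coefficient vector `c0, c1, ..., ci`.
#' @export
monomial_coefficients <- function(i, element, origin = c("global", "local")) {
  check_element(element)
  origin <- match.arg(origin)
  if (!is.numeric(i) || length(i) != 1L || i < 0 || i != round(i))
    stop("`i` must be a non-negative integer.", call. = FALSE)
  i <- as.integer(i)
  cs <- legendre_reference_coefficients(i)[[i + 1L]]
  h <- element[2] - element[1]
  ## global: s = (2/h) t - (t0 + t1)/h ; local: s = (2/h) tau - 1
  a <- 2 / h
  b <- if (origin == "global") -(element[1] + element[2]) / h else -1
  out <- numeric(i + 1L)
  for (k in seq_along(cs)) {          # term cs[k] * (a x + b)^(k-1)
    kk <- k - 1L
    if (cs[k] == 0) next
    m <- 0:kk
    out[m + 1L] <- out[m + 1L] + cs[k] * choose(kk, m) * a^m * b^(kk - m)
  }
  out
}

#' Element mass matrix
#'
#' Diagonal Gram matrix of the shifted Legendre basis on an element of
#' length \eqn{h_l}: entries \eqn{m_{i,i} = h_l/(2i+1)}.
#'
#' @param r polynomial degree of the basis.
#' @param element numeric `c(lower, upper)`.
#' @return an `(r+1) x (r+1)` diagonal matrix.
#' @export
mass_matrix <- function(r, element) {
  check_element(element)
  h <- element[2] - element[1]
  diag(h / (2 * (0:r) + 1), r + 1L, r + 1L)
}

#' Element stiffness matrix
#'
#' Matrix of \eqn{\langle L_i, L_j' \rangle_l} with the *test* index
#' \eqn{j} as the row index (the arrangement used in the local algebraic
#' system).  Exact integration shows the entry is 2 when the differentiated
#' (test) degree exceeds the trial degree and the index sum \eqn{i + j} is
#' odd, and 0 otherwise -- independent of the element length.  The matrix
#' is therefore strictly lower triangular with a checkerboard of 2s, and
#' satisfies the integration-by-parts identity
#' \eqn{s_{j,i} + s_{i,j} = 1 - (-1)^{i+j}}.
#'
#' @inheritParams mass_matrix
#' @return an `(r+1) x (r+1)` matrix (row = test index).
#' @export
stiffness_matrix <- function(r, element = c(-1, 1)) {
  check_element(element)
  S <- matrix(0, r + 1L, r + 1L)
  for (j in 0:r) for (i in 0:r)
    if (j > i && (i + j) %% 2L == 1L) S[j + 1L, i + 1L] <- 2
  S
}

#' Upwind flux operators
#'
#' The boundary coupling of the element system: the all-ones matrix `E`
#' (downwind trace, \eqn{L_i(t_l^-) = 1} for every i) and the inflow load
#' vector \eqn{b_i = (-1)^{i+1} Z_0(t_{l-1}^-)} carrying the upwind value
#' from the previous element (the initial value on the first element).
#'
#' @param r polynomial degree.
#' @param inflow_value upwind trace \eqn{Z_0(t_{l-1}^-)}.
#' @return a list with components `E` (matrix) and `b` (vector).
#' @export
flux_operators <- function(r, inflow_value) {
  if (!is.numeric(inflow_value) || length(inflow_value) != 1L)
    stop("`inflow_value` must be a scalar.", call. = FALSE)
  list(E = matrix(1, r + 1L, r + 1L),
       b = (-1)^((0:r) + 1) * inflow_value)
}

## stable t1^p - t0^p for 0 <= t0 < t1 (cancellation-compensated via
## expm1/log1p when the nodes are close)
power_difference <- function(t1, t0, p) {
  if (t0 == 0) return(t1^p)
  -t1^p * expm1(p * log(t0 / t1))
}

#' Element fractional matrix
#'
#' Matrix of the fractionally integrated basis against the basis,
#' \eqn{d_{i,j} = \langle I^{1-\nu} L_i, L_j \rangle_l}, assembled termwise
#' from the monomial representation of the basis and the closed-form
#' fractional integral of monomials.  Row index is the test index \eqn{j}.
#'
#' Two anchorings of the fractional integral are provided.
#' `"paper_literal"` applies \eqn{I^{1-\nu}} anchored at the global origin
#' \eqn{t = 0} to the polynomial extension of the local basis (the local
#' algebraic system as printed, with no cross-element history term).
#' `"history_corrected"` anchors the local part at the element's left node
#' \eqn{t_{l-1}}, with the memory of earlier elements supplied separately
#' as a history load during marching (see [ldg_solve()]).  The two coincide
#' on the first element and, since \eqn{I^0} is the identity, both reduce
#' exactly to the mass matrix at \eqn{\nu = 1}.
#'
#' @inheritParams mass_matrix
#' @param nu fractional order in (0, 1].
#' @param mode `"paper_literal"` or `"history_corrected"`.
#' @return an `(r+1) x (r+1)` matrix (row = test index).
#' @export
fractional_matrix <- function(r, element, nu,
                              mode = c("paper_literal", "history_corrected")) {
  check_element(element)
  mode <- match.arg(mode)
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu > 1)
    stop("`nu` must lie in (0, 1].", call. = FALSE)
  if (nu == 1) return(mass_matrix(r, element))
  origin <- if (mode == "paper_literal") "global" else "local"
  lo <- if (mode == "paper_literal") element[1] else 0
  hi <- if (mode == "paper_literal") element[2] else element[2] - element[1]
  mono <- lapply(0:r, monomial_coefficients, element = element,
                 origin = origin)
  D <- matrix(0, r + 1L, r + 1L)
  for (i in 0:r) {
    ai <- mono[[i + 1L]]
    ## I^{1-nu} t^m = Gamma(m+1)/Gamma(m+2-nu) t^{m+1-nu}
    wi <- ai * exp(lgamma(0:i + 1) - lgamma(0:i + 2 - nu))
    for (j in 0:r) {
      bj <- mono[[j + 1L]]
      acc <- 0
      for (m in 0:i) {
        if (wi[m + 1L] == 0) next
        for (mp in 0:j) {
          if (bj[mp + 1L] == 0) next
          p <- m + mp + 2 - nu
          acc <- acc + wi[m + 1L] * bj[mp + 1L] *
            power_difference(hi, lo, p) / p
        }
      }
      D[j + 1L, i + 1L] <- acc
    }
  }
  D
}

## Gauss-Legendre rule on [a, b]
gauss_rule <- function(n, a, b) pracma::gaussLegendre(max(n, 2L), a, b)

## basis values at quadrature nodes: matrix (nodes x (r+1))
basis_at <- function(r, element, x) {
  s <- (2 * x - element[1] - element[2]) / (element[2] - element[1])
  vapply(0:r, function(i) legendre_recurrence(i, s), numeric(length(x)))
}

#' Triple-product tensor of the element basis
#'
#' The rank-3 array \eqn{T[i, i', j] = \int_{L_l} L_i L_{i'} L_j \, dt}
#' used by the direct-computation (D.C.) treatment of the logistic
#' nonlinearity, where the Galerkin integral of the squared expansion is
#' the contraction \eqn{n_j = \sum_{i,i'} T[i,i',j] \alpha_i \alpha_{i'}}.
#' Computed by a Gauss-Legendre rule exact for the degree-3r integrand.
#' Symmetric in its first two indices; the slice `T[1, , ]` equals the mass
#' matrix since \eqn{L_0 \equiv 1}.
#'
#' @inheritParams mass_matrix
#' @return an `(r+1) x (r+1) x (r+1)` array (1-based on degree 0).
#' @export
triple_product_tensor <- function(r, element) {
  check_element(element)
  g <- gauss_rule(ceiling((3 * r + 1) / 2) + 2L, element[1], element[2])
  L <- basis_at(r, element, g$x)
  n1 <- r + 1L
  out <- array(0, c(n1, n1, n1))
  for (i in 1:n1) for (ip in i:n1) {
    v <- g$w * L[, i] * L[, ip]
    for (j in 1:n1) {
      val <- sum(v * L[, j])
      out[i, ip, j] <- val
      out[ip, i, j] <- val
    }
  }
  out
}
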