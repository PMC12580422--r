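#' B-spline basis specification for functional coefficients
#'
#' Functional coefficients \eqn{\beta(t)} are represented as penalized
#' B-splines: `K` basis functions of the given order (4 = cubic) with
#' equally spaced knots on \eqn{[0, 1]} and a difference penalty of order
#' `penalty_order` on the basis coefficients. The defaults (K = 9 cubic
#' splines, second-order penalty) are the usual penalized scalar-on-function
#' choices; at 33 grid points they leave ample flexibility while the
#' penalty controls effective degrees of freedom.
#'
#' @param n_basis Number of basis functions K (default 9). Must satisfy
#'   `penalty_order < n_basis <= 33` and `n_basis >= order`.
#' @param order Spline order (polynomial degree + 1); default 4 (cubic).
#' @param penalty_order Order of the difference penalty; default 2, which
#'   shrinks \eqn{\beta(t)} toward a straight line.
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(n_basis = 9L, order = 4L, penalty_order = 2L) {
  n_basis <- as.integer(n_basis); order <- as.integer(order)
  penalty_order <- as.integer(penalty_order)
  if (n_basis > 33L)
    stop("n_basis must be <= 33 (the grid length)", call. = FALSE)
  if (n_basis <= penalty_order)
    stop("n_basis must exceed penalty_order", call. = FALSE)
  if (order < 1L || n_basis < order)
    stop("need order >= 1 and n_basis >= order", call. = FALSE)
  if (penalty_order < 0L)
    stop("penalty_order must be >= 0", call. = FALSE)
  structure(list(n_basis = n_basis, order = order,
                 penalty_order = penalty_order),
            class = "basis_spec")
}

#' Trapezoid quadrature weights on the uniform cycle grid
#'
#' Weights for approximating \eqn{\int_0^1 f(t)\,dt} by
#' \eqn{\sum_l w_l f(t_l)}: \eqn{w_1 = w_L = 1/(2(L-1))}, interior weights
#' \eqn{1/(L-1)}. Exact for piecewise-linear integrands on the grid, which
#' is the representation [resample_trace()] produces.
#'
#' @param L Grid length (>= 2), default 33.
#' @return Numeric weight vector of length `L` summing to 1.
#' @export
quadrature_weights <- function(L = 33L) {
  if (length(L) != 1L || !is.finite(L) || L < 2)
    stop("`L` must be a single integer >= 2", call. = FALSE)
  L <- as.integer(L)
  w <- rep(1 / (L - 1), L)
  w[c(1L, L)] <- 1 / (2 * (L - 1))
  w
}

#' Evaluate the basis and its difference penalty
#'
#' Evaluates the B-spline basis of `spec` on the `L`-point cycle grid and
#' builds the penalty matrix \eqn{P = D^\top D} with `D` the
#' `penalty_order`-th difference operator on the coefficient vector
#' (penalty_order 0 gives a ridge penalty). B-spline rows form a partition
#' of unity; a second-order penalty has a two-dimensional null space
#' (constant and linear coefficient sequences).
#'
#' @param spec A [basis_spec()].
#' @param L Grid length, default 33.
#' @return List with `B` (L x K basis matrix), `P` (K x K penalty),
#'   `null_dim` (penalty null-space dimension) and `spec`.
#' @export
build_basis <- function(spec = basis_spec(), L = 33L) {
  stopifnot(inherits(spec, "basis_spec"))
  K <- spec$n_basis; ord <- spec$order
  if (K > L) stop("n_basis exceeds grid length", call. = FALSE)
  tg <- cycle_grid(L)
  # Eilers-Marx P-spline knots: uniform spacing, extended past [0, 1] so
  # that the difference-penalty null space is exactly polynomial in t
  # (penalty_order 2 shrinks beta(t) to a straight line as lambda grows)
  h <- 1 / (K - ord + 1)
  # integer-ratio knots so 0 and 1 are hit exactly
  knots <- (seq_len(K + ord) - ord) / (K - ord + 1)
  if (ord == 1L) {
    # degree-0 splines are right-open indicators; close the last interval
    B <- matrix(0, L, K)
    B[cbind(seq_len(L), pmin(floor(tg / h) + 1L, K))] <- 1
  } else {
    B <- splines::splineDesign(knots, tg, ord = ord)
  }
  if (spec$penalty_order == 0L) {
    D <- diag(K)
  } else {
    D <- diff(diag(K), differences = spec$penalty_order)
  }
  P <- crossprod(D)
  list(B = B, P = P,
       null_dim = if (spec$penalty_order == 0L) 0L else spec$penalty_order,
       spec = spec)
}

#' Functional design block by numerical integration
#'
#' Builds the n x K block whose (i, k) entry approximates
#' \eqn{\int_0^1 (X_i(t) - \bar X(t))\, b_k(t)\, dt} by trapezoid
#' quadrature, where \eqn{\bar X} is the centering curve. Centering at
#' the sample mean curve decorrelates the intercept from the functional
#' term; the centering curve is returned so it can be re-applied to new
#' curves at prediction time.
#'
#' @param curves List of [normalized_curve()] objects, or an n x L numeric
#'   matrix of curve values.
#' @param basis Result of [build_basis()].
#' @param weights Quadrature weights; default [quadrature_weights()] for
#'   the basis grid length.
#' @param center Centering curve of length L; default the sample mean
#'   curve of `curves`. Use `0` for no centering.
#' @return n x K matrix with attribute `"center"` (the centering curve).
#' @export
functional_design <- function(curves, basis,
                              weights = quadrature_weights(nrow(basis$B)),
                              center = NULL) {
  X <- curves_to_matrix(curves)
  if (nrow(X) == 0L) stop("empty curve list", call. = FALSE)
  L <- nrow(basis$B)
  if (ncol(X) != L)
    stop("curve length does not match basis grid", call. = FALSE)
  if (is.null(center)) center <- colMeans(X)
  if (length(center) == 1L) center <- rep(center, L)
  Xc <- sweep(X, 2L, center)
  out <- (Xc * rep(weights, each = nrow(Xc))) %*% basis$B
  attr(out, "center") <- as.numeric(center)
  out
}

# Coerce a list of normalized curves (or a numeric matrix) to n x L matrix.
curves_to_matrix <- function(curves) {
  if (is.matrix(curves)) return(curves)
  if (inherits(curves, "normalized_curve")) curves <- list(curves)
  if (!length(curves)) return(matrix(numeric(0), 0, 33))
  do.call(rbind, lapply(curves, function(cv) {
    if (inherits(cv, "normalized_curve")) cv$values else as.numeric(cv)
  }))
}
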