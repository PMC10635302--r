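#' Fourier coefficients of a persistence diagram
#'
#' The diagram's Dirac-mass initial condition has Fourier coefficients
#' \eqn{f_k = \sum_{i=1}^P \psi_k(a_i, b_i)}: each coefficient is the sum of
#' the k-th eigenfunction evaluated at every diagram point.  The
#' coefficients do not depend on the bandwidth; the heat weights
#' \eqn{e^{-\lambda_k \sigma}} enter only when reconstructing fields or
#' computing distances.  For the constant eigenfunction,
#' `f_0 = P / sqrt(area)`.
#'
#' @param pd a standardized [persistence_diagram()] (points inside the basis
#'   domain).
#' @param basis an [lb_basis].
#' @return An object of class `hk_coefficients`: numeric `coefficients` of
#'   length kappa + 1, `kappa`, `basis_id`, `n_points`.
#' @export
fourier_coefficients <- function(pd, basis) {
  stopifnot(inherits(pd, "persistence_diagram"), inherits(basis, "lb_basis"))
  if (!nrow(pd$points)) {
    co <- numeric(basis$kappa + 1L)
  } else {
    Psi <- evaluate_basis(basis, pd$points)
    co <- colSums(Psi)
  }
  structure(
    list(coefficients = co, kappa = basis$kappa, basis_id = basis$basis_id,
         n_points = nrow(pd$points)),
    class = "hk_coefficients"
  )
}

#' @export
print.hk_coefficients <- function(x, ...) {
  cat(sprintf("HK coefficient vector: kappa = %d, diagram points = %d\n",
              x$kappa, x$n_points))
  cat("  f_0..f_5:", paste(signif(utils::head(x$coefficients, 6), 5),
                           collapse = ", "), "\n")
  invisible(x)
}

# collect a list of hk_coefficients into a matrix, checking basis identity
coefficient_matrix <- function(coeff_list, basis_id = NULL) {
  if (inherits(coeff_list, "hk_coefficients")) coeff_list <- list(coeff_list)
  if (!length(coeff_list)) stop("empty coefficient list")
  ids <- vapply(coeff_list, function(x) x$basis_id, character(1))
  if (!is.null(basis_id)) ids <- c(ids, basis_id)
  if (length(unique(ids)) > 1L)
    stop("coefficient vectors were computed against different bases")
  do.call(rbind, lapply(coeff_list, function(x) x$coefficients))
}

# heat weights e^{-lambda_k * sigma}
hk_weights <- function(eigenvalues, sigma) {
  if (sigma < 0) stop("'sigma' must be nonnegative")
  exp(-eigenvalues * sigma)
}

# embedding x_k = e^{-lambda_k sigma / 2} f_k turning the weighted L2
# distance into a plain squared Euclidean distance
hk_embed <- function(coeff_list, eigenvalues, sigma) {
  Fm <- coefficient_matrix(coeff_list)
  if (ncol(Fm) != length(eigenvalues))
    stop("coefficient length does not match the number of eigenvalues")
  sweep(Fm, 2, sqrt(hk_weights(eigenvalues, sigma)), `*`)
}

#' Weighted L2 distance between heat-kernel represented diagrams
#'
#' The squared L2 distance between the degree-kappa heat-kernel estimates of
#' two diagrams reduces to
#' \eqn{\sum_k e^{-\lambda_k \sigma} (f_k - g_k)^2}
#' on their Fourier coefficient vectors.  This is the test statistic used by
#' all inference in the package.  Its square root is a pseudometric (the
#' weighted-Euclidean embedding \eqn{x_k = e^{-\lambda_k \sigma/2} f_k}).
#'
#' @param c1,c2 [fourier_coefficients()] results sharing a basis.
#' @param sigma nonnegative bandwidth.
#' @param eigenvalues the basis eigenvalues (or an `lb_basis`).
#' @return nonnegative scalar (squared distance).
#' @export
hk_l2_distance <- function(c1, c2, sigma, eigenvalues) {
  if (inherits(eigenvalues, "lb_basis")) eigenvalues <- eigenvalues$eigenvalues
  if (!identical(c1$basis_id, c2$basis_id))
    stop("coefficient vectors were computed against different bases")
  if (length(c1$coefficients) != length(c2$coefficients))
    stop("coefficient vectors have different truncation degrees")
  sum(hk_weights(eigenvalues, sigma) * (c1$coefficients - c2$coefficients)^2)
}

#' Pairwise weighted L2 distance matrix
#'
#' @param coeff_list list of [fourier_coefficients()] sharing one basis.
#' @param sigma nonnegative bandwidth.
#' @param eigenvalues basis eigenvalues (or an `lb_basis`).
#' @return symmetric matrix of squared distances with zero diagonal.
#' @export
pairwise_distance_matrix <- function(coeff_list, sigma, eigenvalues) {
  if (inherits(eigenvalues, "lb_basis")) eigenvalues <- eigenvalues$eigenvalues
  X <- hk_embed(coeff_list, eigenvalues, sigma)
  D <- as.matrix(stats::dist(X))^2
  dimnames(D) <- NULL
  D
}

#' Reconstruct the smoothed diagram field at a bandwidth
#'
#' Evaluates the degree-kappa heat-kernel estimate
#' \eqn{h_\sigma(p) = \sum_k e^{-\lambda_k \sigma} f_k \psi_k(p)} on a
#' regular lattice clipped to the triangle.  At large sigma the field
#' flattens to P/area everywhere; at sigma = 0 (and large kappa) mass
#' concentrates near the diagram points.  The field integrates to P at any
#' bandwidth because only the constant mode has nonzero integral.
#'
#' @param coeffs an [fourier_coefficients()] result.
#' @param basis the matching [lb_basis].
#' @param sigma nonnegative bandwidth.
#' @param grid_n bounding-lattice resolution (default 100).
#' @return An object of class `smoothed_field`: `grid` (points inside the
#'   triangle), `values`, `sigma`.
#' @export
reconstruct_field <- function(coeffs, basis, sigma, grid_n = 100) {
  stopifnot(inherits(coeffs, "hk_coefficients"), inherits(basis, "lb_basis"))
  if (!identical(coeffs$basis_id, basis$basis_id))
    stop("coefficients were computed against a different basis")
  v <- basis$domain$vertices
  gx <- seq(min(v[, 1]), max(v[, 1]), length.out = grid_n)
  gy <- seq(min(v[, 2]), max(v[, 2]), length.out = grid_n)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  eps <- 1e-9
  keep <- in_domain(basis$domain, grid, tol = -eps)  # strictly inside
  grid <- grid[keep, , drop = FALSE]
  Psi <- evaluate_basis(basis, grid)
  w <- hk_weights(basis$eigenvalues, sigma)
  vals <- as.numeric(Psi %*% (w * coeffs$coefficients))
  structure(list(grid = grid, values = vals, sigma = sigma),
            class = "smoothed_field")
}

#' @export
print.smoothed_field <- function(x, ...) {
  cat(sprintf("Smoothed diagram field: sigma = %g, %d grid points, range [%.4g, %.4g]\n",
              x$sigma, nrow(x$grid), min(x$values), max(x$values)))
  invisible(x)
}

#' Integral of a heat-kernel field over the domain
#'
#' Only the constant mode contributes, so the integral equals the diagram's
#' point count at any bandwidth; computed here from the coefficients and the
#' exact eigenfunction integrals for verification.
#'
#' @param coeffs an [fourier_coefficients()] result.
#' @param basis the matching [lb_basis].
#' @param sigma bandwidth.
#' @return scalar integral.
#' @export
field_integral <- function(coeffs, basis, sigma) {
  ints <- basis_integrals(basis)
  sum(hk_weights(basis$eigenvalues, sigma) * coeffs$coefficients * ints)
}
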