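#' Laplace-Beltrami eigenbasis of the standardized triangle
#'
#' Solves the generalized eigenproblem K v = lambda M v of the P1
#' finite-element discretization of the Laplacian with natural (Neumann)
#' boundary conditions.  With Neumann conditions the spectrum starts at
#' lambda_0 = 0 with a constant first eigenfunction equal to
#' 1/sqrt(area(domain)), and the eigenvectors are orthonormal with respect to
#' the mass matrix.
#'
#' @param mesh a [build_triangle_mesh()] result.
#' @param count number of eigenpairs requested (kappa + 1, including the
#'   constant mode).
#' @param mass_lumping use the diagonal (lumped) mass matrix instead of the
#'   consistent one.
#' @param solver_tol tolerance used to validate lambda_0 ~ 0.
#' @return An object of class `lb_basis` with fields `mesh`, `eigenvalues`
#'   (ascending, length `count`), `eigenvectors` (nodes x count,
#'   mass-orthonormal, sign-fixed), `mass`, `stiffness`, `kappa = count - 1`,
#'   `domain`, `basis_id`.
#' @examples
#' dom <- triangle_domain()
#' msh <- build_triangle_mesh(dom, 1 / 8)
#' bas <- solve_lb_eigenpairs(msh, count = 5)
#' bas$eigenvalues
#' @export
solve_lb_eigenpairs <- function(mesh, count, mass_lumping = FALSE,
                                solver_tol = 1e-9) {
  if (!inherits(mesh, "triangle_mesh")) stop("'mesh' must be a triangle_mesh")
  N <- nrow(mesh$nodes)
  if (count < 1L || count > N)
    stop(sprintf("'count' must be between 1 and the node count (%d)", N))
  fem <- fem_matrices(mesh, mass_lumping = mass_lumping)
  K <- as.matrix(fem$stiffness)
  if (mass_lumping) {
    d <- Matrix::diag(fem$mass)
    s <- 1 / sqrt(d)
    Aw <- K * tcrossprod(s)                      # D^{-1/2} K D^{-1/2}
    ev <- eigen(Aw, symmetric = TRUE)
    vec <- ev$vectors * s                        # back-transform
  } else {
    M <- as.matrix(fem$mass)
    R <- chol(M)
    # A = R^{-T} K R^{-1}, symmetric; eigenvectors back-transformed by R^{-1}
    B <- backsolve(R, K, transpose = TRUE)
    Aw <- backsolve(R, t(B), transpose = TRUE)
    Aw <- (Aw + t(Aw)) / 2
    ev <- eigen(Aw, symmetric = TRUE)
    vec <- backsolve(R, ev$vectors)
  }
  ord <- rev(seq_len(N))[seq_len(count)]         # smallest 'count' eigenvalues
  lambda <- rev(ev$values)[seq_len(count)]
  vec <- vec[, ord, drop = FALSE]
  lambda[lambda < 0 & lambda > -1e-8] <- 0
  if (abs(lambda[1]) > max(solver_tol, 1e-7))
    stop(sprintf(
      "eigensolver failed: lambda_0 = %g not ~0 (mesh %d nodes, count %d)",
      lambda[1], N, count))
  # deterministic sign: first nodal entry of non-negligible magnitude positive
  for (k in seq_len(count)) {
    vk <- vec[, k]
    lead <- which(abs(vk) > 1e-6 * max(abs(vk)))[1]
    if (vk[lead] < 0) vec[, k] <- -vk
  }
  structure(
    list(mesh = mesh, eigenvalues = lambda, eigenvectors = vec,
         mass = fem$mass, stiffness = fem$stiffness,
         kappa = count - 1L, domain = mesh$domain,
         basis_id = sprintf("tri[%s]-n%d-k%d-%s",
                            paste(signif(as.vector(t(mesh$domain$vertices)), 8),
                                  collapse = ";"),
                            mesh$n, count - 1L,
                            if (mass_lumping) "lumped" else "consistent")),
    class = "lb_basis"
  )
}

#' Convenience constructor: mesh + eigenbasis in one call
#'
#' The default mesh resolution is chosen so that the node count is at least
#' 20 times the requested number of eigenpairs.
#'
#' @param kappa truncation degree; `kappa + 1` eigenpairs (including the
#'   constant mode) are computed.
#' @param domain a [triangle_domain()].
#' @param resolution mesh target edge length; if `NULL`, derived from `kappa`.
#' @param ... passed to [solve_lb_eigenpairs()].
#' @return An `lb_basis`.
#' @export
lb_basis <- function(kappa = 100, domain = triangle_domain(), resolution = NULL, ...) {
  count <- kappa + 1L
  if (is.null(resolution)) {
    # nodes (n+1)(n+2)/2 >= 20 * count  =>  smallest such n
    n <- ceiling((-3 + sqrt(9 + 8 * (20 * count - 1))) / 2)
    v <- domain$vertices
    leg <- min(sqrt(sum((v[2, ] - v[1, ])^2)),
               sqrt(sum((v[3, ] - v[2, ])^2)),
               sqrt(sum((v[3, ] - v[1, ])^2)))
    resolution <- leg / n
  }
  mesh <- build_triangle_mesh(domain, resolution)
  solve_lb_eigenpairs(mesh, count = count, ...)
}

#' @export
print.lb_basis <- function(x, ...) {
  cat(sprintf("Laplace-Beltrami eigenbasis (Neumann), kappa = %d\n", x$kappa))
  cat(sprintf("  mesh: %d nodes, %d elements\n",
              nrow(x$mesh$nodes), nrow(x$mesh$elements)))
  cat("  eigenvalues:", paste(signif(utils::head(x$eigenvalues, 6), 5),
                              collapse = ", "),
      if (length(x$eigenvalues) > 6) "..." else "", "\n")
  invisible(x)
}

#' Evaluate eigenfunctions at arbitrary interior points
#'
#' Barycentric (P1) interpolation of the nodal eigenvectors inside the
#' element containing each point.
#'
#' @param basis an [lb_basis].
#' @param points n x 2 matrix of coordinates in the standardized domain.
#' @param tol out-of-domain tolerance.
#' @return n x (kappa + 1) matrix `Psi` with `Psi[i, k]` the value of the
#'   (k-1)-th eigenfunction at point i.
#' @export
evaluate_basis <- function(basis, points, tol = 1e-8) {
  stopifnot(inherits(basis, "lb_basis"))
  points <- rbind(points)
  loc <- locate_points(basis$mesh, points, tol = tol)
  if (any(!loc$inside)) {
    bad <- which(!loc$inside)[1]
    stop(sprintf("point (%g, %g) lies outside the standardized domain",
                 points[bad, 1], points[bad, 2]))
  }
  V <- basis$eigenvectors
  out <- matrix(0, nrow(points), ncol(V))
  for (r in seq_len(nrow(points))) {
    out[r, ] <- loc$bary[r, ] %*% V[loc$tri[r, ], , drop = FALSE]
  }
  out
}

#' Truncated heat-kernel value
#'
#' Evaluates \eqn{K_\sigma(p, q) = \sum_k e^{-\lambda_k \sigma}
#' \psi_k(p)\psi_k(q)} over the available eigenpairs.  Symmetric in p and q;
#' as sigma grows the value tends to 1/area(domain) for all p, q.
#'
#' @param basis an [lb_basis].
#' @param p,q points (length-2 numeric) in the standardized domain.
#' @param sigma nonnegative diffusion bandwidth.
#' @return scalar kernel value.
#' @export
heat_kernel_value <- function(basis, p, q, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("'sigma' must be a nonnegative number")
  Psi <- evaluate_basis(basis, rbind(p, q))
  sum(exp(-basis$eigenvalues * sigma) * Psi[1, ] * Psi[2, ])
}

# integral of each eigenfunction over the domain: t(1) M V  (exact for P1)
basis_integrals <- function(basis) {
  as.numeric(Matrix::crossprod(rep(1, nrow(basis$mesh$nodes)),
                               basis$mass %*% basis$eigenvectors))
}
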