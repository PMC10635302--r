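test_that("mesh construction: coarsest mesh, area conservation, refinement", {
  dom <- triangle_domain()
  m1 <- build_triangle_mesh(dom, 1)
  expect_equal(nrow(m1$nodes), 3L)
  expect_equal(nrow(m1$elements), 1L)

  m2 <- build_triangle_mesh(dom, 1 / 2)
  areas <- apply(m2$elements, 1, function(tr)
    abs(pdheat:::signed_area2(m2$nodes[tr[1], ], m2$nodes[tr[2], ],
                              m2$nodes[tr[3], ])))
  expect_equal(sum(areas), dom$area, tolerance = 1e-12)
  expect_true(all(areas > 0))

  # halving the resolution quadruples the element count
  for (res in c(1 / 2, 1 / 4, 1 / 8)) {
    a <- nrow(build_triangle_mesh(dom, res)$elements)
    b <- nrow(build_triangle_mesh(dom, res / 2)$elements)
    expect_equal(b, 4L * a)
  }
  expect_error(build_triangle_mesh(dom, -0.1), "positive")
})

test_that("Neumann eigenpairs: zero mode, closed-form spectrum, orthonormality", {
  bas <- tiny_basis()
  lam <- bas$eigenvalues
  expect_true(all(diff(lam) >= -1e-9))
  expect_lt(abs(lam[1]), 1e-7)
  # constant ground state 1/sqrt(area)
  expect_equal(unname(bas$eigenvectors[, 1]),
               rep(1 / sqrt(bas$domain$area), nrow(bas$mesh$nodes)),
               tolerance = 1e-8)
  # closed form pi^2 (m^2 + n^2) on legs of length 1; the default test mesh
  # resolves the leading modes to < 1%, a finer mesh the deeper ones
  exact <- neumann_triangle_eigenvalues(12)
  expect_lt(max(abs(lam[2:5] - exact[2:5]) / exact[2:5]), 0.01)
  fine <- solve_lb_eigenpairs(build_triangle_mesh(triangle_domain(), 1 / 70), 12)
  expect_lt(max(abs(fine$eigenvalues[2:12] - exact[2:12]) / exact[2:12]), 0.01)
  # mass-orthonormality
  G <- t(bas$eigenvectors) %*% as.matrix(bas$mass) %*% bas$eigenvectors
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
  # Neumann orthogonality to constants: eigenfunction integrals vanish
  ints <- pdheat:::basis_integrals(bas)
  expect_equal(ints[1], sqrt(bas$domain$area), tolerance = 1e-10)
  expect_lt(max(abs(ints[-1])), 1e-8)
})

test_that("spectrum error shrinks under mesh refinement", {
  dom <- triangle_domain()
  exact <- neumann_triangle_eigenvalues(6)
  err <- sapply(c(10, 20, 40), function(n) {
    b <- solve_lb_eigenpairs(build_triangle_mesh(dom, 1 / n), 6)
    max(abs(b$eigenvalues[2:6] - exact[2:6]) / exact[2:6])
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("eigenfunction evaluation: constants, nodal identity, convergence", {
  bas <- tiny_basis()
  pts <- rbind(c(0.2, 0.7), c(0.45, 0.55), c(0.1, 0.95))
  Psi <- evaluate_basis(bas, pts)
  expect_equal(Psi[, 1], rep(1 / sqrt(bas$domain$area), 3), tolerance = 1e-10)
  # interpolation identity at mesh nodes
  idx <- c(1, 11, 25)
  Psi_nodes <- evaluate_basis(bas, bas$mesh$nodes[idx, ])
  expect_equal(Psi_nodes, bas$eigenvectors[idx, ], tolerance = 1e-10)
  expect_error(evaluate_basis(bas, rbind(c(0.9, 0.1))), "outside")

  # self-convergence of interpolated values under refinement (sign-aligned)
  dom <- triangle_domain()
  set.seed(4)
  u <- runif(20); v <- runif(20)
  p <- cbind(pmin(u, v), pmax(u, v))
  p <- p[p[, 2] - p[, 1] > 0.05, , drop = FALSE]
  exact_f <- function(x, y) cos(pi * x) + cos(pi * y)   # first nonzero mode
  vals <- lapply(c(15, 30, 60), function(n) {
    b <- solve_lb_eigenpairs(build_triangle_mesh(dom, 1 / n), 3)
    f <- evaluate_basis(b, p)[, 2]
    f / sqrt(sum(f^2)) * sign(sum(f * exact_f(p[, 1], p[, 2])))
  })
  ref <- exact_f(p[, 1], p[, 2]); ref <- ref / sqrt(sum(ref^2))
  errs <- vapply(vals, function(f) max(abs(f - ref)), 0)
  expect_true(all(diff(errs) < 0))
})

test_that("heat kernel: uniform limit, unit mass, locality, symmetry", {
  bas <- tiny_basis()
  p <- c(0.2, 0.7); q <- c(0.48, 0.62)
  expect_equal(heat_kernel_value(bas, p, q, 1e3), 1 / bas$domain$area,
               tolerance = 1e-8)
  expect_equal(heat_kernel_value(bas, p, q, 0.2),
               heat_kernel_value(bas, q, p, 0.2), tolerance = 1e-12)
  # small sigma: on-diagonal value exceeds distant value
  expect_gt(heat_kernel_value(bas, p, p, 0.01),
            heat_kernel_value(bas, p, c(0.05, 0.95), 0.01))
  expect_error(heat_kernel_value(bas, p, q, -1), "nonnegative")

  # kernel mass = 1 at any truncation: integral of K_sigma(p, .) via the
  # exact eigenfunction integrals
  ints <- pdheat:::basis_integrals(bas)
  Psi <- evaluate_basis(bas, rbind(p, q))
  for (sigma in c(0, 0.05, 0.5, 5)) {
    for (r in 1:2) {
      for (kap in c(3, 10, bas$kappa + 1)) {
        mass <- sum(exp(-bas$eigenvalues[1:kap] * sigma) *
                      Psi[r, 1:kap] * ints[1:kap])
        expect_equal(mass, 1, tolerance = 1e-8)
      }
    }
  }
})

test_that("heat-kernel smoothing is a contraction on random nodal functions", {
  bas <- tiny_basis()
  M <- as.matrix(bas$mass)
  V <- bas$eigenvectors
  w <- exp(-bas$eigenvalues * 0.1)
  set.seed(9)
  for (r in 1:10) {
    g <- rnorm(nrow(M))
    coef <- as.numeric(t(V) %*% M %*% g)
    sm <- V %*% (w * coef)
    norm_g <- sqrt(as.numeric(t(g) %*% M %*% g))
    norm_sm <- sqrt(as.numeric(t(sm) %*% M %*% sm))
    expect_lte(norm_sm, norm_g + 1e-12)
  }
})

test_that("lumped mass option yields the same leading spectrum", {
  dom <- triangle_domain()
  mesh <- build_triangle_mesh(dom, 1 / 30)
  b1 <- solve_lb_eigenpairs(mesh, 5)
  b2 <- solve_lb_eigenpairs(mesh, 5, mass_lumping = TRUE)
  expect_equal(b1$eigenvalues, b2$eigenvalues, tolerance = 0.02)
  expect_equal(unname(b2$eigenvectors[, 1]),
               rep(1 / sqrt(dom$area), nrow(mesh$nodes)), tolerance = 1e-8)
})

test_that("standardization: pooled min-max map, margins, degenerate pools", {
  dom <- triangle_domain()
  pd <- persistence_diagram(rbind(c(0.5, 1.5)), 1)
  fitted <- fit_standardization(list(pd, persistence_diagram(rbind(c(0, 2)), 1)),
                                dom, margin = 0)
  std <- standardize_diagram(pd, fitted)
  expect_equal(unname(std$points), rbind(c(0.25, 0.75)))
  # margin shrinks into the interior
  fitted2 <- fit_standardization(list(persistence_diagram(rbind(c(0, 2)), 1)),
                                 dom, margin = 0.05)
  std2 <- standardize_diagram(persistence_diagram(rbind(c(0, 2)), 1), fitted2)
  expect_equal(unname(std2$points), rbind(c(0.05, 0.95)))
  # empty diagram passes through
  e <- standardize_diagram(persistence_diagram(matrix(0, 0, 2), 1), fitted)
  expect_equal(nrow(e$points), 0L)
  # degenerate (zero-range) pool maps everything to the triangle centroid
  degen <- dom
  degen$standardization <- list(offset = 1, scale = 1, margin = 0.01,
                                degenerate = TRUE)
  mapped <- pdheat:::apply_standardization(degen, rbind(c(1, 1), c(1, 1)))
  expect_equal(mapped, rbind(c(1 / 3, 2 / 3), c(1 / 3, 2 / 3)))
  unfitted <- triangle_domain()
  expect_error(standardize_diagram(pd, unfitted), "fitted")
})
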