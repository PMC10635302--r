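# Independent oracles used across the suite.  These deliberately re-derive
# everything from first principles (naive full boundary-matrix reduction,
# from-scratch statistics) and share no code with the package internals.

# --- naive persistence of the Rips complex up to dimension 1 -------------
# Full reduction over vertices, edges and triangles sorted by
# (filtration value, dimension, vertex tuple).  Returns finite pairs per
# dimension; zero-persistence pairs are dropped to match the reported
# diagrams.
brute_rips <- function(dmat, max_radius = max(dmat) * (1 + 1e-9)) {
  n <- nrow(dmat)
  simp <- list()
  for (v in seq_len(n)) simp[[length(simp) + 1]] <- list(val = 0, dim = 0, verts = v)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (dmat[i, j] <= max_radius)
      simp[[length(simp) + 1]] <- list(val = dmat[i, j], dim = 1, verts = c(i, j))
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      w <- max(dmat[i, j], dmat[i, k], dmat[j, k])
      if (w <= max_radius)
        simp[[length(simp) + 1]] <- list(val = w, dim = 2, verts = c(i, j, k))
    }
  }
  key <- vapply(simp, function(s)
    sprintf("%.17e|%d|%s", s$val, s$dim,
            paste(sprintf("%04d", s$verts), collapse = ",")), "")
  ord <- order(vapply(simp, `[[`, 0, "val"),
               vapply(simp, `[[`, 0, "dim"), key)
  simp <- simp[ord]
  ns <- length(simp)
  index_of <- new.env()
  for (s in seq_len(ns))
    assign(paste(simp[[s]]$verts, collapse = "-"), s, envir = index_of)
  bnd <- function(s) {
    v <- simp[[s]]$verts
    if (length(v) == 1) return(integer(0))
    faces <- lapply(seq_along(v), function(drop) v[-drop])
    sort(vapply(faces, function(f)
      get(paste(f, collapse = "-"), envir = index_of), 0L))
  }
  cols <- lapply(seq_len(ns), bnd)
  low <- rep(NA_integer_, ns)     # pivot row of each reduced column
  owner <- rep(NA_integer_, ns)   # pivot row -> column owning it
  for (s in seq_len(ns)) {
    col <- cols[[s]]
    while (length(col)) {
      piv <- max(col)
      if (is.na(owner[piv])) break
      other <- cols[[owner[piv]]]
      col <- sort(union(setdiff(col, other), setdiff(other, col)))
    }
    cols[[s]] <- col
    if (length(col)) {
      low[s] <- max(col)
      owner[max(col)] <- s
    }
  }
  pairs <- list(dim0 = matrix(0, 0, 2), dim1 = matrix(0, 0, 2))
  for (s in seq_len(ns)) {
    if (is.na(low[s])) next
    b <- simp[[low[s]]]$val; d <- simp[[s]]$val
    if (d <= b) next
    dm <- simp[[low[s]]]$dim
    nm <- paste0("dim", dm)
    pairs[[nm]] <- rbind(pairs[[nm]], c(b, d))
  }
  # infinite classes: positive simplices never used as pivot rows
  positive <- setdiff(which(is.na(low)), integer(0))
  inf_births <- list(dim0 = numeric(0), dim1 = numeric(0))
  for (s in positive) {
    dm <- simp[[s]]$dim
    if (dm <= 1 && is.na(owner[s]))
      inf_births[[paste0("dim", dm)]] <-
        c(inf_births[[paste0("dim", dm)]], simp[[s]]$val)
  }
  list(pairs = pairs, inf_births = inf_births)
}

sort_pairs <- function(m) {
  if (!nrow(m)) return(m)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# --- from-scratch two-sample statistic under explicit labels -------------
# X: embedded coefficient matrix; labA: logical/0-1 vector marking group A.
two_sample_stat_direct <- function(X, labA) {
  sum((colMeans(X[as.logical(labA), , drop = FALSE]) -
       colMeans(X[!as.logical(labA), , drop = FALSE]))^2)
}

# --- from-scratch TSSB/TSSW under explicit labels ------------------------
tss_direct <- function(D, labels) {
  tssb <- 0; tssw <- 0
  N <- nrow(D)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    if (labels[i] == labels[j]) tssw <- tssw + D[i, j]
    else tssb <- tssb + D[i, j]
  }
  c(tssb = tssb, tssw = tssw)
}

# closed-form Neumann eigenvalues of the right isosceles triangle with legs
# of length L: pi^2 (m^2 + n^2) / L^2 over 0 <= m <= n (symmetric cosine
# products on the folded square)
neumann_triangle_eigenvalues <- function(count, L = 1) {
  mx <- ceiling(sqrt(count)) + 3
  vals <- c()
  for (m in 0:mx) for (n in m:mx) vals <- c(vals, m^2 + n^2)
  sort(vals)[seq_len(count)] * pi^2 / L^2
}

# small helper: shared basis for cheap tests (memoized per session)
tiny_basis <- local({
  cache <- NULL
  function(kappa = 20) {
    if (is.null(cache) || cache$kappa != kappa)
      cache <<- lb_basis(kappa = kappa, resolution = 1 / 30)
    cache
  }
})

# random coefficient sets drawn from one exchangeable generator
random_coeffs <- function(n, basis, n_pts = 8) {
  lapply(seq_len(n), function(i) {
    b <- runif(n_pts, 0.05, 0.6)
    d <- b + runif(n_pts, 0.02, 0.35)
    pd <- persistence_diagram(cbind(b, d), 1)
    dom <- fit_standardization(pd, basis$domain, margin = 0.01)
    fourier_coefficients(standardize_diagram(pd, dom), basis)
  })
}
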