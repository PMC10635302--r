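#' Two-sample spectral transposition test
#'
#' Tests equality of the functional means of the heat-kernel representations
#' of two groups of persistence diagrams.  The statistic is the weighted
#' squared L2 distance between the group mean coefficient vectors,
#' \eqn{\|\bar f - \bar g\|_2^2 = \sum_k e^{-\lambda_k\sigma}(\bar f_k - \bar g_k)^2}.
#' The null distribution is sampled by a random walk of single cross-group
#' label transpositions: at every step one subject of each group is drawn
#' uniformly and swapped, the group means are updated by the transposition
#' increments (never recomputed from scratch), and the statistic is
#' recorded.  The p-value is the add-one-corrected exceedance proportion
#' `(1 + #{permuted >= observed}) / (1 + steps)`; ties count toward the
#' null.
#'
#' @param groupA,groupB lists of [fourier_coefficients()] sharing one basis;
#'   both groups need at least 2 members.
#' @param sigma bandwidth of the heat weights (default 0.1 on the
#'   standardized triangle).
#' @param eigenvalues basis eigenvalues (or the `lb_basis` itself).
#' @param n_transpositions chain length (default 1e5).
#' @param seed integer RNG seed; all chain randomness derives from it.
#' @param rerandomize_every fully re-randomize all labels (and recompute the
#'   means directly) every this many steps; `0` disables, giving the pure
#'   serially-dependent transposition walk.
#' @param return_trace keep the full statistic trace in the result.
#' @return An object of class `transposition_test`: `observed`, `p_value`,
#'   `n_transpositions`, `trace_summary` (running p-value diagnostics), and
#'   optionally `trace`.
#' @export
two_sample_test <- function(groupA, groupB, sigma = 0.1, eigenvalues,
                            n_transpositions = 1e5, seed = NULL,
                            rerandomize_every = 500, return_trace = FALSE) {
  if (inherits(eigenvalues, "lb_basis")) eigenvalues <- eigenvalues$eigenvalues
  m <- length(groupA); n <- length(groupB)
  if (m < 2 || n < 2) stop("invalid design: both groups need at least 2 subjects")
  if (n_transpositions < 1) stop("'n_transpositions' must be >= 1")
  X <- hk_embed(c(groupA, groupB), eigenvalues, sigma)
  obs <- sum((colMeans(X[seq_len(m), , drop = FALSE]) -
              colMeans(X[m + seq_len(n), , drop = FALSE]))^2)
  if (!is.null(seed)) set.seed(seed)
  chain <- two_sample_chain_cpp(X, m, n, as.integer(n_transpositions),
                                as.integer(rerandomize_every), FALSE)
  trace <- chain$trace
  p <- (1 + sum(trace >= obs)) / (1 + length(trace))
  run_p <- (1 + cumsum(trace >= obs)) / (1 + seq_along(trace))
  out <- structure(
    list(observed = obs, p_value = p, n_transpositions = length(trace),
         m = m, n = n, sigma = sigma, seed = seed,
         rerandomize_every = rerandomize_every,
         trace_summary = list(
           running_p_tail = utils::tail(run_p, 5),
           final_p = p)),
    class = "transposition_test"
  )
  if (return_trace) out$trace <- trace
  out
}

#' @export
print.transposition_test <- function(x, ...) {
  cat("Two-sample spectral transposition test\n")
  cat(sprintf("  groups: m = %d, n = %d; sigma = %g\n", x$m, x$n, x$sigma))
  cat(sprintf("  observed ||f.bar - g.bar||^2 = %.6g\n", x$observed))
  cat(sprintf("  transpositions: %d;  p-value = %.6g\n",
              x$n_transpositions, x$p_value))
  invisible(x)
}

#' Topological analysis of variance (T-ANOVA) by transpositions
#'
#' Multi-group comparison of heat-kernel represented diagrams through the
#' ratio statistic phi = TSSB / TSSW, where TSSB (TSSW) is the sum of
#' pairwise squared L2 distances between (within) groups.  All pairwise
#' distances are precomputed once; each transposition draws the two groups
#' proportionally to their sizes (distinct), the subjects uniformly, and
#' updates TSSB/TSSW incrementally.  Labels are fully re-randomized every
#' `rerandomize_every` steps with direct recomputation.  The p-value is the
#' add-one-corrected proportion of permuted phi values at or above the
#' observed phi.
#'
#' @param groups list of K >= 2 lists of [fourier_coefficients()] (each of
#'   size >= 2) sharing one basis.
#' @param sigma bandwidth.
#' @param eigenvalues basis eigenvalues (or an `lb_basis`).
#' @param n_transpositions chain length (default 1e5).
#' @param seed integer RNG seed.
#' @param rerandomize_every re-randomization period (default 500; 0 disables).
#' @param return_trace keep the phi trace.
#' @return An object of class `t_anova`: `tssb`, `tssw`, `phi`, `p_value`,
#'   `n_transpositions`, `group_sizes`, and optionally `trace`.
#' @export
t_anova <- function(groups, sigma = 0.1, eigenvalues, n_transpositions = 1e5,
                    seed = NULL, rerandomize_every = 500,
                    return_trace = FALSE) {
  if (inherits(eigenvalues, "lb_basis")) eigenvalues <- eigenvalues$eigenvalues
  K <- length(groups)
  if (K < 2) stop("invalid design: need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("invalid design: every group needs at least 2 subjects")
  D <- pairwise_distance_matrix(do.call(c, groups), sigma, eigenvalues)
  labels <- rep(seq_len(K), sizes)
  obs <- tss_decompose(D, labels)
  if (!is.null(seed)) set.seed(seed)
  chain <- tanova_chain_cpp(D, as.integer(labels),
                            as.integer(n_transpositions),
                            as.integer(rerandomize_every), FALSE)
  phi_tr <- chain$phi
  p <- (1 + sum(phi_tr >= obs$phi)) / (1 + length(phi_tr))
  out <- structure(
    list(tssb = obs$tssb, tssw = obs$tssw, phi = obs$phi, p_value = p,
         n_transpositions = length(phi_tr), group_sizes = sizes,
         sigma = sigma, seed = seed, rerandomize_every = rerandomize_every),
    class = "t_anova"
  )
  if (return_trace) {
    out$trace <- phi_tr
    out$tssb_trace <- chain$tssb
    out$tssw_trace <- chain$tssw
  }
  out
}

# direct TSSB/TSSW decomposition of a squared-distance matrix under labels
tss_decompose <- function(D, labels) {
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(D)
  tssw <- sum(D[ut & same])
  tssb <- sum(D[ut & !same])
  list(tssb = tssb, tssw = tssw, phi = tssb / tssw)
}

#' @export
print.t_anova <- function(x, ...) {
  cat("Topological analysis of variance (transposition T-ANOVA)\n")
  cat(sprintf("  groups: K = %d, sizes = (%s); sigma = %g\n",
              length(x$group_sizes), paste(x$group_sizes, collapse = ", "),
              x$sigma))
  cat(sprintf("  TSSB = %.6g, TSSW = %.6g, phi = %.6g\n",
              x$tssb, x$tssw, x$phi))
  cat(sprintf("  transpositions: %d;  p-value = %.6g\n",
              x$n_transpositions, x$p_value))
  invisible(x)
}

#' Distance-based PERMANOVA baseline
#'
#' The standard permutational multivariate ANOVA pseudo-F on a matrix of
#' squared dissimilarities, with whole-label permutations of the null:
#' `F = (SSB / (K - 1)) / (SSW / (N - K))` from the usual distance-based
#' sums of squares.  Provided as the baseline against which the
#' transposition T-ANOVA is compared.
#'
#' @param distance_matrix symmetric matrix of squared dissimilarities
#'   (e.g. from [pairwise_distance_matrix()]).
#' @param group_labels group assignment vector (>= 2 groups).
#' @param n_permutations number of whole-label permutations (default 999).
#' @param seed integer RNG seed.
#' @return An object of class `permanova`: `pseudo_f`, `ssb`, `ssw`,
#'   `p_value`, `n_permutations`, `group_sizes`.
#' @export
permanova_baseline <- function(distance_matrix, group_labels,
                               n_permutations = 999, seed = NULL) {
  D <- as.matrix(distance_matrix)
  labels <- as.integer(factor(group_labels))
  N <- nrow(D)
  if (length(labels) != N) stop("label length does not match the distance matrix")
  K <- length(unique(labels))
  if (K < 2) stop("invalid design: need at least 2 groups")
  pseudo_f <- function(lab) {
    sst <- sum(D[upper.tri(D)]) / N
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ssw <- ssw + sum(D[idx, idx][upper.tri(D[idx, idx, drop = FALSE])]) /
        length(idx)
    }
    ssb <- sst - ssw
    list(f = (ssb / (K - 1)) / (ssw / (N - K)), ssb = ssb, ssw = ssw)
  }
  obs <- pseudo_f(labels)
  if (!is.null(seed)) set.seed(seed)
  perm_f <- vapply(seq_len(n_permutations),
                   function(i) pseudo_f(sample(labels))$f, numeric(1))
  p <- (1 + sum(perm_f >= obs$f)) / (1 + n_permutations)
  structure(
    list(pseudo_f = obs$f, ssb = obs$ssb, ssw = obs$ssw, p_value = p,
         n_permutations = n_permutations,
         group_sizes = as.integer(table(labels))),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat("Distance-based PERMANOVA baseline\n")
  cat(sprintf("  sizes = (%s); pseudo-F = %.6g; p-value = %.6g (%d permutations)\n",
              paste(x$group_sizes, collapse = ", "), x$pseudo_f, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Stabilization diagnostic for a chain trace
#'
#' Declares the running exceedance p-value stabilized when it changes by
#' less than `tol` over the last `window` steps.
#'
#' @param stat_trace statistic trace of a chain.
#' @param observed observed statistic.
#' @param window number of trailing steps examined (default 5000).
#' @param tol maximal allowed change of the running p-value over the window
#'   (default 0.002).
#' @return list with `stabilized` (logical) and `running_p` (the full
#'   running p-value curve, add-one corrected).
#' @export
stabilization_check <- function(stat_trace, observed, window = 5000,
                                tol = 0.002) {
  if (!length(stat_trace)) stop("empty trace")
  run_p <- (1 + cumsum(stat_trace >= observed)) / (1 + seq_along(stat_trace))
  stab <- FALSE
  if (length(run_p) > window) {
    tail_win <- run_p[(length(run_p) - window):length(run_p)]
    stab <- (max(tail_win) - min(tail_win)) < tol
  }
  list(stabilized = stab, running_p = run_p)
}
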