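#' Run a simulation study end to end
#'
#' For each simulation: sample the group point clouds of the named design,
#' compute dimension-1 Rips persistence diagrams, standardize them on the
#' pooled coordinate range of the simulation, compute heat-kernel Fourier
#' coefficients against a shared eigenbasis, and run the requested test.
#' Returns per-simulation p-values with the usual summary (mean, sd,
#' rejection rate at 0.05).
#'
#' @param study_spec list naming the study:
#'   \describe{
#'     \item{design}{a two-sample design (`power`, `noise_fixed`,
#'       `noise_random`, `quarter_fixed`, `quarter_random`) or a three-group
#'       design (`sensitivity`, or the robustness designs again) — the
#'       `test` entry decides which family is meant.}
#'     \item{test}{`"two_sample"`, `"t_anova"` or `"permanova"`.}
#'     \item{sizes}{group sizes: length 2 for two-sample, 3 otherwise.}
#'     \item{percentage}{percentage of points on the shape (default 100).}
#'     \item{sigma, kappa, steps}{inference settings (defaults 0.1, 100,
#'       1e5).}
#'     \item{n_points}{cloud size (default 100).}
#'   }
#' @param n_sims number of simulations.
#' @param seed integer master seed; per-simulation seeds derive from it.
#' @param basis optional prebuilt [lb_basis] (built once from `kappa`
#'   otherwise).
#' @param spec a [key_shape_spec()].
#' @return data.frame of class `pd_simulation_study` with columns `sim`,
#'   `p_value`, `statistic`, and attributes `summary` and `study_spec`.
#' @export
run_simulation_study <- function(study_spec, n_sims, seed = 1, basis = NULL,
                                 spec = key_shape_spec()) {
  test <- match.arg(study_spec$test, c("two_sample", "t_anova", "permanova"))
  sizes <- study_spec$sizes
  sigma <- study_spec$sigma %||% 0.1
  kappa <- study_spec$kappa %||% 100
  steps <- study_spec$steps %||% 1e5
  pct <- study_spec$percentage %||% 100
  n_points <- study_spec$n_points %||% 100
  if (is.null(basis)) basis <- lb_basis(kappa = kappa)
  if (test == "two_sample" && length(sizes) != 2)
    stop("two-sample designs need sizes of length 2")
  if (test != "two_sample" && length(sizes) != 3)
    stop("multi-group designs need sizes of length 3")
  set.seed(seed)
  sim_seeds <- sample.int(2^31 - 2, n_sims)
  rows <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    res <- tryCatch(
      run_one_sim(study_spec$design, test, sizes, pct, sim_seeds[s], basis,
                  sigma, steps, spec, n_points),
      error = function(e) stop(sprintf("simulation %d failed: %s",
                                       s, conditionMessage(e)), call. = FALSE))
    rows[[s]] <- data.frame(sim = s, p_value = res$p_value,
                            statistic = res$statistic)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    mean_p = mean(out$p_value),
    sd_p = if (n_sims > 1) stats::sd(out$p_value) else NA_real_,
    rejection_rate_05 = mean(out$p_value < 0.05),
    n_sims = n_sims)
  attr(out, "study_spec") <- study_spec
  class(out) <- c("pd_simulation_study", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_one_sim <- function(design, test, sizes, pct, sim_seed, basis, sigma,
                        steps, spec, n_points) {
  set.seed(sim_seed)
  if (test == "two_sample") {
    setting <- make_two_sample_setting(design, sizes[1], sizes[2], pct,
                                       seed = NULL, spec = spec,
                                       n_points = n_points)
    clouds <- c(setting$groupA, setting$groupB)
    grp_len <- c(length(setting$groupA), length(setting$groupB))
  } else {
    setting <- make_anova_setting(design, sizes[1], sizes[2], sizes[3], pct,
                                  seed = NULL, spec = spec,
                                  n_points = n_points)
    clouds <- do.call(c, setting)
    grp_len <- lengths(setting)
  }
  pds <- lapply(clouds, function(cl) rips_diagram(cl, max_dimension = 1)$dim1)
  dom <- fit_standardization(pds, basis$domain)
  coeffs <- lapply(pds, function(pd)
    fourier_coefficients(standardize_diagram(pd, dom), basis))
  idx_end <- cumsum(grp_len)
  idx_start <- c(1, utils::head(idx_end, -1) + 1)
  groups <- lapply(seq_along(grp_len), function(g)
    coeffs[idx_start[g]:idx_end[g]])
  if (test == "two_sample") {
    r <- two_sample_test(groups[[1]], groups[[2]], sigma = sigma,
                         eigenvalues = basis, n_transpositions = steps,
                         seed = sim_seed %% 2147483646 + 1)
    list(p_value = r$p_value, statistic = r$observed)
  } else if (test == "t_anova") {
    r <- t_anova(groups, sigma = sigma, eigenvalues = basis,
                 n_transpositions = steps, seed = sim_seed %% 2147483646 + 1)
    list(p_value = r$p_value, statistic = r$phi)
  } else {
    D <- pairwise_distance_matrix(do.call(c, groups), sigma,
                                  basis$eigenvalues)
    labels <- rep(seq_along(grp_len), grp_len)
    r <- permanova_baseline(D, labels,
                            n_permutations = min(steps, 9999),
                            seed = sim_seed %% 2147483646 + 1)
    list(p_value = r$p_value, statistic = r$pseudo_f)
  }
}

#' @export
print.pd_simulation_study <- function(x, ...) {
  s <- attr(x, "summary")
  sp <- attr(x, "study_spec")
  cat(sprintf("Simulation study: design = %s, test = %s, %d simulations\n",
              sp$design, sp$test, s$n_sims))
  cat(sprintf("  p-value mean %s sd: %.4f %s %s\n", "±", s$mean_p,
              "±", ifelse(is.na(s$sd_p), "NA", sprintf("%.4f", s$sd_p))))
  cat(sprintf("  rejection rate at 0.05: %.2f\n", s$rejection_rate_05))
  invisible(x)
}
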