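#' Parametric key-shape specification
#'
#' The simulation shape is a key drawn inside the unit square: a circular
#' head with a concentric keyhole (the one prominent topological feature), a
#' rectangular shaft and two teeth.  Variants add either a much smaller
#' "topological noise" hole at one of four sites around the keyhole, or
#' replace the keyhole by one of its four quarter-sectors (the rest of the
#' keyhole disc filled in), which changes geometry while every quarter
#' variant keeps the same first-homology rank.
#'
#' All geometry constants are package choices (the underlying study design
#' fixes only the topology: one prominent hole, optionally a small second
#' hole).
#'
#' @param keyhole_radius radius of the keyhole disc (default 0.12).
#' @param head_radius outer radius of the head (default 0.28).
#' @param head_center center of head and keyhole (default c(0.35, 0.5)).
#' @param noise_hole_radius radius of the small noise hole (default 0.035;
#'   must stay below a third of the keyhole radius).
#' @return An object of class `key_shape_spec`.
#' @export
key_shape_spec <- function(keyhole_radius = 0.12, head_radius = 0.28,
                           head_center = c(0.35, 0.5),
                           noise_hole_radius = 0.035) {
  if (noise_hole_radius >= keyhole_radius / 3)
    stop("'noise_hole_radius' must be smaller than a third of the keyhole radius")
  site_ring <- (keyhole_radius + head_radius) / 2
  site_angles <- c(45, 135, 225, 315) * pi / 180
  sites <- cbind(head_center[1] + site_ring * cos(site_angles),
                 head_center[2] + site_ring * sin(site_angles))
  structure(
    list(
      bounding_box = c(0, 1, 0, 1),
      head_center = head_center, head_radius = head_radius,
      keyhole_radius = keyhole_radius,
      shaft = c(0.55, 0.95, 0.44, 0.56),          # xmin xmax ymin ymax
      teeth = list(c(0.82, 0.88, 0.30, 0.44), c(0.90, 0.95, 0.30, 0.44)),
      noise_hole_radius = noise_hole_radius,
      noise_hole_sites = sites,
      # quarter sectors of the keyhole, degrees: top-left, top-right,
      # bottom-left, bottom-right
      quarter_angles = list(c(90, 180), c(0, 90), c(180, 270), c(270, 360))
    ),
    class = "key_shape_spec"
  )
}

#' @export
print.key_shape_spec <- function(x, ...) {
  cat("Key-shape specification (unit square)\n")
  cat(sprintf("  head r = %g at (%g, %g); keyhole r = %g; noise hole r = %g\n",
              x$head_radius, x$head_center[1], x$head_center[2],
              x$keyhole_radius, x$noise_hole_radius))
  invisible(x)
}

in_rect <- function(xy, r) {
  xy[, 1] >= r[1] & xy[, 1] <= r[2] & xy[, 2] >= r[3] & xy[, 2] <= r[4]
}

#' Key-shape region membership
#'
#' @param spec a [key_shape_spec()].
#' @param xy n x 2 matrix of points.
#' @param variant one of `"none"`, `"quarter_1"`..`"quarter_4"`,
#'   `"noise_1"`..`"noise_4"`.
#' @return logical vector: point lies on the (possibly variant-modified)
#'   shape.
#' @export
key_region_contains <- function(spec, xy, variant = "none") {
  xy <- rbind(xy)
  dx <- xy[, 1] - spec$head_center[1]
  dy <- xy[, 2] - spec$head_center[2]
  r2 <- dx^2 + dy^2
  head_ann <- r2 <= spec$head_radius^2 & r2 >= spec$keyhole_radius^2
  base <- head_ann | in_rect(xy, spec$shaft)
  for (t in spec$teeth) base <- base | in_rect(xy, t)
  if (variant == "none") return(base)
  kind <- sub("_[0-9]$", "", variant)
  k <- as.integer(sub("^.*_", "", variant))
  if (kind == "noise") {
    if (is.na(k) || k < 1 || k > 4) stop("unknown variant: ", variant)
    site <- spec$noise_hole_sites[k, ]
    hole <- (xy[, 1] - site[1])^2 + (xy[, 2] - site[2])^2 <=
      spec$noise_hole_radius^2
    return(base & !hole)
  }
  if (kind == "quarter") {
    if (is.na(k) || k < 1 || k > 4) stop("unknown variant: ", variant)
    ang <- spec$quarter_angles[[k]] * pi / 180
    theta <- atan2(dy, dx) %% (2 * pi)
    in_keyhole <- r2 < spec$keyhole_radius^2
    in_sector <- theta >= ang[1] & theta < ang[2]
    # keyhole filled except the retained quarter-sector
    return(base | (in_keyhole & !in_sector))
  }
  stop("unknown variant: ", variant)
}

resolve_variant <- function(variant) {
  if (variant == "random_noise") paste0("noise_", sample.int(4, 1))
  else if (variant == "random_quarter") paste0("quarter_", sample.int(4, 1))
  else variant
}

#' Sample a key-shape point cloud
#'
#' `round(frac_on_shape * n_points)` points (round half up) are drawn
#' uniformly on the (variant-modified) shape region by rejection sampling;
#' the remainder is uniform on the bounding rectangle.
#'
#' @param spec a [key_shape_spec()].
#' @param n_points cloud size (default 100).
#' @param frac_on_shape fraction of points on the shape, in `[0, 1]`.
#' @param variant `"none"`, `"quarter_1"`..`"quarter_4"`,
#'   `"noise_1"`..`"noise_4"`, `"random_quarter"`, `"random_noise"` (random
#'   variants are resolved once per cloud).
#' @param seed optional integer seed (sampling also respects the ambient RNG
#'   state when `seed` is `NULL`).
#' @return A [point_cloud()]; its label records the resolved variant.
#' @export
sample_key_cloud <- function(spec, n_points = 100, frac_on_shape = 1,
                             variant = "none", seed = NULL) {
  if (n_points < 1) stop("'n_points' must be >= 1")
  if (frac_on_shape < 0 || frac_on_shape > 1) stop("'frac_on_shape' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  variant <- resolve_variant(variant)
  n_on <- as.integer(floor(frac_on_shape * n_points + 0.5))
  n_off <- n_points - n_on
  bb <- spec$bounding_box
  pts <- matrix(0, 0, 2)
  while (nrow(pts) < n_on) {
    cand <- cbind(stats::runif(4 * (n_on - nrow(pts)) + 16, bb[1], bb[2]),
                  stats::runif(4 * (n_on - nrow(pts)) + 16, bb[3], bb[4]))
    keep <- key_region_contains(spec, cand, variant)
    if (!any(keep) && nrow(pts) == 0 && n_on > 0) {
      # a few empty batches are expected; a structurally empty region is not
      probe <- cbind(stats::runif(20000, bb[1], bb[2]),
                     stats::runif(20000, bb[3], bb[4]))
      if (!any(key_region_contains(spec, probe, variant)))
        stop("variant produced an empty shape region")
      next
    }
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n_on), , drop = FALSE]
  if (n_off > 0) {
    pts <- rbind(pts, cbind(stats::runif(n_off, bb[1], bb[2]),
                            stats::runif(n_off, bb[3], bb[4])))
  }
  point_cloud(pts, label = sprintf("key[%s] frac=%g", variant, frac_on_shape))
}

two_sample_designs <- c("power", "noise_fixed", "noise_random",
                        "quarter_fixed", "quarter_random")

#' Generate a two-group simulation setting
#'
#' Group compositions of the two-sample simulation studies:
#' \describe{
#'   \item{power}{group 1 uniform on the rectangle, group 2 on the key shape
#'     with `percentage` of its points on the shape.}
#'   \item{noise_fixed / noise_random}{group 1 on the plain key shape, group
#'     2 with the small extra noise hole at site 1 (fixed) or a random site
#'     per cloud.}
#'   \item{quarter_fixed / quarter_random}{group 1 with only the top-left
#'     keyhole quarter retained, group 2 with the bottom-right quarter
#'     (fixed) or a random quarter per cloud.}
#' }
#' In the robustness settings both groups carry `percentage` of their points
#' on the shape.
#'
#' @param setting_name one of `r paste(two_sample_designs, collapse=", ")`.
#' @param m,n group sizes.
#' @param percentage percentage (0-100) of cloud points on the shape.
#' @param seed integer seed.
#' @param spec a [key_shape_spec()].
#' @param n_points points per cloud (default 100).
#' @return list with elements `groupA`, `groupB` (lists of [point_cloud()]).
#' @export
make_two_sample_setting <- function(setting_name, m, n, percentage = 100,
                                    seed = NULL, spec = key_shape_spec(),
                                    n_points = 100) {
  if (!setting_name %in% two_sample_designs)
    stop("unknown setting '", setting_name, "'; valid: ",
         paste(two_sample_designs, collapse = ", "))
  if (m < 1 || n < 1) stop("group sizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  frac <- percentage / 100
  cfg <- switch(setting_name,
    power          = list(a = list(frac = 0,    var = "none"),
                          b = list(frac = frac, var = "none")),
    noise_fixed    = list(a = list(frac = frac, var = "none"),
                          b = list(frac = frac, var = "noise_1")),
    noise_random   = list(a = list(frac = frac, var = "none"),
                          b = list(frac = frac, var = "random_noise")),
    quarter_fixed  = list(a = list(frac = frac, var = "quarter_1"),
                          b = list(frac = frac, var = "quarter_4")),
    quarter_random = list(a = list(frac = frac, var = "quarter_1"),
                          b = list(frac = frac, var = "random_quarter")))
  list(
    groupA = lapply(seq_len(m), function(i)
      sample_key_cloud(spec, n_points, cfg$a$frac, cfg$a$var)),
    groupB = lapply(seq_len(n), function(i)
      sample_key_cloud(spec, n_points, cfg$b$frac, cfg$b$var))
  )
}

anova_designs <- c("sensitivity", "noise_fixed", "noise_random",
                   "quarter_fixed", "quarter_random")

#' Generate a three-group simulation setting
#'
#' `sensitivity` puts the key shape only in group 3 (groups 1-2 are
#' rectangle clouds); the robustness settings apply the same variant family
#' to all three groups (fixed variants use site/quarter 1 everywhere, random
#' variants are drawn per cloud).
#'
#' @param setting_name one of `r paste(anova_designs, collapse=", ")`.
#' @param n1,n2,n3 group sizes.
#' @inheritParams make_two_sample_setting
#' @return list of three lists of [point_cloud()].
#' @export
make_anova_setting <- function(setting_name, n1, n2, n3, percentage = 100,
                               seed = NULL, spec = key_shape_spec(),
                               n_points = 100) {
  if (!setting_name %in% anova_designs)
    stop("unknown setting '", setting_name, "'; valid: ",
         paste(anova_designs, collapse = ", "))
  sizes <- c(n1, n2, n3)
  if (any(sizes < 1)) stop("group sizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  frac <- percentage / 100
  per_group <- switch(setting_name,
    sensitivity    = list(list(frac = 0, var = "none"),
                          list(frac = 0, var = "none"),
                          list(frac = frac, var = "none")),
    noise_fixed    = rep(list(list(frac = frac, var = "noise_1")), 3),
    noise_random   = rep(list(list(frac = frac, var = "random_noise")), 3),
    quarter_fixed  = rep(list(list(frac = frac, var = "quarter_1")), 3),
    quarter_random = rep(list(list(frac = frac, var = "random_quarter")), 3))
  lapply(seq_len(3), function(g)
    lapply(seq_len(sizes[g]), function(i)
      sample_key_cloud(spec, n_points, per_group[[g]]$frac, per_group[[g]]$var)))
}
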