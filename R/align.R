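#' Alignment configuration
#'
#' @param W_O weight (> 1) of filled orientation-marker sites in the 2D
#'   cost: residuals at matched markers count `W_O`-fold, forcing markers
#'   to fit tightly. Keep it moderate -- large values subsidize placements
#'   that strand the markers entirely (see the package vignette)
#' @param rot_step coarse rotation step, degrees
#' @param trans_step,trans_range coarse translation step and half-range, nm
#'   (the grid is centered on the centroid center of mass)
#' @param scale_bounds allowed `[s_min, s_max]` for the anisotropic scales;
#'   bounds away from 0 forbid the template collapsing onto one cluster
#' @param mode `"two_stage"` (coarse rotation x translation grid, then
#'   simultaneous local refinement of all five parameters) or `"global"`
#'   (seeded multi-start refinement over the full transform box)
#' @param n_starts starts for `"global"` mode
#' @param z_scale_grid candidate z scale factors for the 3D search (applied
#'   to the centroid z values)
#' @param phi_step 3D rotation step about z, degrees (full 360 covered)
#' @param trans_step_3d,trans_range_3d 3D translation step / half-range, nm
#' @param tz_grid z-translation offsets for the 3D search; the default
#'   single 0 skips the z translation (centroid and template centers of
#'   mass differ negligibly along z)
#' @param seed RNG seed (used by `"global"` mode)
#' @return object of class `alignment_config`
#' @export
alignment_config <- function(W_O = 1.3, rot_step = 2, trans_step = 4,
                             trans_range = 30, scale_bounds = c(0.7, 1.3),
                             mode = c("two_stage", "global"), n_starts = 40L,
                             z_scale_grid = seq(1, 5, by = 0.1),
                             phi_step = 2, trans_step_3d = 2,
                             trans_range_3d = 20, tz_grid = 0, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(W_O > 1, scale_bounds[1] > 0, scale_bounds[1] <= scale_bounds[2],
            rot_step > 0, trans_step > 0, phi_step > 0)
  structure(list(W_O = W_O, rot_step = rot_step, trans_step = trans_step,
                 trans_range = trans_range, scale_bounds = scale_bounds,
                 mode = mode, n_starts = as.integer(n_starts),
                 z_scale_grid = z_scale_grid, phi_step = phi_step,
                 trans_step_3d = trans_step_3d,
                 trans_range_3d = trans_range_3d, tz_grid = tz_grid,
                 seed = as.integer(seed)),
            class = "alignment_config")
}

#' 2D template transform
#'
#' Application order is fixed: rotate by `theta`, scale x by `sx`, scale y
#' by `sy`, translate by `(tx, ty)`. Rotating before the anisotropic
#' scaling lets the transformed template shear, absorbing
#' immobilization-distorted origami.
#'
#' @param theta rotation, degrees
#' @param sx,sy axis scales (unitless)
#' @param tx,ty translation, nm
#' @return object of class `transform_2d`
#' @export
transform_2d <- function(theta = 0, sx = 1, sy = 1, tx = 0, ty = 0) {
  structure(list(theta = theta, sx = sx, sy = sy, tx = tx, ty = ty),
            class = "transform_2d")
}

#' @export
print.transform_2d <- function(x, ...) {
  cat(sprintf("<transform_2d> theta = %.2f deg, sx = %.3f, sy = %.3f, t = (%.1f, %.1f) nm\n",
              x$theta, x$sx, x$sy, x$tx, x$ty))
  invisible(x)
}

transform_linear <- function(tr) diag(c(tr$sx, tr$sy)) %*% rot2(tr$theta)

#' Apply a 2D transform to a point set
#'
#' @param tr a [transform_2d()]
#' @param xy n x 2 matrix
#' @return transformed n x 2 matrix
#' @export
apply_transform_2d <- function(tr, xy) {
  out <- xy %*% t(transform_linear(tr))
  out[, 1] <- out[, 1] + tr$tx
  out[, 2] <- out[, 2] + tr$ty
  out
}

template_xy <- function(rule) unname(as.matrix(rule$sites[, c("x", "y")]))

template_xyz <- function(rule) unname(as.matrix(rule$sites[, c("x", "y", "z")]))

#' Weighted 2D alignment cost
#'
#' Applies `transform` to the rule's template and evaluates
#' `C = sqrt(D + 1) / n * sum_i (|A_i - B_i| P_i S_i)^2`, where `B_i` is
#' the transformed site nearest to centroid `A_i` (ties broken towards the
#' lowest site index), `P_i = W_O` when `B_i` is a filled orientation
#' marker (else 1), `S_i` the cluster size, and `D` the number of filled
#' markers that are nearest site to no centroid. Assignment is independent
#' per centroid; several centroids may share a site.
#'
#' @param centroids n x 2 matrix of cluster centroids (nm)
#' @param sizes localization count per cluster (length n)
#' @param rule a [pattern_rule()] supplying template sites and marker roles
#' @param transform a [transform_2d()]
#' @param cfg an [alignment_config()] (supplies `W_O` and scale bounds)
#' @return list with `cost`, `assignment` (centroid -> site index), `D`
#' @export
cost_2d <- function(centroids, sizes, rule, transform, cfg = alignment_config()) {
  centroids <- as_matrix_2d(centroids)
  stopifnot(nrow(centroids) >= 1, length(sizes) == nrow(centroids))
  if (transform$sx < cfg$scale_bounds[1] || transform$sx > cfg$scale_bounds[2] ||
      transform$sy < cfg$scale_bounds[1] || transform$sy > cfg$scale_bounds[2]) {
    stop("degenerate transform: scales outside [",
         cfg$scale_bounds[1], ", ", cfg$scale_bounds[2], "]")
  }
  Tm <- apply_transform_2d(transform, template_xy(rule))
  cost_2d_cpp(centroids, as.numeric(sizes), Tm,
              rule$sites$role == "marker_filled", cfg$W_O)
}

as_matrix_2d <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y")])
  unname(as.matrix(x))[, 1:2, drop = FALSE]
}

#' Fit the 2D template alignment
#'
#' Stage 1 scans a coarse rotation x translation grid (scales fixed at 1,
#' grid centered on the centroid center of mass); stage 2 refines all five
#' transform parameters simultaneously with box-constrained quasi-Newton
#' minimization of [cost_2d()]. `mode = "global"` instead refines from
#' `n_starts` seeded random transforms spanning the full box. The shear
#' angle `alpha` is the deviation from orthogonality of the images of the
#' template axes under the fitted linear map.
#'
#' @inheritParams cost_2d
#' @return object of class `alignment_result`: `transform`, `cost`,
#'   `assignment`, `D`, `alpha` (degrees), `accepted`
#' @export
align_2d <- function(centroids, sizes, rule, cfg = alignment_config()) {
  A <- as_matrix_2d(centroids)
  S <- as.numeric(sizes)
  stopifnot(nrow(A) >= 1, length(S) == nrow(A))
  Tm <- template_xy(rule)
  marker <- rule$sites$role == "marker_filled"
  ctr <- colMeans(Tm)
  com <- colMeans(A)

  obj <- function(par) {
    tr <- transform_2d(par[1], par[2], par[3], par[4], par[5])
    Tt <- apply_transform_2d(tr, Tm)
    cost_2d_cpp(A, S, Tt, marker, cfg$W_O)$cost
  }

  refine <- function(par0, theta_halfwidth, trans_halfwidth) {
    lower <- c(par0[1] - theta_halfwidth, cfg$scale_bounds[1], cfg$scale_bounds[1],
               par0[4] - trans_halfwidth, par0[5] - trans_halfwidth)
    upper <- c(par0[1] + theta_halfwidth, cfg$scale_bounds[2], cfg$scale_bounds[2],
               par0[4] + trans_halfwidth, par0[5] + trans_halfwidth)
    tryCatch(stats::optim(par0, obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 60L, factr = 1e9)),
             error = function(e) list(par = par0, value = obj(par0)))
  }

  if (cfg$mode == "two_stage") {
    thetas <- seq(0, 360 - cfg$rot_step, by = cfg$rot_step)
    offs <- seq(-cfg$trans_range, cfg$trans_range, by = cfg$trans_step)
    coarse <- coarse_align_2d_cpp(A, S, Tm, marker, cfg$W_O,
                                  thetas, offs, offs, com)
    ## coarse places the template centroid at (ox, oy) after rotation about
    ## the centroid; as a canonical (rotate-about-origin) transform:
    R <- rot2(coarse$theta)
    t0 <- c(coarse$ox, coarse$oy) - as.vector(R %*% ctr)
    fit <- refine(c(coarse$theta, 1, 1, t0[1], t0[2]),
                  theta_halfwidth = 1.5 * cfg$rot_step,
                  trans_halfwidth = 1.5 * cfg$trans_step)
  } else {
    set.seed(cfg$seed)
    best <- NULL
    for (i in seq_len(cfg$n_starts)) {
      par0 <- c(stats::runif(1, 0, 360),
                stats::runif(2, cfg$scale_bounds[1], cfg$scale_bounds[2]),
                com[1] + stats::runif(1, -cfg$trans_range, cfg$trans_range),
                com[2] + stats::runif(1, -cfg$trans_range, cfg$trans_range))
      fit_i <- refine(par0, theta_halfwidth = 180,
                      trans_halfwidth = cfg$trans_range)
      if (is.null(best) || fit_i$value < best$value) best <- fit_i
    }
    fit <- best
  }
  if (!is.finite(fit$value)) reject_particle("2D alignment optimizer failed")

  tr <- transform_2d(fit$par[1] %% 360, fit$par[2], fit$par[3],
                     fit$par[4], fit$par[5])
  final <- cost_2d(A, S, rule, tr, cfg)
  structure(list(transform = tr, cost = final$cost,
                 assignment = final$assignment, D = final$D,
                 alpha = shear_angle_deg(transform_linear(tr)),
                 accepted = TRUE, n = nrow(A), dim = 2L),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %dD, n = %d centroids, cost = %.4g, D = %d%s%s\n",
              x$dim, x$n, x$cost, x$D,
              if (is.finite(x$alpha)) sprintf(", alpha = %.2f deg", x$alpha) else "",
              if (x$accepted) "" else " [rejected]"))
  print(x$transform)
  invisible(x)
}

#' 3D transform of the z-scale / z-rotation family
#'
#' `z_scale` divides the template z extent (modelling the axial compression
#' of the imaged structure relative to the design; the reported value is
#' the expansion factor that would restore the design height); `phi`
#' rotates the template about the z axis through its center of mass, which
#' is then translated to `(tx, ty, tz)`.
#'
#' @param z_scale axial compression factor fitted to the template, `> 0`
#' @param phi rotation about z, degrees
#' @param tx,ty,tz template center-of-mass target, nm
#' @return object of class `transform_3d`
#' @export
transform_3d <- function(z_scale = 1, phi = 0, tx = 0, ty = 0, tz = 0) {
  stopifnot(z_scale > 0)
  structure(list(z_scale = z_scale, phi = phi, tx = tx, ty = ty, tz = tz),
            class = "transform_3d")
}

#' @export
print.transform_3d <- function(x, ...) {
  cat(sprintf("<transform_3d> z_scale = %.2f, phi = %.1f deg, com -> (%.1f, %.1f, %.1f) nm\n",
              x$z_scale, x$phi, x$tx, x$ty, x$tz))
  invisible(x)
}

#' Unweighted 3D alignment cost
#'
#' `C = sum_i |A_i - B_i|^2` with nearest-site assignment after applying
#' `transform` to the template (z compression, rotation about z,
#' translation of the center of mass).
#'
#' @param centroids n x 3 matrix (nm)
#' @param rule a [pattern_rule()]
#' @param transform a [transform_3d()]
#' @return list with `cost`, `assignment`
#' @export
cost_3d <- function(centroids, rule, transform = transform_3d()) {
  A <- unname(as.matrix(centroids))[, 1:3, drop = FALSE]
  cost_3d_cpp(A, transformed_template_3d(transform, rule))
}

transformed_template_3d <- function(tr, rule) {
  Tm <- template_xyz(rule)
  Tm <- sweep(Tm, 2, colMeans(Tm))
  Tm[, 3] <- Tm[, 3] / tr$z_scale
  R <- diag(3)
  R[1:2, 1:2] <- rot2(tr$phi)
  Tm <- Tm %*% t(R)
  sweep(Tm, 2, c(tr$tx, tr$ty, tr$tz), `+`)
}

#' Fit the 3D template alignment
#'
#' The template center of mass is aligned with the centroid center of
#' mass, then a grid over the z-scale candidates, the full 360 degrees of
#' z rotation and x/y translation offsets is searched for the minimal
#' [cost_3d()]. z translation is skipped unless `cfg$tz_grid` contains
#' nonzero offsets. Rotationally degenerate layouts (the cuboctahedron
#' vertex set is 4-fold symmetric about z) produce near-tied minima that
#' differ only in which sites the centroids match; among candidates within
#' `tie_factor` of the minimal cost, the cheapest one passing
#' [marker_check()] is preferred. Particles whose final alignment still
#' strands a filled orientation marker, or matches a deliberately empty
#' marker site, are flagged not accepted.
#'
#' @inheritParams cost_3d
#' @param cfg an [alignment_config()]
#' @param tie_factor cost ratio within which candidate rotations count as
#'   tied for marker-based disambiguation
#' @return an `alignment_result` with a [transform_3d()]
#' @export
align_3d <- function(centroids, rule, cfg = alignment_config(),
                     tie_factor = 1.5) {
  A <- unname(as.matrix(centroids))[, 1:3, drop = FALSE]
  if (length(cfg$z_scale_grid) == 0 || cfg$phi_step <= 0) {
    stop("empty 3D search grid")
  }
  Tm <- template_xyz(rule)
  phis <- seq(0, 360 - cfg$phi_step, by = cfg$phi_step)
  offs <- seq(-cfg$trans_range_3d, cfg$trans_range_3d, by = cfg$trans_step_3d)
  g <- grid_align_3d_cpp(A, Tm, cfg$z_scale_grid, phis, offs, offs,
                         cfg$tz_grid)
  as_result <- function(i) {
    tr <- transform_3d(g$z_scale[i], g$phi[i], g$ox[i], g$oy[i], g$oz[i])
    final <- cost_3d(A, rule, tr)
    res <- structure(list(transform = tr, cost = final$cost,
                          assignment = final$assignment,
                          D = marker_miss_count(final$assignment, rule),
                          alpha = NA_real_, accepted = TRUE,
                          n = nrow(A), dim = 3L),
                     class = "alignment_result")
    res$accepted <- marker_check(res, rule)
    res
  }
  ord <- order(g$cost)
  cmin <- g$cost[ord[1]]
  best <- NULL
  for (i in ord) {
    if (g$cost[i] > cmin * tie_factor) break
    res <- as_result(i)
    if (res$accepted) { best <- res; break }
    if (is.null(best)) best <- res
  }
  if (is.null(best)) best <- as_result(ord[1])
  best
}

marker_miss_count <- function(assignment, rule) {
  sum(!(filled_marker_sites(rule) %in% assignment))
}

#' Orientation-marker acceptance check
#'
#' For 3D rules a particle is accepted only when every filled orientation
#' marker is the nearest site of at least one centroid and no deliberately
#' empty marker site is matched by any centroid. For 2D rules the check
#' always accepts: markers enter the 2D fit through the `W_O` weighting and
#' the `sqrt(D + 1)` penalty instead.
#'
#' @param result an `alignment_result`
#' @param rule a [pattern_rule()]
#' @return logical
#' @export
marker_check <- function(result, rule) {
  if (result$dim == 2L) return(TRUE)
  all(filled_marker_sites(rule) %in% result$assignment) &&
    !any(empty_marker_sites(rule) %in% result$assignment)
}

#' Least-squares superposition with a z-scale search
#'
#' For each candidate z scale, `cloudA` (with z multiplied by the
#' candidate) is rigidly superposed onto `cloudB` by the SVD (Kabsch)
#' solution of the corresponded least-squares problem, and the scale with
#' the lowest RMSD wins. Points must correspond row by row.
#'
#' @param cloudA,cloudB n x 3 matrices with known row correspondence,
#'   `n >= 3` and not collinear
#' @param z_scale_grid candidate z scales
#' @return list with `rotation` (3 x 3), `translation`, `z_scale`, `rmsd`,
#'   `rmsd_curve` (named by scale)
#' @export
superpose_with_z_scale <- function(cloudA, cloudB, z_scale_grid = seq(1, 5, 0.1)) {
  A0 <- unname(as.matrix(cloudA)); B <- unname(as.matrix(cloudB))
  stopifnot(ncol(A0) == 3, ncol(B) == 3, nrow(A0) == nrow(B))
  if (nrow(A0) < 3 || qr(sweep(A0, 2, colMeans(A0)))$rank < 2) {
    stop("need at least 3 non-collinear corresponded points")
  }
  rmsd_curve <- numeric(length(z_scale_grid))
  fits <- vector("list", length(z_scale_grid))
  for (i in seq_along(z_scale_grid)) {
    A <- A0
    A[, 3] <- A[, 3] * z_scale_grid[i]
    fits[[i]] <- kabsch(A, B)
    rmsd_curve[i] <- fits[[i]]$rmsd
  }
  names(rmsd_curve) <- z_scale_grid
  i <- which.min(rmsd_curve)
  list(rotation = fits[[i]]$R, translation = fits[[i]]$t,
       z_scale = z_scale_grid[i], rmsd = rmsd_curve[i],
       rmsd_curve = rmsd_curve)
}

## corresponded rigid superposition (proper rotation), minimizing
## ||R A + t - B||_F
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cb - as.vector(R %*% ca)
  fitted <- sweep(A %*% t(R), 2, t_vec, `+`)
  list(R = R, t = t_vec, rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}
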