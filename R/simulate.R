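#' Generator configuration for synthetic DNA-PAINT localization data
#'
#' The generator emulates the statistical structure of pre-picked DNA-PAINT
#' particle data: per-site Bernoulli detection (optionally with a
#' center-high / corner-low gradient), a Poisson number of localizations per
#' detected site spread with the lateral (and, for 3D geometries, axial)
#' localization precision, a uniform background, and a per-particle random
#' transform -- in-plane rotation, a small immobilization shear injected as
#' an area-preserving axis-ratio combined with the rotation (the same
#' rotate-then-scale family the 2D aligner fits), a translation jitter, and
#' a multiplicative z compression modelling the axial collapse of flexible
#' 3D structures.
#'
#' @param detection_map per-site detection probability: a scalar in `[0,1]`
#'   or a vector with one probability per site (see [detection_gradient()])
#' @param locs_per_site_mean expected localizations per detected site
#' @param sigma_xy lateral localization SD per site, nm (per-spot extent of
#'   roughly 4 sigma stays within the 10 nm the imaging resolves)
#' @param sigma_z axial localization SD per site, nm (3D geometries): the
#'   per-localization axial precision. Structure flexibility is modelled
#'   separately by `z_compression`, not folded into `sigma_z`
#' @param background_rate expected spurious localizations per particle
#' @param rotation_range in-plane rotation is uniform over this range
#'   (degrees)
#' @param shear_alpha_sd SD (degrees) of the Gaussian target shear angle
#' @param translation_sigma SD (nm) of the particle translation jitter
#' @param z_compression multiplicative factor applied to true site z before
#'   noise (`1` = rigid; flexible wireframes compress to roughly 1/3.3)
#' @param n_frames frame index range for the synthetic frame column
#' @return an object of class `generator_config`
#' @export
generator_config <- function(detection_map = 0.89,
                             locs_per_site_mean = 30,
                             sigma_xy = 2.5,
                             sigma_z = 6,
                             background_rate = 2,
                             rotation_range = c(0, 360),
                             shear_alpha_sd = 3,
                             translation_sigma = 5,
                             z_compression = 1,
                             n_frames = 30000L) {
  stopifnot(all(detection_map >= 0), all(detection_map <= 1),
            locs_per_site_mean >= 0, sigma_xy >= 0, sigma_z >= 0,
            background_rate >= 0, z_compression > 0,
            shear_alpha_sd >= 0, translation_sigma >= 0)
  structure(list(detection_map = detection_map,
                 locs_per_site_mean = locs_per_site_mean,
                 sigma_xy = sigma_xy, sigma_z = sigma_z,
                 background_rate = background_rate,
                 rotation_range = rotation_range,
                 shear_alpha_sd = shear_alpha_sd,
                 translation_sigma = translation_sigma,
                 z_compression = z_compression,
                 n_frames = as.integer(n_frames)),
            class = "generator_config")
}

#' Center-high / corner-low per-site detection probabilities
#'
#' Interpolates between a corner and a center detection probability by the
#' site's radial distance from the layout centroid (in the xy plane),
#' emulating the systematic detection gradient observed across rectangular
#' origami. The map is symmetric under the layout's rotational symmetries.
#'
#' @param rule a [pattern_rule()]
#' @param center,corner detection probability at the layout center / at the
#'   most distant site
#' @return numeric vector, one probability per site
#' @export
detection_gradient <- function(rule, center = 0.95, corner = 0.85) {
  r <- sqrt(rule$sites$x^2 + rule$sites$y^2)
  w <- if (max(r) > 0) r / max(r) else r * 0
  center - (center - corner) * w
}

## shear angle (deg) of the linear map [u1 u2]: deviation of the angle
## between the images of the unit axes from 90 degrees
shear_angle_deg <- function(L) {
  u1 <- L[, 1]; u2 <- L[, 2]
  ang <- acos(pmin(1, pmax(-1, sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2)))))
  90 - ang * 180 / pi
}

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
}

## linear part of the particle transform: rotate theta, then scale by
## (1/sqrt(r), sqrt(r)); r solved so the implied shear angle hits
## alpha_target where attainable (at theta near multiples of 90 degrees the
## family cannot shear, and the closest attainable angle is used)
particle_linear_map <- function(theta_deg, alpha_target, r_bounds = c(0.8, 1.25)) {
  f <- function(r) shear_angle_deg(diag(c(1 / sqrt(r), sqrt(r))) %*% rot2(theta_deg))
  lo <- f(r_bounds[1]); hi <- f(r_bounds[2])
  target <- min(max(alpha_target, min(lo, hi)), max(lo, hi))
  r <- if (abs(hi - lo) < 1e-12) 1 else
    stats::uniroot(function(r) f(r) - target, r_bounds, tol = 1e-10)$root
  diag(c(1 / sqrt(r), sqrt(r))) %*% rot2(theta_deg)
}

#' Simulate one particle's localization cloud
#'
#' Every occupied site of `pattern` is detected independently with its
#' detection probability; each detected site emits `Poisson(locs_per_site_mean)`
#' localizations around the transformed site position with `sigma_xy` (and
#' `sigma_z` after `z_compression`, when the geometry is 3D); background
#' localizations are uniform over the particle bounding box.
#'
#' @param pattern a `bit_pattern` (see [encode_message()], [full_pattern()])
#' @param rule a [pattern_rule()]
#' @param cfg a [generator_config()]
#' @param seed integer seed; identical seeds give identical output
#' @param particle_id id stored in the table
#' @return list with `locs` (data.frame: `particle_id`, `frame`, `x`, `y`,
#'   `z`, `sigma_xy`, `sigma_z`) and `truth` (list: transform parameters,
#'   per-site detection mask, true character/position)
#' @export
simulate_particle <- function(pattern, rule, cfg, seed, particle_id = 1L) {
  stopifnot(inherits(pattern, "bit_pattern"), inherits(rule, "pattern_rule"),
            inherits(cfg, "generator_config"))
  set.seed(as.integer(seed))
  ns <- n_sites(rule)
  p <- rep(cfg$detection_map, length.out = ns)
  three_d <- is_rule_3d(rule)

  detected <- pattern$occupied & (stats::runif(ns) < p)

  theta <- stats::runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
  alpha_target <- stats::rnorm(1, 0, cfg$shear_alpha_sd)
  L <- particle_linear_map(theta, alpha_target)
  tx <- stats::rnorm(1, 0, cfg$translation_sigma)
  ty <- stats::rnorm(1, 0, cfg$translation_sigma)

  xy <- as.matrix(rule$sites[, c("x", "y")]) %*% t(L)
  xy <- sweep(xy, 2, c(tx, ty), `+`)
  z_true <- rule$sites$z * cfg$z_compression

  counts <- stats::rpois(ns, cfg$locs_per_site_mean) * detected
  idx <- rep(seq_len(ns), counts)
  n_loc <- length(idx)
  x <- xy[idx, 1] + stats::rnorm(n_loc, 0, cfg$sigma_xy)
  y <- xy[idx, 2] + stats::rnorm(n_loc, 0, cfg$sigma_xy)
  z <- if (three_d) z_true[idx] + stats::rnorm(n_loc, 0, cfg$sigma_z) else numeric(n_loc)

  n_bg <- stats::rpois(1, cfg$background_rate)
  if (n_bg > 0) {
    pad <- 3 * cfg$sigma_xy
    bx <- stats::runif(n_bg, min(xy[, 1]) - pad, max(xy[, 1]) + pad)
    by <- stats::runif(n_bg, min(xy[, 2]) - pad, max(xy[, 2]) + pad)
    bz <- if (three_d) {
      padz <- 3 * cfg$sigma_z
      stats::runif(n_bg, min(z_true) - padz, max(z_true) + padz)
    } else numeric(n_bg)
    x <- c(x, bx); y <- c(y, by); z <- c(z, bz)
    n_loc <- n_loc + n_bg
  }

  locs <- data.frame(particle_id = rep(as.integer(particle_id), n_loc),
                     frame = if (n_loc) sort(sample.int(cfg$n_frames, n_loc,
                                                        replace = TRUE)) else integer(0),
                     x = x, y = y, z = z,
                     sigma_xy = rep(cfg$sigma_xy, n_loc),
                     sigma_z = rep(if (three_d) cfg$sigma_z else 0, n_loc))
  truth <- list(particle_id = as.integer(particle_id),
                character = pattern$character, position = pattern$position,
                theta = theta, alpha = shear_angle_deg(L),
                sx = sqrt(sum(L[, 1]^2) / sum(rot2(theta)[, 1]^2)),
                tx = tx, ty = ty,
                linear = L, mask = detected)
  list(locs = locs, truth = truth)
}

#' Simulate a full message dataset with ground truth
#'
#' Encodes `text` under `rule`/`cmap` and simulates `n_per_char`
#' independent particles per character, with independent per-particle
#' transforms. All randomness flows from `seed` through per-particle
#' substream seeds, so the same seed reproduces the dataset bit for bit.
#'
#' @inheritParams simulate_particle
#' @param text message to encode
#' @param cmap a [character_map()]
#' @param n_per_char particles per character, `>= 1`
#' @param seed master seed
#' @return list with `locs` (all particles, row-bound), `truth`
#'   (data.frame: one row per particle: `particle_id`, `character`,
#'   `position`, `theta`, `alpha`, `tx`, `ty`), `masks` (detection masks,
#'   particles x sites), `rule`, `text`
#' @export
simulate_dataset <- function(text, rule, cmap, n_per_char, cfg, seed) {
  stopifnot(n_per_char >= 1)
  patterns <- encode_message(text, rule, cmap)
  n_total <- n_per_char * length(patterns)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(2147483646L, n_total)
  pid <- 0L
  locs <- vector("list", n_total)
  rows <- vector("list", n_total)
  masks <- matrix(FALSE, n_total, n_sites(rule))
  for (pat in patterns) {
    for (i in seq_len(n_per_char)) {
      pid <- pid + 1L
      sim <- simulate_particle(pat, rule, cfg, sub_seeds[pid], particle_id = pid)
      locs[[pid]] <- sim$locs
      tr <- sim$truth
      rows[[pid]] <- data.frame(particle_id = pid, character = tr$character,
                                position = tr$position, theta = tr$theta,
                                alpha = tr$alpha, tx = tr$tx, ty = tr$ty)
      masks[pid, ] <- tr$mask
    }
  }
  list(locs = do.call(rbind, locs), truth = do.call(rbind, rows),
       masks = masks, rule = rule, text = text)
}
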