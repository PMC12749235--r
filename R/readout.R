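#' Raw site occupancy from an accepted alignment
#'
#' A template site reads 1 when it is the assigned nearest site of at least
#' one centroid.
#'
#' @param result an `alignment_result` (see [align_2d()], [align_3d()])
#' @param rule a [pattern_rule()]
#' @return integer vector of 0/1 per template site
#' @export
extract_bits <- function(result, rule) {
  as.integer(seq_len(n_sites(rule)) %in% result$assignment)
}

#' Collapse raw site bits into logical bits
#'
#' Each logical bit is the OR over its redundancy site group: if any of the
#' binding sites corresponding to a bit was read as occupied the bit is 1.
#' With `use_redundancy = FALSE` only the first (main) site of each group
#' is consulted -- the "without redundancy" readout of the same raw bits.
#'
#' @param raw_site_bits 0/1 per template site (see [extract_bits()])
#' @param rule a [pattern_rule()]
#' @param use_redundancy consult the full redundancy group?
#' @return integer vector of logical bits
#' @export
apply_redundancy <- function(raw_site_bits, rule, use_redundancy = TRUE) {
  vapply(rule$redundancy, function(ix) {
    if (!use_redundancy) ix <- ix[1]
    as.integer(any(raw_site_bits[ix] == 1L))
  }, integer(1))
}

#' Decode every particle of a localization table
#'
#' Runs the full readout stack per particle: (3D only) density prefilter,
#' k-means scan with elbow selection of the cluster count, (2D only)
#' cluster size filtering, template alignment, orientation-marker check,
#' bit extraction, redundancy collapse and character/position decoding.
#' Rejected particles keep their per-stage rejection reason; particle
#' conservation (decoded + rejected = selected) always holds.
#'
#' @param locs localization table (see [simulate_dataset()],
#'   [read_localizations()]) with a `particle_id` column
#' @param rule a [pattern_rule()]
#' @param cmap a [character_map()]
#' @param elbow_cfg an [elbow_config()]; default derived from the rule
#' @param filter_cfg a [filter_config()]
#' @param align_cfg an [alignment_config()]
#' @param seed seed for the clustering restarts (and global-mode starts)
#' @param use_redundancy consult redundancy groups at collapse time?
#' @return object of class `origami_readout`: `records` (one row per
#'   particle: decoded character/position, validity, k, cost, D, alpha,
#'   rejection reason), `raw_bits` (particles x sites matrix), `rule`,
#'   `n_rejected`
#' @export
decode_particles <- function(locs, rule, cmap,
                             elbow_cfg = NULL,
                             filter_cfg = filter_config(),
                             align_cfg = alignment_config(),
                             seed = 1L,
                             use_redundancy = TRUE) {
  stopifnot(inherits(rule, "pattern_rule"), inherits(cmap, "character_map"))
  if (is.null(elbow_cfg)) elbow_cfg <- default_elbow_config(rule, seed = seed)
  else elbow_cfg$seed <- as.integer(seed)
  three_d <- is_rule_3d(rule)
  ids <- unique(locs$particle_id)
  n <- length(ids)
  raw_bits <- matrix(NA_integer_, n, n_sites(rule))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pl <- locs[locs$particle_id == ids[i], , drop = FALSE]
    rec <- tryCatch(
      decode_one(pl, rule, cmap, elbow_cfg, filter_cfg, align_cfg,
                 three_d, use_redundancy),
      particle_reject = function(e) {
        list(row = data.frame(particle_id = ids[i], character = NA_character_,
                              position = NA_integer_, valid = FALSE,
                              rejected = TRUE, reason = conditionMessage(e),
                              k = NA_integer_, cost = NA_real_,
                              D = NA_integer_, alpha = NA_real_,
                              z_scale = NA_real_),
             bits = NULL)
      })
    rec$row$particle_id <- ids[i]
    rows[[i]] <- rec$row
    if (!is.null(rec$bits)) raw_bits[i, ] <- rec$bits
  }
  records <- do.call(rbind, rows)
  structure(list(records = records, raw_bits = raw_bits, rule = rule,
                 n_rejected = sum(records$rejected)),
            class = "origami_readout")
}

decode_one <- function(pl, rule, cmap, elbow_cfg, filter_cfg, align_cfg,
                       three_d, use_redundancy) {
  if (three_d) pl <- density_prefilter_3d(pl, filter_cfg)
  scan <- kmeans_scan(pl, elbow_cfg)
  clusters <- select_clusters(scan, elbow_cfg)
  if (!three_d) clusters <- size_filter(clusters, filter_cfg)
  res <- if (three_d) {
    align_3d(clusters$centroids, rule, align_cfg)
  } else {
    align_2d(clusters$centroids, clusters$sizes, rule, align_cfg)
  }
  if (!res$accepted) reject_particle("orientation marker check failed")
  bits <- extract_bits(res, rule)
  logical_bits <- apply_redundancy(bits, rule, use_redundancy)
  dec <- decode_bits(logical_bits, rule, cmap)
  list(row = data.frame(particle_id = NA_integer_,
                        character = dec$character, position = dec$position,
                        valid = dec$valid, rejected = FALSE, reason = "",
                        k = clusters$k, cost = res$cost, D = res$D,
                        alpha = res$alpha,
                        z_scale = if (three_d) res$transform$z_scale
                                  else NA_real_),
       bits = bits)
}

#' Re-decode a readout from its raw site bits
#'
#' Re-runs only the redundancy collapse and character decoding on the raw
#' site bits already extracted -- the natural paired comparison of
#' redundancy ON versus OFF on identical clustering and alignment results.
#'
#' @param readout an `origami_readout`
#' @param cmap a [character_map()]
#' @param use_redundancy consult the full redundancy groups?
#' @return a new `origami_readout`
#' @export
recollapse_readout <- function(readout, cmap, use_redundancy = TRUE) {
  stopifnot(inherits(readout, "origami_readout"))
  rec <- readout$records
  rule <- readout$rule
  for (i in seq_len(nrow(rec))) {
    if (rec$rejected[i]) next
    bits <- apply_redundancy(readout$raw_bits[i, ], rule, use_redundancy)
    dec <- decode_bits(bits, rule, cmap)
    rec$character[i] <- dec$character
    rec$position[i] <- dec$position
    rec$valid[i] <- dec$valid
  }
  structure(list(records = rec, raw_bits = readout$raw_bits, rule = rule,
                 n_rejected = readout$n_rejected),
            class = "origami_readout")
}

#' @export
print.origami_readout <- function(x, ...) {
  n <- nrow(x$records)
  cat("<origami_readout> ", x$rule$geometry_id, ": ", n, " particles, ",
      n - x$n_rejected, " decoded, ", x$n_rejected, " rejected\n", sep = "")
  h <- aggregate_readout(x$records)
  if (nrow(h)) {
    top <- utils::head(h[order(-h$count), ], 5)
    cat("top readout cells:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.origami_readout <- function(object, truth = NULL, ...) {
  rec <- object$records
  out <- list(n = nrow(rec), decoded = sum(!rec$rejected),
              rejected = sum(rec$rejected),
              reasons = table(rec$reason[rec$rejected]),
              histogram = aggregate_readout(rec))
  if (!is.null(truth)) {
    out$accuracy <- mean(readout_correct(rec, truth))
  }
  class(out) <- "summary.origami_readout"
  out
}

#' @export
print.summary.origami_readout <- function(x, ...) {
  cat(x$decoded, "/", x$n, " particles decoded (", x$rejected, " rejected)\n",
      sep = "")
  if (length(x$reasons)) print(x$reasons)
  if (!is.null(x$accuracy)) cat(sprintf("accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' @export
plot.origami_readout <- function(x, ...) {
  h <- aggregate_readout(x$records)
  if (!nrow(h)) stop("no decoded particles to plot")
  lab <- paste0(h$character, ",", h$position)
  graphics::barplot(h$count, names.arg = lab, las = 2,
                    xlab = "(character, position)", ylab = "count", ...)
  invisible(h)
}

#' Histogram of decoded (character, position) cells
#'
#' @param records the `records` data.frame of an `origami_readout` (or the
#'   readout object itself)
#' @return data.frame `character`, `position`, `count`; counts sum to the
#'   number of validly decoded particles
#' @export
aggregate_readout <- function(records) {
  if (inherits(records, "origami_readout")) records <- records$records
  ok <- !records$rejected & records$valid
  if (!any(ok)) {
    return(data.frame(character = character(0), position = integer(0),
                      count = integer(0)))
  }
  tab <- table(character = records$character[ok],
               position = records$position[ok])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  data.frame(character = df$character, position = as.integer(df$position),
             count = as.integer(df$Freq))
}

#' Peak ratios between true readout cells and the best false peak
#'
#' @param hist histogram from [aggregate_readout()]
#' @param true_cells data.frame with `character` and `position` of the
#'   encoded message cells
#' @return named numeric: `lowest_main_over_highest_false` and
#'   `highest_main_over_highest_false`; `Inf` when no false peak exists
#' @export
peak_ratio <- function(hist, true_cells) {
  key <- paste(hist$character, hist$position)
  true_key <- paste(true_cells$character, true_cells$position)
  main <- hist$count[key %in% true_key]
  if (length(main) < nrow(true_cells)) {
    main <- c(main, rep(0L, nrow(true_cells) - length(main)))
  }
  false_counts <- hist$count[!(key %in% true_key)]
  highest_false <- if (length(false_counts)) max(false_counts) else 0L
  if (highest_false == 0L) {
    return(c(lowest_main_over_highest_false = Inf,
             highest_main_over_highest_false = Inf))
  }
  c(lowest_main_over_highest_false = min(main) / highest_false,
    highest_main_over_highest_false = max(main) / highest_false)
}

readout_correct <- function(records, truth) {
  m <- match(records$particle_id, truth$particle_id)
  if (anyNA(m)) stop("ground truth missing for some particles")
  !records$rejected & records$valid &
    records$character == truth$character[m] &
    records$position == truth$position[m]
}

#' Readout accuracy over repeated pipeline runs
#'
#' Re-runs the clustering + alignment + extraction stack `n_runs` times
#' with distinct seeds and reports the per-letter and global accuracy as
#' mean +/- SD. A particle is correct only when both its character and its
#' position match the ground truth; rejected and invalid readouts count as
#' wrong. Accuracies over the accepted-only denominator are reported
#' alongside.
#'
#' @inheritParams decode_particles
#' @param truth ground-truth data.frame (`particle_id`, `character`,
#'   `position`), as from [simulate_dataset()]
#' @param n_runs repeat count (`>= 1`)
#' @return list with `global` / `global_accepted` (mean, sd) and
#'   `per_letter` (data.frame of per-character mean/sd), plus `runs`
#' @export
accuracy_report <- function(locs, truth, rule, cmap, n_runs = 3L,
                            elbow_cfg = NULL, filter_cfg = filter_config(),
                            align_cfg = alignment_config(), seed = 1L,
                            use_redundancy = TRUE) {
  stopifnot(n_runs >= 1)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ro <- decode_particles(locs, rule, cmap, elbow_cfg, filter_cfg,
                           align_cfg, seed = seed + r - 1L,
                           use_redundancy = use_redundancy)
    correct <- readout_correct(ro$records, truth)
    m <- match(ro$records$particle_id, truth$particle_id)
    runs[[r]] <- data.frame(run = r, particle_id = ro$records$particle_id,
                            character = truth$character[m],
                            correct = correct,
                            accepted = !ro$records$rejected)
  }
  all_runs <- do.call(rbind, runs)
  global <- vapply(split(all_runs, all_runs$run),
                   function(d) mean(d$correct), numeric(1))
  global_acc <- vapply(split(all_runs, all_runs$run),
                       function(d) mean(d$correct[d$accepted]), numeric(1))
  per_letter <- do.call(rbind, lapply(split(all_runs, all_runs$character),
    function(d) {
      by_run <- vapply(split(d, d$run), function(x) mean(x$correct), numeric(1))
      data.frame(character = d$character[1], mean = mean(by_run),
                 sd = stats::sd(by_run))
    }))
  rownames(per_letter) <- NULL
  list(global = c(mean = mean(global), sd = stats::sd(global)),
       global_accepted = c(mean = mean(global_acc), sd = stats::sd(global_acc)),
       per_letter = per_letter, runs = all_runs)
}

#' Per-site bit frequency split by readout correctness
#'
#' @param readout an `origami_readout`
#' @param truth ground-truth data.frame
#' @return data.frame per site: frequency of 1-bits among correct-readout
#'   and among wrong-readout particles (`NA` for an empty stratum)
#' @export
global_bit_map <- function(readout, truth) {
  stopifnot(inherits(readout, "origami_readout"))
  rec <- readout$records
  correct <- readout_correct(rec, truth)
  have_bits <- !rec$rejected
  freq <- function(stratum) {
    idx <- which(have_bits & stratum)
    if (!length(idx)) return(rep(NA_real_, ncol(readout$raw_bits)))
    colMeans(readout$raw_bits[idx, , drop = FALSE])
  }
  data.frame(site_id = seq_len(ncol(readout$raw_bits)),
             role = readout$rule$sites$role,
             freq_correct = freq(correct),
             freq_wrong = freq(!correct))
}

#' Per-site detection efficiency from aligned full-pattern particles
#'
#' Particles carrying the full pattern (every site occupied) are clustered
#' and aligned; a site counts as detected in a particle when some centroid
#' lies within `match_radius` of the site after alignment. Reports the
#' per-site detection frequency, the detected-count distribution and the
#' mean +/- SD detection efficiency.
#'
#' Efficiency structures carry a docking strand at every site, so there are
#' no orientation markers to register against; alignment therefore runs
#' marker-blind (all roles treated as plain sites). A rotationally
#' symmetric layout then cannot be oriented and sites related by the
#' symmetry report an averaged probability -- with a symmetric detection
#' map (as any radial gradient is) the averaging is exact. Aligning with
#' markers active instead *biases* the estimates: whenever a marker-site
#' docking goes undetected, the fit prefers the orientation that still
#' covers the marker, inflating marker-site frequencies.
#'
#' @inheritParams decode_particles
#' @param match_radius nm; default half the rule's design pitch
#' @return object of class `efficiency_report`: `per_site`, `count_dist`,
#'   `mean_pct`, `sd_pct`, `incorporation_mean_pct`, `n_particles`
#' @export
detection_efficiency <- function(locs, rule, match_radius = rule$pitch / 2,
                                 elbow_cfg = NULL,
                                 filter_cfg = filter_config(),
                                 align_cfg = alignment_config(),
                                 seed = 1L) {
  three_d <- is_rule_3d(rule)
  if (is.null(elbow_cfg)) {
    elbow_cfg <- elbow_config(N = max(2L, floor(n_sites(rule) / 2)),
                              M = n_sites(rule), seed = seed)
  } else elbow_cfg$seed <- as.integer(seed)
  ## full-pattern structures have no markers; align marker-blind
  rule <- local({
    r <- rule
    r$sites$role[r$sites$role == "marker_filled"] <- "marker_empty"
    r
  })
  ids <- unique(locs$particle_id)
  detected <- matrix(NA, length(ids), n_sites(rule))
  for (i in seq_along(ids)) {
    pl <- locs[locs$particle_id == ids[i], , drop = FALSE]
    det <- tryCatch({
      if (three_d) pl <- density_prefilter_3d(pl, filter_cfg)
      scan <- kmeans_scan(pl, elbow_cfg)
      clusters <- select_clusters(scan, elbow_cfg)
      if (!three_d) clusters <- size_filter(clusters, filter_cfg)
      res <- if (three_d) align_3d(clusters$centroids, rule, align_cfg)
             else align_2d(clusters$centroids, clusters$sizes, rule, align_cfg)
      site_detected(clusters$centroids, rule, res, match_radius)
    }, particle_reject = function(e) NULL)
    if (!is.null(det)) detected[i, ] <- det
  }
  ok <- stats::complete.cases(detected)
  if (!any(ok)) stop("no particle could be aligned")
  detected <- detected[ok, , drop = FALSE]
  per_site <- colMeans(detected)
  counts <- rowSums(detected)
  per_particle_pct <- 100 * counts / n_sites(rule)
  structure(list(per_site = per_site,
                 count_dist = table(factor(counts, levels = 0:n_sites(rule))),
                 mean_pct = mean(per_particle_pct),
                 sd_pct = stats::sd(per_particle_pct),
                 incorporation_mean_pct =
                   incorporation_from_detection(mean(per_particle_pct)),
                 n_particles = nrow(detected)),
            class = "efficiency_report")
}

site_detected <- function(centroids, rule, result, match_radius) {
  if (result$dim == 2L) {
    sites <- apply_transform_2d(result$transform, template_xy(rule))
    A <- as_matrix_2d(centroids)
  } else {
    sites <- transformed_template_3d(result$transform, rule)
    A <- unname(as.matrix(centroids))[, 1:3, drop = FALSE]
  }
  vapply(seq_len(nrow(sites)), function(j) {
    d2 <- rowSums(sweep(A, 2, sites[j, ])^2)
    any(d2 <= match_radius^2)
  }, logical(1))
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("<efficiency_report> %d particles: detection %.1f +/- %.1f%%, incorporation %.1f%%\n",
              x$n_particles, x$mean_pct, x$sd_pct, x$incorporation_mean_pct))
  invisible(x)
}

#' Incorporation efficiency from detection efficiency
#'
#' Docking strands can be folded into the origami yet missed by imaging;
#' the fixed 7-percentage-point offset between the two converts a measured
#' detection efficiency into the strand incorporation efficiency, capped
#' at 100.
#'
#' @param detection_pct detection efficiency in percent, `[0, 100]`
#' @return incorporation efficiency in percent
#' @examples
#' incorporation_from_detection(88.8) # 95.8
#' @export
incorporation_from_detection <- function(detection_pct) {
  stopifnot(all(detection_pct >= 0), all(detection_pct <= 100))
  pmin(detection_pct + 7, 100)
}
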