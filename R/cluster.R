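#' Elbow-scan configuration
#'
#' @param N,M minimum / maximum candidate cluster counts (`N <= M`)
#' @param mode `"saturation"` picks the smallest k after which the inertia
#'   curve is flat; `"threshold"` picks the k whose saturation score is
#'   closest to `T_I`
#' @param saturation_level saturation score cutoff in `(0, 1]`
#' @param T_I threshold-mode target score
#' @param restarts k-means restarts per candidate k (best inertia kept)
#' @param seed RNG seed for the k-means initializations
#' @return object of class `elbow_config`
#' @export
elbow_config <- function(N, M, mode = c("saturation", "threshold"),
                         saturation_level = 0.95, T_I = 0.9,
                         restarts = 10L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(N >= 1, N <= M, saturation_level > 0, saturation_level <= 1)
  structure(list(N = as.integer(N), M = as.integer(M), mode = mode,
                 saturation_level = saturation_level, T_I = T_I,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "elbow_config")
}

## default candidate range for a rule: from the filled-marker count (every
## pattern occupies at least one more site, so the scan window always sees
## a real cluster split and the gradient normalization has a genuine
## reference drop) up to the largest number of occupiable sites
default_elbow_config <- function(rule, ...) {
  n_filled <- length(filled_marker_sites(rule))
  max_occ <- n_filled + sum(lengths(rule$redundancy))
  elbow_config(N = max(2L, n_filled), M = max_occ, ...)
}

#' Cluster / localization filter configuration
#'
#' @param T_S size-threshold multiplier: clusters smaller than
#'   `mean(sizes) * T_S` localizations are discarded
#' @param eps neighborhood radius (coordinate units, nm by default) of the
#'   3D density prefilter
#' @param min_neighbors neighbors (excluding the point itself) within `eps`
#'   required for a core point
#' @return object of class `filter_config`
#' @export
filter_config <- function(T_S = 0.5, eps = 7, min_neighbors = 4L) {
  stopifnot(T_S >= 0, eps > 0, min_neighbors >= 1)
  structure(list(T_S = T_S, eps = eps,
                 min_neighbors = as.integer(min_neighbors)),
            class = "filter_config")
}

## classed rejection used throughout the per-particle pipeline
reject_particle <- function(reason) {
  stop(structure(class = c("particle_reject", "error", "condition"),
                 list(message = reason, call = NULL)))
}

#' k-means scan over candidate cluster counts
#'
#' Runs k-means for every k in `[N, M]` (best of `restarts` seeded
#' restarts), recording the inertia (total within-cluster sum of squared
#' distances), centroids and memberships of each candidate clustering.
#' When the data contain fewer distinct points than `M` the scan stops at
#' the largest feasible k.
#'
#' @param locs matrix or data.frame of localization coordinates (`x`, `y`
#'   and optionally `z` columns, or a bare 2-/3-column matrix)
#' @param cfg an [elbow_config()]
#' @return object of class `kmeans_scan`: list with `k_values`,
#'   `inertia` (named by k), `fits` (per-k list of `centroids`, `sizes`,
#'   `membership`)
#' @export
kmeans_scan <- function(locs, cfg) {
  X <- loc_matrix(locs)
  if (nrow(X) < cfg$M) {
    reject_particle(sprintf("only %d localizations for a scan up to M = %d",
                            nrow(X), cfg$M))
  }
  n_distinct <- nrow(unique(X))
  if (n_distinct < cfg$N) {
    reject_particle(sprintf("only %d distinct points for a scan from N = %d",
                            n_distinct, cfg$N))
  }
  ks <- cfg$N:min(cfg$M, n_distinct)
  set.seed(cfg$seed)
  fits <- vector("list", length(ks))
  inertia <- numeric(length(ks))
  for (i in seq_along(ks)) {
    km <- run_kmeans(X, ks[i], cfg$restarts)
    fits[[i]] <- list(centroids = unname(km$centers),
                      sizes = as.integer(km$size),
                      membership = km$cluster)
    inertia[i] <- km$tot.withinss
  }
  names(inertia) <- ks
  structure(list(k_values = ks, inertia = inertia, fits = fits, X = X),
            class = "kmeans_scan")
}

## best of `restarts` runs, each seeded with a kmeans++ (D^2 sampling)
## initialization: uniform random starts essentially never seed all of a
## dozen well-separated clusters at once, which leaves spurious merges in
## the inertia curve exactly where the elbow looks
run_kmeans <- function(X, k, restarts) {
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(X, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100L)),
      error = function(e) NULL)
    if (is.null(km)) {
      km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                           iter.max = 100L,
                                           algorithm = "Lloyd"))
    }
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  nd <- ncol(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  sq_to <- function(i) {
    d2 <- (X[, 1] - X[i, 1])^2 + (X[, 2] - X[i, 2])^2
    if (nd == 3L) d2 <- d2 + (X[, 3] - X[i, 3])^2
    d2
  }
  d2 <- sq_to(idx[1])
  for (j in seq_len(k - 1L)) {
    tot <- sum(d2)
    idx[j + 1L] <- if (tot <= 0) sample.int(n, 1) else
      min(n, findInterval(stats::runif(1) * tot, cumsum(d2)) + 1L)
    d2 <- pmin(d2, sq_to(idx[j + 1L]))
  }
  X[idx, , drop = FALSE]
}

loc_matrix <- function(locs) {
  if (is.matrix(locs)) return(locs)
  cols <- intersect(c("x", "y", "z"), names(locs))
  X <- as.matrix(locs[, cols, drop = FALSE])
  if ("z" %in% cols && all(abs(X[, "z"]) < 1e-12)) {
    X <- X[, c("x", "y"), drop = FALSE]
  }
  unname(X)
}

#' Select the cluster count from an inertia curve (elbow method)
#'
#' The drop in inertia from k to k+1 is the gradient attributed to
#' candidate k; gradients are normalized to a maximum of 1 and the
#' saturation score of k is one minus its normalized gradient, so the score
#' saturates towards 1 once adding clusters stops paying. In
#' `"saturation"` mode the selected k is the smallest candidate whose score
#' reaches `saturation_level` (the first k after which the curve is flat);
#' if the curve never flattens the largest candidate is returned. In
#' `"threshold"` mode the k with score closest to `T_I` is selected. A flat
#' curve (all gradients zero) returns `N` with a warning.
#'
#' @param inertia_curve numeric inertia per candidate k, named by k (as
#'   produced by [kmeans_scan()])
#' @param cfg an [elbow_config()]
#' @return the selected k (integer)
#' @export
elbow_select <- function(inertia_curve, cfg) {
  ks <- as.integer(names(inertia_curve))
  if (is.null(names(inertia_curve))) ks <- seq(cfg$N, length.out = length(inertia_curve))
  if (length(ks) == 1L) return(ks)
  drops <- pmax(0, -diff(inertia_curve)) # non-increasing within solver tolerance
  if (max(drops) == 0) {
    warning("flat inertia curve; returning N = ", ks[1])
    return(ks[1])
  }
  score <- 1 - drops / max(drops)
  cand <- ks[-length(ks)] # gradient at k is the drop from k to k+1
  if (cfg$mode == "saturation") {
    hit <- which(score >= cfg$saturation_level)
    if (!length(hit)) return(ks[length(ks)])
    cand[hit[1]]
  } else {
    cand[which.min(abs(score - cfg$T_I))]
  }
}

#' Extract the selected clustering from a scan
#'
#' @param scan a [kmeans_scan()] result
#' @param k cluster count (defaults to [elbow_select()] under `cfg`)
#' @param cfg an [elbow_config()]
#' @return object of class `cluster_set`: `k`, `centroids`, `sizes`,
#'   `membership`, `inertia_curve`
#' @export
select_clusters <- function(scan, cfg, k = NULL) {
  if (is.null(k)) k <- elbow_select(scan$inertia, cfg)
  i <- match(k, scan$k_values)
  if (is.na(i)) stop("k = ", k, " was not scanned")
  fit <- scan$fits[[i]]
  structure(list(k = k, centroids = fit$centroids, sizes = fit$sizes,
                 membership = fit$membership, inertia_curve = scan$inertia),
            class = "cluster_set")
}

#' Discard undersized clusters
#'
#' The size threshold is `mean(sizes) * T_S`; clusters below it are removed
#' together with their localizations and the remaining clusters re-indexed.
#'
#' @param clusters a `cluster_set` (see [select_clusters()])
#' @param cfg a [filter_config()]
#' @return filtered `cluster_set`
#' @export
size_filter <- function(clusters, cfg) {
  stopifnot(inherits(clusters, "cluster_set"))
  threshold <- mean(clusters$sizes) * cfg$T_S
  keep <- which(clusters$sizes >= threshold)
  if (!length(keep)) reject_particle("all clusters below the size threshold")
  if (length(keep) == length(clusters$sizes)) return(clusters)
  memb <- clusters$membership
  loc_keep <- memb %in% keep
  structure(list(k = length(keep),
                 centroids = clusters$centroids[keep, , drop = FALSE],
                 sizes = clusters$sizes[keep],
                 membership = match(memb[loc_keep], keep),
                 inertia_curve = clusters$inertia_curve),
            class = "cluster_set")
}

#' Density prefilter for 3D localization clouds
#'
#' DBSCAN-style core/border labeling by brute-force neighbor counting: a
#' point is core when at least `min_neighbors` other points lie within
#' `eps`; points that are neither core nor within `eps` of a core point are
#' noise and dropped.
#'
#' @param locs data.frame with `x`, `y`, `z` columns (or 3-column matrix)
#' @param cfg a [filter_config()]
#' @return `locs` with noise rows removed
#' @export
density_prefilter_3d <- function(locs, cfg) {
  X <- if (is.matrix(locs)) locs else as.matrix(locs[, c("x", "y", "z")])
  if (ncol(X) != 3L) stop("3D coordinates required")
  D <- as.matrix(stats::dist(X))
  nb <- rowSums(D <= cfg$eps) - 1L
  core <- nb >= cfg$min_neighbors
  keep <- core
  if (any(core)) {
    near_core <- rowSums(D[, core, drop = FALSE] <= cfg$eps) > 0
    keep <- core | near_core
  }
  if (!any(keep)) reject_particle("all localizations labeled noise")
  if (is.matrix(locs)) locs[keep, , drop = FALSE] else locs[keep, ]
}
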