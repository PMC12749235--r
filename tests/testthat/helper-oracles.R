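# brute-force oracles, independent of the package's compiled kernels

# weighted registration cost by explicit all-pairs nearest neighbor
oracle_cost_2d <- function(A, S, Tt, marker, WO) {
  n <- nrow(A)
  acc <- 0
  hit <- rep(FALSE, nrow(Tt))
  assign <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (A[i, 1] - Tt[, 1])^2 + (A[i, 2] - Tt[, 2])^2
    j <- which.min(d2) # which.min takes the lowest index on ties
    hit[j] <- TRUE
    assign[i] <- j
    P <- if (marker[j]) WO else 1
    acc <- acc + (sqrt(d2[j]) * P * S[i])^2
  }
  D <- sum(marker & !hit)
  list(cost = sqrt(D + 1) / n * acc, assignment = assign, D = D)
}

oracle_cost_3d <- function(A, Tt) {
  acc <- 0
  for (i in seq_len(nrow(A))) {
    d2 <- (A[i, 1] - Tt[, 1])^2 + (A[i, 2] - Tt[, 2])^2 +
      (A[i, 3] - Tt[, 3])^2
    acc <- acc + min(d2)
  }
  acc
}

# DBSCAN-style noise labeling by direct neighbor counting
oracle_dbscan_keep <- function(X, eps, min_neighbors) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) - 1L >= min_neighbors,
                 logical(1))
  vapply(seq_len(n), function(i) core[i] || any(D[i, core] <= eps), logical(1))
}

rot2d <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
}

# smallest absolute angular difference in degrees
ang_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# occupied-site coordinates of a pattern under a planted transform
planted_centroids <- function(rule, occupied, theta, sx = 1, sy = 1,
                              tx = 0, ty = 0) {
  xy <- as.matrix(rule$sites[occupied, c("x", "y")])
  out <- xy %*% t(diag(c(sx, sy)) %*% rot2d(theta))
  out[, 1] <- out[, 1] + tx
  out[, 2] <- out[, 2] + ty
  out
}

# decimal-string doubling, an independent big-integer oracle for capacity()
oracle_pow2_string <- function(bits) {
  digits <- c(1L)
  for (i in seq_len(bits)) {
    digits <- digits * 2L
    carry <- 0L
    for (j in seq_along(digits)) {
      v <- digits[j] + carry
      digits[j] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste(rev(digits), collapse = "")
}

# all-occupied datasets for efficiency analyses
simulate_dataset_full <- function(rule, n, cfg, seed) {
  set.seed(seed)
  seeds <- sample.int(2147483646L, n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_particle(full_pattern(rule), rule, cfg, seeds[i],
                      particle_id = i)$locs
  }))
}
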