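clean_cfg <- function(...) {
  generator_config(detection_map = 1, sigma_xy = 0.8, background_rate = 0,
                   translation_sigma = 2, shear_alpha_sd = 1, ...)
}

test_that("extract_bits marks exactly the assigned sites", {
  rule <- rule_rro12()
  res <- list(assignment = c(1L, 2L, 7L, 7L, 11L), dim = 2L)
  bits <- extract_bits(res, rule)
  expect_equal(which(bits == 1L), c(1L, 2L, 7L, 11L))
  none <- extract_bits(list(assignment = c(1L, 2L)), rule)
  expect_equal(sum(none[-(1:2)]), 0L) # information sites all zero
  spur <- extract_bits(list(assignment = c(1L, 2L, 4L)), rule)
  expect_equal(sum(spur), 3L) # exactly one spurious 1-bit beyond markers
})

test_that("redundancy collapse is an OR over the site group", {
  rule <- rule_rro48()
  raw <- rep(0L, 48)
  grp <- rule$redundancy[[1]]
  raw[grp[2]] <- 1L # main site 0, redundant site 1
  expect_equal(apply_redundancy(raw, rule)[1], 1L)
  expect_equal(apply_redundancy(raw, rule, use_redundancy = FALSE)[1], 0L)
  raw[grp] <- 1L
  expect_equal(apply_redundancy(raw, rule)[1], 1L) # idempotent
  expect_equal(apply_redundancy(rep(0L, 48), rule), rep(0L, 12))
})

test_that("readout histograms conserve particles and rank true cells first", {
  rec <- data.frame(particle_id = 1:10, character = "N", position = 1L,
                    valid = TRUE, rejected = FALSE)
  h <- aggregate_readout(rec)
  expect_equal(nrow(h), 1)
  expect_equal(h$count, 10L)

  rule <- rule_rro12(); cm <- default_map_3bit()
  ds <- simulate_dataset("NSF", rule, cm, 25, clean_cfg(), seed = 61)
  ro <- decode_particles(ds$locs, rule, cm, seed = 3)
  h2 <- aggregate_readout(ro)
  expect_equal(sum(h2$count), sum(!ro$records$rejected & ro$records$valid))
  top3 <- h2[order(-h2$count), ][1:3, ]
  expect_setequal(paste(top3$character, top3$position),
                  c("N 1", "S 2", "F 3"))
})

test_that("peak ratios follow the definition and report an Inf sentinel", {
  hist <- data.frame(character = c("N", "S", "F", "Q"),
                     position = c(1L, 2L, 3L, 1L),
                     count = c(50L, 40L, 30L, 10L))
  truth <- data.frame(character = c("N", "S", "F"), position = 1:3)
  pr <- peak_ratio(hist, truth)
  expect_equal(unname(pr), c(3, 5))
  no_false <- peak_ratio(hist[1:3, ], truth)
  expect_true(all(is.infinite(no_false)))
  # a missing true cell enters the ratio as zero
  pr0 <- peak_ratio(hist[c(1, 2, 4), ], truth)
  expect_equal(unname(pr0[1]), 0)
})

test_that("accuracy_report reaches 1 on clean data and 0 on scrambled truth", {
  rule <- rule_rro12(); cm <- default_map_3bit()
  ds <- simulate_dataset("NS", rule, cm, 8, clean_cfg(), seed = 62)
  rep1 <- accuracy_report(ds$locs, ds$truth, rule, cm, n_runs = 2, seed = 5)
  expect_equal(unname(rep1$global["mean"]), 1)
  expect_equal(unname(rep1$global["sd"]), 0)
  expect_true(all(rep1$per_letter$mean == 1))

  wrong <- ds$truth
  wrong$character <- "E" # a letter never encoded
  rep0 <- accuracy_report(ds$locs, wrong, rule, cm, n_runs = 1, seed = 5)
  expect_equal(unname(rep0$global["mean"]), 0)
})

test_that("particle conservation holds through rejections", {
  rule <- rule_rro12(); cm <- default_map_3bit()
  ds <- simulate_dataset("NSF", rule, cm, 6, generator_config(), seed = 63)
  # force rejections: starve one particle of localizations
  locs <- ds$locs[!(ds$locs$particle_id == 1 &
                      seq_len(nrow(ds$locs)) > 5), ]
  ro <- decode_particles(locs, rule, cm, seed = 4)
  expect_equal(nrow(ro$records), length(unique(locs$particle_id)))
  expect_equal(sum(ro$records$rejected) + sum(!ro$records$rejected),
               nrow(ro$records))
  expect_true(any(ro$records$rejected))
  expect_match(ro$records$reason[ro$records$rejected][1], "localizations")
})

test_that("global bit maps split site frequencies by correctness", {
  rule <- rule_rro12(); cm <- default_map_3bit()
  ds <- simulate_dataset("N", rule, cm, 10, clean_cfg(), seed = 64)
  ro <- decode_particles(ds$locs, rule, cm, seed = 6)
  gbm <- global_bit_map(ro, ds$truth)
  occupied <- encode_message("N", rule, cm)[[1]]$occupied
  expect_equal(gbm$freq_correct, as.numeric(occupied))
  expect_true(all(is.na(gbm$freq_wrong))) # empty stratum reported missing
  expect_true(all(gbm$freq_correct >= 0 & gbm$freq_correct <= 1))
})

test_that("incorporation efficiency is detection plus the 7-point offset", {
  expect_equal(incorporation_from_detection(88.8), 95.8)
  expect_equal(incorporation_from_detection(89.16), 96.16)
  expect_equal(incorporation_from_detection(0), 7)
  expect_equal(incorporation_from_detection(97), 100) # capped
  expect_error(incorporation_from_detection(120))
})

test_that("detection efficiency recovers the generator probabilities", {
  rule <- rule_rro12()
  # perfect detection: every site efficiency is 1
  ds1 <- simulate_dataset_full(rule, 25, clean_cfg(), seed = 65)
  eff1 <- detection_efficiency(ds1, rule, seed = 8)
  expect_equal(unname(eff1$per_site), rep(1, 12))
  expect_equal(eff1$mean_pct, 100)
  expect_equal(eff1$incorporation_mean_pct, 100)

  # a symmetric per-site map is recovered within the binomial 99.9% CI
  pmap <- detection_gradient(rule, center = 0.97, corner = 0.86)
  n <- 400
  ds2 <- simulate_dataset_full(rule, n,
                               generator_config(detection_map = pmap,
                                                background_rate = 0),
                               seed = 66)
  eff2 <- detection_efficiency(ds2, rule, seed = 9)
  used <- eff2$n_particles
  ci <- 3.3 * sqrt(pmap * (1 - pmap) / used)
  expect_true(all(abs(eff2$per_site - pmap) <= ci + 0.02))
  # the layout's 180-degree ambiguity averages symmetric site pairs, and the
  # gradient map is itself symmetric, so corner stays below center
  corner <- which.max(rule$sites$x^2 + rule$sites$y^2)
  center <- which.min(rule$sites$x^2 + rule$sites$y^2)
  expect_lt(eff2$per_site[corner], eff2$per_site[center])
})

test_that("accuracy decreases with the bit load of the character", {
  rule <- rule_rro48(); cm <- default_map_6bit()
  # characters spanning 1 to 6 one-bits in their codes
  chars <- c("A", "C", "G", "O", "_", "~")
  bitload <- vapply(chars, function(ch) {
    sum(paintcrypt:::int_to_bits(char_to_code(cm, ch), 6))
  }, integer(1))
  expect_equal(sort(unique(bitload)), 1:6)
  ds <- simulate_dataset(paste(chars, collapse = ""), rule, cm, 25,
                         generator_config(detection_map = 0.85), seed = 67)
  ro <- decode_particles(ds$locs, rule, cm, seed = 10,
                         use_redundancy = FALSE)
  correct <- paintcrypt:::readout_correct(ro$records, ds$truth)
  acc <- vapply(split(correct, ds$truth$character), mean, numeric(1))[chars]
  expect_lt(cor(bitload, acc, method = "spearman"), 0)
})

test_that("accuracy is non-increasing as detection probability falls", {
  rule <- rule_rro12(); cm <- default_map_3bit()
  probs <- c(1, 0.875, 0.75, 0.625, 0.5)
  acc <- vapply(probs, function(p) {
    ds <- simulate_dataset("NSF", rule, cm, 40,
                           generator_config(detection_map = p), seed = 68)
    ro <- decode_particles(ds$locs, rule, cm, seed = 11)
    mean(paintcrypt:::readout_correct(ro$records, ds$truth))
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.02)) # sampling slack on a strong trend
  expect_lt(acc[5], acc[1] - 0.3)
})

test_that("recollapse reproduces a full no-redundancy decode", {
  rule <- rule_rro48(); cm <- default_map_6bit()
  ds <- simulate_dataset("AS", rule, cm, 10, generator_config(), seed = 69)
  ro <- decode_particles(ds$locs, rule, cm, seed = 12)
  off <- recollapse_readout(ro, cm, use_redundancy = FALSE)
  full <- decode_particles(ds$locs, rule, cm, seed = 12,
                           use_redundancy = FALSE)
  expect_equal(off$records$character, full$records$character)
  expect_equal(off$records$position, full$records$position)
})

test_that("decoding with the wrong pattern rule destroys the message", {
  rule <- rule_rro12(); cm <- default_map_3bit()
  # same geometry, different bit assignment: markers on the other corners,
  # character and position rows swapped -- a wrong "key 1"
  sites <- rule$sites
  sites$role <- "marker_empty"; sites$logical_bit <- NA_integer_
  sites$role[c(paintcrypt:::grid_index(2, 1, 4),
               paintcrypt:::grid_index(3, 4, 4))] <- "marker_filled"
  for (j in 1:3) {
    i <- paintcrypt:::grid_index(1, j, 4)
    sites$role[i] <- "char_bit"; sites$logical_bit[i] <- j
  }
  for (j in 1:3) {
    i <- paintcrypt:::grid_index(3, j, 4)
    sites$role[i] <- "pos_bit"; sites$logical_bit[i] <- 3L + j
  }
  wrong_rule <- pattern_rule("rro12", sites, 3L, 3L, 20)

  ds <- simulate_dataset("NSF", rule, cm, 25, generator_config(), seed = 70)
  good <- decode_particles(ds$locs, rule, cm, seed = 13)
  bad <- decode_particles(ds$locs, wrong_rule, cm, seed = 13)
  acc_good <- mean(paintcrypt:::readout_correct(good$records, ds$truth))
  acc_bad <- mean(paintcrypt:::readout_correct(bad$records, ds$truth))
  expect_gt(acc_good, 0.4)
  expect_lt(acc_bad, 0.15)
})
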