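# Independent brute-force oracle for the periodicity score: enumerate
# every offset and count directly.
oracle_spacing <- function(active, k) {
  best <- 0
  for (r in 0:(k - 1)) {
    frac <- sum(active %% k == r) / length(active)
    best <- max(best, frac)
  }
  best
}

test_that("spacing score matches the brute-force oracle", {
  expect_identical(score_spacing(c(1, 4, 7), 3), 1)
  expect_equal(score_spacing(c(1, 4, 7), 2), 2 / 3)
  set.seed(7)
  for (i in 1:50) {
    active <- sort(sample(1:15, sample(2:8, 1)))
    for (k in 2:5) {
      expect_equal(score_spacing(active, k), oracle_spacing(active, k))
    }
  }
})

test_that("a single residue class scores 1 at its own period", {
  for (k in 2:4) {
    for (r in 1:k) {
      active <- seq(r, r + 4 * k, by = k)
      expect_identical(score_spacing(active, k), 1)
    }
  }
})

test_that("spacing score rejects degenerate input", {
  expect_error(score_spacing(c(1, 4, 7), 1), "at least 2")
  expect_error(score_spacing(4, 3), "active loci")
})

test_that("direction inference follows the developmental gradient", {
  bf <- infer_direction(c(1, 4, 7), c(1, 2, 3))
  expect_identical(bf$direction, "back_to_front")
  expect_gt(bf$statistic, 0)
  fb <- infer_direction(c(1, 4, 7), c(3, 2, 1))
  expect_identical(fb$direction, "front_to_back")
  tie <- infer_direction(c(1, 4, 7), c(2, 2, 2))
  expect_identical(tie$direction, "indeterminate")
  expect_identical(tie$statistic, 0)
  # a confidence floor suppresses weak gradients
  weak <- infer_direction(c(1, 4, 7, 10), c(1, 3, 2, 3), floor = 0.9)
  expect_identical(weak$direction, "indeterminate")
})

test_that("direction inference works straight from observation tables", {
  obs <- galesaurus_observations()
  q <- obs[obs$specimen_id == "SAM-PK-K10468" & obs$jaw == "lower" &
             obs$side == "left" & obs$tooth_class == "postcanine", ]
  expect_no_error(infer_direction(q))
})

test_that("synchrony is symmetric and perfect for identical sides", {
  obs <- data.frame(locus_index = 1:9,
                    flags = c("functional_present", "replacement_present",
                              "functional_present", "replacement_present",
                              "replacement_present", "functional_present",
                              "functional_present", "functional_present",
                              "functional_present"))
  expect_identical(synchrony_score(obs, obs), 1)
  other <- obs
  other$flags[8] <- "replacement_present"
  expect_equal(synchrony_score(obs, other), synchrony_score(other, obs))
  expect_lt(synchrony_score(obs, other), 1)
})

test_that("the asymmetric adult maxillae score below perfect synchrony", {
  obs <- galesaurus_observations()
  sam <- obs[obs$specimen_id == "SAM-PK-K10468" & obs$jaw == "upper" &
               obs$tooth_class == "postcanine", ]
  l <- sam[sam$side == "left", ]
  r <- sam[sam$side == "right", ]
  s <- synchrony_score(l, r)
  expect_lt(s, 1)
  # mismatches only at PC8 (extra right replacement) and the right-only
  # distal crypt at PC10: 8 of 10 loci agree
  expect_equal(s, 0.8)
})

test_that("phase-offset sides are less synchronous than aligned sides", {
  p <- model_params()
  traj <- simulate_ontogeny(p, 24L, keep_states = TRUE)
  states <- attr(traj, "states")
  aligned <- quadrant_observations(states[[17L]], side = "left")
  offset <- quadrant_observations(states[[18L]], side = "right")
  aligned_r <- aligned
  aligned_r$side <- "right"
  expect_gte(synchrony_score(aligned, aligned_r),
             synchrony_score(aligned, offset))
})

test_that("the pooled fixture report favours the every-third-locus model", {
  obs <- galesaurus_observations()
  rep <- pattern_report(obs, candidate_k = 2:4)
  expect_identical(rep$best_spacing_k, 3L)
  expect_true(rep$spacing_scores[["3"]] >= rep$spacing_scores[["2"]])
  expect_true(rep$synchrony >= 0 && rep$synchrony <= 1)
  expect_true(all(rep$spacing_scores >= 0 & rep$spacing_scores <= 1))
})

test_that("simulator output is recovered noise-free at its true spacing", {
  p <- model_params()
  traj <- simulate_ontogeny(p, 28L, keep_states = TRUE)
  states <- attr(traj, "states")
  snap_stages <- traj$stage[!is.na(traj$wave_initiated)] + 2L
  snap_stages <- snap_stages[snap_stages >= 15L & snap_stages <= 28L]
  for (t in snap_stages) {
    q <- quadrant_observations(states[[t]])
    active <- q$locus_index[flags_active <- grepl("present", q$flags)]
    expect_identical(score_spacing(active, 3), 1)
    expect_gt(score_spacing(active, 3), score_spacing(active, 2))
    expect_identical(infer_direction(q)$direction, "back_to_front")
  }
})
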