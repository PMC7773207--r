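test_that("initialization honours the lattice contract", {
  p <- model_params()
  st <- initialize_quadrant(p)
  expect_identical(st$stage, 1L)
  expect_identical(sum(!st$retired), p$initial_locus_count)
  view <- quadrant_loci(st)
  # mesial-most loci functional at generation 1, distal ones still maturing
  expect_true(all(view$lifecycle[1:4] == "functional"))
  expect_true(all(view$lifecycle[5:6] %in% c("erupting", "germ", "crypt")))
  expect_identical(st$canine$root, "closed")
  expect_true(st$canine$replacement_active)
  expect_error(model_params(initial_locus_count = 0), "at least 1")
})

test_that("default schedule reaches 7 functional postcanines at stage 8", {
  traj <- simulate_ontogeny(model_params(), 28L)
  expect_identical(traj$functional_pc[traj$stage == 8L], 7L)
  # and ends within the observed sample range at the largest skull
  expect_gte(traj$functional_pc[28L], 7L)
  expect_lte(traj$functional_pc[28L], 12L)
})

test_that("wave residue classes match the every-third-locus pattern", {
  expect_identical(wave_affected_loci(8, 3, 1), c(1L, 4L, 7L))
  expect_identical(wave_affected_loci(6, 2, 0), c(2L, 4L, 6L))
  expect_identical(wave_affected_loci(9, 3, 3), c(3L, 6L, 9L))
  # brute-force residue coverage: k consecutive offsets tile the lattice
  for (k in 2:4) {
    for (n in 7:12) {
      hits <- integer(n)
      for (r in seq_len(k)) {
        hits[wave_affected_loci(n, k, r)] <- hits[wave_affected_loci(n, k, r)] + 1L
      }
      expect_identical(hits, rep(1L, n))
    }
  }
})

test_that("initiate_wave schedules one residue class and one distal crypt", {
  p <- model_params(initial_locus_count = 8L)
  st <- initialize_quadrant(p)
  st$stage <- 3L
  st2 <- initiate_wave(st, p)   # wave I, offset 1
  expect_identical(attr(st2, "affected"),
                   intersect(c(1L, 4L, 7L), st$locus[st$incumbent == "functional"]))
  expect_identical(attr(st2, "added"), 1L)
  expect_identical(max(st2$locus), 9L)
  expect_identical(quadrant_loci(st2)$successor[9L], "crypt")
})

test_that("three consecutive waves visit each functional locus exactly once", {
  p <- model_params(wave_interval_stages = 4L)
  traj <- simulate_ontogeny(p, 16L, keep_states = TRUE,
                            stage_to_bsl = rep(80, 16L))
  states <- attr(traj, "states")
  final <- states[[16L]]
  offsets <- final$waves$residue[1:3]
  expect_identical(sort(unique(offsets %% 3)), c(0, 1, 2))
})

test_that("the subadult +3:-1 triplet nets exactly two loci per cycle", {
  gains <- net_gain_per_cycle(model_params(), n_cycles = 5L, "subadult")
  expect_identical(as.integer(gains), rep(2L, 5L))
})

test_that("the adult +2:-1 regime nets exactly one locus per cycle", {
  gains <- net_gain_per_cycle(model_params(), n_cycles = 5L, "adult")
  expect_identical(as.integer(gains), rep(1L, 5L))
})

test_that("a single wave with no cycle boundary adds one active locus", {
  p <- model_params(waves_per_cycle = 3L, wave_interval_stages = 10L,
                    first_wave_stage = 3L)
  traj <- simulate_ontogeny(p, 8L, stage_to_bsl = rep(80, 8L))
  # exactly one wave initiated, no retirement
  expect_identical(sum(!is.na(traj$wave_initiated)), 1L)
  expect_identical(sum(traj$retired), 0L)
  expect_identical(traj$active_loci[8L] - traj$active_loci[1L], 1L)
})

test_that("canine threshold semantics form a single step", {
  p <- model_params()
  st <- initialize_quadrant(p)
  st88 <- canine_update(st, p, 88)
  expect_true(st88$canine$replacement_active)
  expect_identical(st88$canine$root, "closed")
  st94 <- canine_update(st, p, 94)
  expect_false(st94$canine$replacement_active)
  expect_identical(st94$canine$root, "open")
  # monotone BSL sweep: one true -> false transition, then absorbing
  bsl_seq <- seq(60, 114, by = 2)
  s <- st
  active <- logical(length(bsl_seq))
  for (i in seq_along(bsl_seq)) {
    s <- canine_update(s, p, bsl_seq[i])
    active[i] <- s$canine$replacement_active
  }
  expect_identical(sum(diff(active) != 0), 1L)
  expect_true(all(active[bsl_seq < 90]))
  expect_false(any(active[bsl_seq >= 90]))
})

test_that("canine generations are finite and stage-map invariant", {
  p <- model_params()
  runs <- lapply(list(
    vapply(1:28, linear_stage_to_bsl(28), numeric(1)),
    vapply(1:28, linear_stage_to_bsl(28), numeric(1))
  ), function(bsl) simulate_ontogeny(p, 28L, stage_to_bsl = bsl))
  gens <- vapply(runs, function(tr) max(tr$canine_generation), numeric(1))
  expect_identical(gens[1], gens[2])
  # generation count frozen after the threshold stage
  tr <- runs[[1]]
  after <- tr$canine_generation[tr$bsl_mm >= 90]
  expect_identical(length(unique(after)), 1L)
})

test_that("incisor wave groups alternate in antiphase", {
  even_up <- incisor_state("upper", "even")
  expect_identical(even_up$locus[even_up$active], c(2L, 4L))
  expect_identical(even_up$locus[!even_up$active], c(1L, 3L))
  even_lo <- incisor_state("lower", "even")
  expect_identical(even_lo$locus[even_lo$active], 2L)
  odd_lo <- incisor_state("lower", "odd")
  expect_identical(odd_lo$locus[odd_lo$active], c(1L, 3L))
  # back-to-front: distal member more advanced; front-to-back mirrors it
  btf <- incisor_state("upper", "even", "back_to_front")
  ftb <- incisor_state("upper", "even", "front_to_back")
  expect_gt(btf$dev[4], btf$dev[2])
  expect_gt(ftb$dev[2], ftb$dev[4])
  expect_identical(sort(btf$dev[btf$active]), sort(ftb$dev[ftb$active]))
})

test_that("identical parameters give identical trajectories", {
  p <- model_params()
  t1 <- simulate_ontogeny(p, 24L)
  t2 <- simulate_ontogeny(p, 24L)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("a one-stage run reports the initial state", {
  p <- model_params()
  traj <- simulate_ontogeny(p, 1L, stage_to_bsl = 70)
  expect_identical(nrow(traj), 1L)
  expect_identical(traj$functional_pc, functional_count(initialize_quadrant(p)))
})

test_that("non-monotone stage-to-BSL maps are rejected", {
  expect_error(simulate_ontogeny(model_params(), 5L,
                                 stage_to_bsl = c(70, 72, 71, 73, 74)),
               "monotone")
})

test_that("direction flag reverses within-wave ordering, not counts", {
  p_btf <- model_params(wave_direction = "back_to_front")
  p_ftb <- model_params(wave_direction = "front_to_back")
  t_btf <- simulate_ontogeny(p_btf, 24L)
  t_ftb <- simulate_ontogeny(p_ftb, 24L)
  expect_identical(t_btf$functional_pc, t_ftb$functional_pc)
  expect_identical(t_btf$active_loci, t_ftb$active_loci)
})

test_that("lifecycle legality and conservation hold on randomized runs", {
  set.seed(421)
  for (i in 1:60) {
    expect_no_error(check_simulation_run(random_params(), n_stages = 18L))
  }
})
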