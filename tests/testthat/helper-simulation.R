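# Shared helpers: randomized simulator configurations and an independent
# step-by-step checker of lifecycle legality and locus-count conservation.

random_params <- function() {
  wpc <- sample(1:3, 1)
  model_params(
    wave_spacing_k = sample(2:4, 1),
    waves_per_cycle = wpc,
    wave_interval_stages = sample(1:5, 1),
    within_wave_lag_stages = sample(0:2, 1),
    wave_direction = sample(c("back_to_front", "front_to_back"), 1),
    adult_waves_per_cycle = sample(seq_len(wpc), 1),
    generations_at_mesial_locus = sample(2:3, 1),
    initial_locus_count = sample(3:8, 1),
    first_wave_stage = sample(2:5, 1)
  )
}

# Legal per-track transitions. The replacement track may complete and be
# instantly re-opened by a new visit in the same stage (erupting -> crypt).
legal_successor <- list(
  none = c("none", "crypt"),
  crypt = "germ",
  germ = "erupting",
  erupting = c("none", "crypt")
)
legal_incumbent <- list(
  none = c("none", "functional"),
  functional = c("functional", "resorbing", "none"),
  resorbing = "shed_with_remnant_root",
  shed_with_remnant_root = "functional"
)

# Runs the simulator with per-stage state snapshots and asserts, step by
# step, that every locus follows the legal lifecycle chains, that tooth
# generation increments exactly on re-eruption, and that active-locus
# bookkeeping balances. Returns invisibly; throws on violation.
check_simulation_run <- function(params, n_stages = 20L,
                                 stage_to_bsl = NULL) {
  traj <- simulate_ontogeny(params, n_stages, stage_to_bsl = stage_to_bsl,
                            keep_states = TRUE)
  states <- attr(traj, "states")
  # conservation from the trajectory record
  d_active <- diff(traj$active_loci)
  if (!all(d_active == traj$added[-1] - traj$retired[-1])) {
    stop("active-locus conservation violated")
  }
  for (t in seq_len(n_stages)[-1]) {
    prev <- quadrant_loci(states[[t - 1L]])
    cur <- quadrant_loci(states[[t]])
    common <- intersect(prev$locus, cur$locus)
    p <- prev[match(common, prev$locus), ]
    q <- cur[match(common, cur$locus), ]
    for (i in seq_along(common)) {
      if (p$retired[i] && !q$retired[i]) stop("retirement must be absorbing")
      if (q$retired[i]) next
      if (!q$successor[i] %in% legal_successor[[p$successor[i]]]) {
        stop(sprintf("illegal replacement-track step %s -> %s at locus %d",
                     p$successor[i], q$successor[i], common[i]))
      }
      if (!q$incumbent[i] %in% legal_incumbent[[p$incumbent[i]]]) {
        stop(sprintf("illegal incumbent-track step %s -> %s at locus %d",
                     p$incumbent[i], q$incumbent[i], common[i]))
      }
      dgen <- q$generation[i] - p$generation[i]
      erupted <- p$incumbent[i] %in% c("shed_with_remnant_root", "none") &&
        q$incumbent[i] == "functional"
      if (dgen != as.integer(erupted)) {
        stop("generation must increment exactly on re-eruption")
      }
    }
    # new loci must enter as unerupted crypts
    fresh <- cur[!cur$locus %in% common, ]
    if (nrow(fresh) > 0L &&
        !all(fresh$successor == "crypt" & fresh$generation == 0L)) {
      stop("distal additions must enter the lattice as crypts")
    }
  }
  invisible(traj)
}
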