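#' Parameters of the replacement-wave simulator
#'
#' The simulator advances a jaw quadrant through discrete ontogenetic
#' stages. Replacement waves sweep the ordered postcanine locus lattice,
#' each wave visiting the loci of one residue class modulo
#' \code{wave_spacing_k} (every third locus by default, e.g. pc1, pc4,
#' pc7) and appending \code{distal_add_per_wave} new loci to the distal
#' end of the row. After every \code{waves_per_cycle} completed waves (one
#' replacement cycle) the mesial-most locus is retired, provided it has
#' lived through at least \code{generations_at_mesial_locus} tooth
#' generations; the subadult triplet "+3:-1" therefore nets two loci per
#' cycle. Above \code{adult_onset_bsl_mm} the cycle shortens to
#' \code{adult_waves_per_cycle} waves ("+2:-1", net one locus per cycle).
#' The canine replaces once per cycle until the skull reaches
#' \code{canine_cessation_bsl_mm}, after which replacement stops
#' permanently and the final-generation root remains open.
#'
#' @param wave_spacing_k Loci between successive replacements within one
#'   wave (>= 2). 3 for the Galesaurus pattern; 2 for a
#'   Thrinaxodon-like alternating pattern.
#' @param waves_per_cycle Waves per replacement cycle (default 3).
#' @param distal_add_per_wave New distal loci appended per wave.
#' @param mesial_loss_per_cycle Mesial loci retired per completed cycle.
#' @param wave_interval_stages Stages between successive wave initiations.
#' @param within_wave_lag_stages Stage lag between successive loci visited
#'   by the same wave.
#' @param wave_direction \code{"back_to_front"} (distal loci visited
#'   first) or \code{"front_to_back"}.
#' @param adult_waves_per_cycle Waves per cycle in the adult regime
#'   (must not exceed \code{waves_per_cycle}).
#' @param adult_onset_bsl_mm BSL at which the adult regime activates.
#' @param canine_cessation_bsl_mm BSL at which canine replacement ceases.
#' @param generations_at_mesial_locus Tooth generations a mesial locus
#'   must complete before it may be retired.
#' @param initial_locus_count Loci on the lattice at stage 1.
#' @param first_wave_stage Stage at which wave I initiates.
#' @param seed Integer seed reserved for stochastic options; the reference
#'   model is deterministic and ignores it.
#' @return An object of class \code{model_params}.
#' @export
model_params <- function(wave_spacing_k = 3L,
                         waves_per_cycle = 3L,
                         distal_add_per_wave = 1L,
                         mesial_loss_per_cycle = 1L,
                         wave_interval_stages = 4L,
                         within_wave_lag_stages = 1L,
                         wave_direction = c("back_to_front", "front_to_back"),
                         adult_waves_per_cycle = 2L,
                         adult_onset_bsl_mm = 90,
                         canine_cessation_bsl_mm = 90,
                         generations_at_mesial_locus = 2L,
                         initial_locus_count = 6L,
                         first_wave_stage = 3L,
                         seed = NULL) {
  wave_direction <- match.arg(wave_direction)
  p <- list(wave_spacing_k = as.integer(wave_spacing_k),
            waves_per_cycle = as.integer(waves_per_cycle),
            distal_add_per_wave = as.integer(distal_add_per_wave),
            mesial_loss_per_cycle = as.integer(mesial_loss_per_cycle),
            wave_interval_stages = as.integer(wave_interval_stages),
            within_wave_lag_stages = as.integer(within_wave_lag_stages),
            wave_direction = wave_direction,
            adult_waves_per_cycle = as.integer(adult_waves_per_cycle),
            adult_onset_bsl_mm = adult_onset_bsl_mm,
            canine_cessation_bsl_mm = canine_cessation_bsl_mm,
            generations_at_mesial_locus = as.integer(generations_at_mesial_locus),
            initial_locus_count = as.integer(initial_locus_count),
            first_wave_stage = as.integer(first_wave_stage),
            seed = seed)
  stopifnot(p$wave_spacing_k >= 2L,
            p$waves_per_cycle >= 1L,
            p$distal_add_per_wave >= 1L,
            p$mesial_loss_per_cycle >= 1L,
            p$wave_interval_stages >= 1L,
            p$within_wave_lag_stages >= 0L,
            p$generations_at_mesial_locus >= 1L,
            p$first_wave_stage >= 1L)
  if (p$adult_waves_per_cycle > p$waves_per_cycle) {
    stop("the adult regime cannot gain more per cycle than the subadult regime",
         call. = FALSE)
  }
  if (p$initial_locus_count < 1L) {
    stop("initial_locus_count must be at least 1", call. = FALSE)
  }
  class(p) <- "model_params"
  p
}

# Number of incisor loci per quadrant.
incisor_loci <- function(jaw) if (jaw == "upper") 4L else 3L

#' Initialize a jaw quadrant at model stage 1
#'
#' The stage-1 lattice has \code{initial_locus_count} postcanine loci: the
#' mesial-most are functional first-generation teeth, the distal one or
#' two are still erupting or mineralizing, reflecting a row that is
#' actively elongating. The canine is functional, first generation,
#' closed-rooted.
#'
#' @param params A [model_params()] object.
#' @return An object of class \code{jaw_quadrant}.
#' @export
initialize_quadrant <- function(params) {
  stopifnot(inherits(params, "model_params"))
  n0 <- params$initial_locus_count
  n_functional <- max(n0 - 2L, 1L)
  locus <- seq_len(n0)
  incumbent <- rep("none", n0)
  incumbent[seq_len(n_functional)] <- "functional"
  generation <- ifelse(incumbent == "functional", 1L, 0L)
  # distal loci still maturing: visit_stage encodes how far along they are
  visit_stage <- rep(NA_integer_, n0)
  if (n0 >= n_functional + 1L) visit_stage[n0] <- 0L        # germ at stage 1
  if (n0 >= n_functional + 2L) visit_stage[n0 - 1L] <- -1L  # erupting at stage 1
  state <- list(stage = 1L,
                locus = locus,
                incumbent = incumbent,
                visit_stage = visit_stage,
                generation = as.integer(generation),
                retired = rep(FALSE, n0),
                born_stage = rep(1L, n0),
                waves = data.frame(wave_id = integer(), init_stage = integer(),
                                   residue = integer(),
                                   complete_stage = integer(),
                                   completed = logical()),
                pv_locus = integer(), pv_stage = integer(), pv_wave = integer(),
                inits_since_retire = 0L,
                canine = list(generation = 1L, root = "closed",
                              replacement_active = TRUE),
                incisor_parity = "odd",
                last_wave_initiated = NA_integer_)
  class(state) <- "jaw_quadrant"
  state
}

# successor phase at stage t: 0 crypt, 1 germ, 2 erupting, >= 3 complete
successor_phase <- function(state, t = state$stage) {
  ifelse(is.na(state$visit_stage), NA_integer_, t - state$visit_stage)
}

#' Number of functional postcanine positions in a quadrant
#'
#' A locus counts toward the functional series once its first tooth has
#' erupted and until the locus is retired; a position briefly between
#' crowns mid-replacement (shed incumbent, erupting successor) remains
#' part of the series.
#'
#' @param state A \code{jaw_quadrant}.
#' @return Integer count.
#' @export
functional_count <- function(state) {
  sum(!state$retired & state$generation >= 1L)
}

#' Loci of one residue class on a lattice
#'
#' A replacement wave with spacing \code{k} and offset \code{r} affects
#' the loci \eqn{\{l : l \equiv r (mod k)\}}; offset 1 with spacing 3
#' gives the classic pc1, pc4, pc7 triplet.
#'
#' @param n_loci Lattice size.
#' @param k Wave spacing (>= 2).
#' @param offset Residue offset (0 to k-1; k means residue 0).
#' @return Integer vector of affected loci, mesial to distal.
#' @export
wave_affected_loci <- function(n_loci, k, offset) {
  stopifnot(n_loci >= 1L, k >= 2L)
  loci <- seq_len(n_loci)
  loci[loci %% k == offset %% k]
}

#' Per-locus view of a quadrant state
#'
#' @param state A \code{jaw_quadrant}.
#' @return A data.frame with one row per locus: \code{locus},
#'   \code{lifecycle} (the single most salient lifecycle value:
#'   the replacement track when an episode is under way, the incumbent
#'   track otherwise), \code{incumbent}, \code{successor},
#'   \code{generation}, \code{retired}.
#' @export
quadrant_loci <- function(state) {
  phase <- successor_phase(state)
  successor <- ifelse(is.na(phase), "none",
                      c("crypt", "germ", "erupting")[pmin(phase, 2L) + 1L])
  incumbent_view <- ifelse(state$incumbent == "remnant_root",
                           "shed_with_remnant_root", state$incumbent)
  lifecycle <- ifelse(state$retired, "retired",
                      ifelse(successor != "none", successor,
                             ifelse(incumbent_view == "none", "inactive",
                                    incumbent_view)))
  data.frame(locus = state$locus,
             lifecycle = lifecycle,
             incumbent = incumbent_view,
             successor = successor,
             generation = state$generation,
             retired = state$retired,
             stringsAsFactors = FALSE)
}

#' Register a new replacement wave on a quadrant
#'
#' Computes the wave's residue offset (cycling with the wave ordinal),
#' schedules a visit for every eligible affected locus in wave order
#' (distal first under \code{back_to_front}), and appends the scheduled
#' distal locus (or loci) as unfilled crypts.
#'
#' @param state A \code{jaw_quadrant}.
#' @param params A [model_params()].
#' @param offset Residue offset override; by default the offset cycles
#'   with the wave ordinal so that any \code{wave_spacing_k} consecutive
#'   waves cover each locus exactly once.
#' @return The updated \code{jaw_quadrant}; the number of distal loci
#'   added this call is in \code{attr(, "added")} and the affected locus
#'   set in \code{attr(, "affected")}.
#' @export
initiate_wave <- function(state, params, offset = NULL) {
  t <- state$stage
  k <- params$wave_spacing_k
  w <- nrow(state$waves) + 1L
  if (is.null(offset)) offset <- ((w - 1L) %% k) + 1L
  eligible <- !state$retired &
    state$incumbent == "functional" &
    is.na(state$visit_stage) &
    (state$locus %% k == offset %% k)
  affected <- state$locus[eligible]
  ord <- if (params$wave_direction == "back_to_front") {
    order(affected, decreasing = TRUE)
  } else {
    order(affected)
  }
  affected <- affected[ord]
  visit_at <- t + params$within_wave_lag_stages * (seq_along(affected) - 1L)
  state$pv_locus <- c(state$pv_locus, affected)
  state$pv_stage <- c(state$pv_stage, visit_at)
  state$pv_wave <- c(state$pv_wave, rep(w, length(affected)))
  added <- 0L
  for (d in seq_len(params$distal_add_per_wave)) {
    new_locus <- max(state$locus) + 1L
    state$locus <- c(state$locus, new_locus)
    state$incumbent <- c(state$incumbent, "none")
    state$visit_stage <- c(state$visit_stage, t)
    state$generation <- c(state$generation, 0L)
    state$retired <- c(state$retired, FALSE)
    state$born_stage <- c(state$born_stage, t)
    added <- added + 1L
  }
  complete_stage <- max(c(visit_at, t)) + 3L
  state$waves <- rbind(state$waves,
                       data.frame(wave_id = w, init_stage = t, residue = offset,
                                  complete_stage = complete_stage,
                                  completed = FALSE))
  state$last_wave_initiated <- w
  state$incisor_parity <- if (state$incisor_parity == "odd") "even" else "odd"
  attr(state, "added") <- added
  attr(state, "affected") <- sort(affected)
  state
}

#' Update the canine sub-model for a given skull size
#'
#' While the skull is below the cessation threshold the canine keeps its
#' replacement machinery: closed roots, replacement active. At and above
#' the threshold replacement switches off permanently and the
#' final-generation root transitions to (and stays) open.
#'
#' @param state A \code{jaw_quadrant}.
#' @param params A [model_params()].
#' @param bsl_mm Current basal skull length in mm.
#' @return The updated \code{jaw_quadrant}.
#' @export
canine_update <- function(state, params, bsl_mm) {
  can <- state$canine
  if (bsl_mm >= params$canine_cessation_bsl_mm || !can$replacement_active) {
    can$replacement_active <- FALSE
    can$root <- "open"
  } else {
    can$replacement_active <- TRUE
    can$root <- "closed"
  }
  state$canine <- can
  state
}

#' Alternating incisor wave state for one quadrant
#'
#' Incisor loci are partitioned into odd- and even-numbered groups that
#' replace in antiphase. Within the active group, the distal member is at
#' a more advanced developmental stage under back-to-front waves (and the
#' mesial member under front-to-back).
#'
#' @param jaw \code{"upper"} (4 loci) or \code{"lower"} (3 loci).
#' @param parity Which wave group is active, \code{"odd"} or
#'   \code{"even"}.
#' @param direction Wave direction.
#' @return A data.frame with \code{locus}, \code{active} and \code{dev}
#'   (developmental ordinal among active loci; \code{NA} when inactive).
#' @export
incisor_state <- function(jaw = c("upper", "lower"),
                          parity = c("odd", "even"),
                          direction = c("back_to_front", "front_to_back")) {
  jaw <- match.arg(jaw)
  parity <- match.arg(parity)
  direction <- match.arg(direction)
  n <- incisor_loci(jaw)
  locus <- seq_len(n)
  active <- (locus %% 2L == 1L) == (parity == "odd")
  dev <- rep(NA_integer_, n)
  act <- locus[active]
  ranks <- if (direction == "back_to_front") rank(act) else rank(-act)
  dev[active] <- as.integer(ranks)
  data.frame(locus = locus, active = active, dev = dev)
}

#' Toggle the active incisor wave group of a quadrant
#'
#' @param state A \code{jaw_quadrant}.
#' @param params A [model_params()].
#' @return The updated \code{jaw_quadrant}.
#' @export
incisor_update <- function(state, params) {
  state$incisor_parity <- if (state$incisor_parity == "odd") "even" else "odd"
  state
}

#' Advance a quadrant by one ontogenetic stage
#'
#' Executes one tick of the wave scheduler: replacement episodes progress
#' one lifecycle step (crypt to germ to erupting to functional, while the
#' incumbent passes functional, resorbing, shed-with-remnant-root and is
#' cleared), a new wave initiates if the stage clock is due, scheduled
#' visits open new crypts, completed cycles retire the mesial-most
#' eligible locus, and the canine sub-model is updated against the stage's
#' skull length.
#'
#' @param state A \code{jaw_quadrant}.
#' @param params A [model_params()].
#' @param bsl_mm Basal skull length at the new stage, mm.
#' @return The updated \code{jaw_quadrant}; the trajectory row for the new
#'   stage is in \code{attr(, "row")}.
#' @export
advance_stage <- function(state, params, bsl_mm) {
  t <- state$stage + 1L
  added <- 0L
  retired_n <- 0L
  wave_initiated <- NA_integer_

  ## 1. mature running episodes
  phase <- ifelse(is.na(state$visit_stage), NA_integer_, t - state$visit_stage)
  shed1 <- !is.na(phase) & phase == 1L & state$incumbent == "functional"
  shed2 <- !is.na(phase) & phase == 2L & state$incumbent == "resorbing"
  state$incumbent[shed1] <- "resorbing"
  state$incumbent[shed2] <- "remnant_root"
  done <- !is.na(phase) & phase >= 3L & !state$retired
  if (any(done)) {
    state$incumbent[done] <- "functional"
    state$generation[done] <- state$generation[done] + 1L
    state$visit_stage[done] <- NA_integer_
  }

  ## 2. wave initiation on the stage clock
  state$stage <- t
  if (t >= params$first_wave_stage &&
      (t - params$first_wave_stage) %% params$wave_interval_stages == 0L) {
    state <- initiate_wave(state, params)
    added <- added + attr(state, "added")
    wave_initiated <- state$last_wave_initiated
  }

  ## 3. execute visits due this stage
  due <- state$pv_stage == t
  if (any(due)) {
    for (i in which(due)) {
      l <- state$pv_locus[i]
      j <- match(l, state$locus)
      if (!state$retired[j] && state$incumbent[j] == "functional" &&
          is.na(state$visit_stage[j])) {
        state$visit_stage[j] <- t
      }
    }
    keep <- !due
    state$pv_locus <- state$pv_locus[keep]
    state$pv_stage <- state$pv_stage[keep]
    state$pv_wave <- state$pv_wave[keep]
  }

  ## 4. wave completion bookkeeping (for introspection)
  newly_done <- !state$waves$completed & state$waves$complete_stage <= t
  if (any(newly_done)) state$waves$completed[newly_done] <- TRUE

  ## 5. cycle boundary on the wave-initiation clock: mesial retirement and
  ## canine generation. Counting cycles by initiations keeps the cycle
  ## length exact; a wave's running time grows with the lattice, so
  ## completion-based boundaries would drift.
  cycle_end <- FALSE
  wpc <- if (bsl_mm >= params$adult_onset_bsl_mm) {
    params$adult_waves_per_cycle
  } else {
    params$waves_per_cycle
  }
  if (!is.na(wave_initiated)) {
    state$inits_since_retire <- state$inits_since_retire + 1L
    if (state$inits_since_retire >= wpc) {
      state$inits_since_retire <- 0L
      cycle_end <- TRUE
      for (m in seq_len(params$mesial_loss_per_cycle)) {
        active_idx <- which(!state$retired)
        if (length(active_idx) == 0L) break
        mesial <- active_idx[which.min(state$locus[active_idx])]
        if (state$generation[mesial] >= params$generations_at_mesial_locus) {
          state$retired[mesial] <- TRUE
          state$incumbent[mesial] <- "none"
          state$visit_stage[mesial] <- NA_integer_
          retired_n <- retired_n + 1L
        }
      }
      if (state$canine$replacement_active &&
          bsl_mm < params$canine_cessation_bsl_mm) {
        state$canine$generation <- state$canine$generation + 1L
      }
    }
  }

  ## 6. canine threshold semantics
  state <- canine_update(state, params, bsl_mm)

  attr(state, "row") <- data.frame(stage = t, bsl_mm = bsl_mm,
                                   functional_pc = functional_count(state),
                                   active_loci = sum(!state$retired),
                                   wave_initiated = wave_initiated,
                                   added = added, retired = retired_n,
                                   cycle_end = cycle_end,
                                   canine_generation = state$canine$generation,
                                   canine_root = state$canine$root,
                                   canine_replacing = state$canine$replacement_active)
  state
}

#' Linear stage-to-BSL map anchored at the smallest known specimen
#'
#' Maps the discrete stage clock to basal skull length by linear
#' interpolation through (stage 8, 62 mm) -- the smallest specimen of the
#' growth series approximates developmental stage 8 -- and
#' (\code{n_stages}, \code{final_bsl}).
#'
#' @param n_stages Final stage of the run.
#' @param anchor_stage,anchor_bsl The calibration anchor (8, 62 mm).
#' @param final_bsl BSL at the final stage (114 mm, the largest specimen).
#' @return A function mapping stage to BSL in mm.
#' @export
linear_stage_to_bsl <- function(n_stages, anchor_stage = 8, anchor_bsl = 62,
                                final_bsl = 114) {
  stopifnot(n_stages > anchor_stage, final_bsl > anchor_bsl)
  slope <- (final_bsl - anchor_bsl) / (n_stages - anchor_stage)
  function(stage) anchor_bsl + (stage - anchor_stage) * slope
}

#' Simulate a full ontogeny of one jaw quadrant
#'
#' Runs the replacement-wave state machine from stage 1 to
#' \code{n_stages} against a monotone stage-to-BSL map and records the
#' per-stage trajectory. The reference model is deterministic: identical
#' parameters give identical trajectories.
#'
#' @param params A [model_params()].
#' @param n_stages Number of stages (>= 1); default 28.
#' @param stage_to_bsl A function of stage, or a numeric vector of length
#'   \code{n_stages}; must be monotone non-decreasing. Defaults to
#'   [linear_stage_to_bsl()].
#' @param keep_states Also return the list of per-stage quadrant states
#'   (in \code{attr(, "states")}).
#' @return A data.frame of class \code{trajectory} with columns
#'   \code{stage}, \code{bsl_mm}, \code{functional_pc},
#'   \code{active_loci}, \code{wave_initiated}, \code{added},
#'   \code{retired}, \code{canine_generation}, \code{canine_root},
#'   \code{canine_replacing}.
#' @export
simulate_ontogeny <- function(params = model_params(), n_stages = 28L,
                              stage_to_bsl = NULL, keep_states = FALSE) {
  stopifnot(n_stages >= 1L)
  if (is.null(stage_to_bsl)) {
    stage_to_bsl <- if (n_stages > 8) linear_stage_to_bsl(n_stages) else function(s) 62
  }
  bsl <- if (is.function(stage_to_bsl)) {
    vapply(seq_len(n_stages), stage_to_bsl, numeric(1))
  } else {
    stopifnot(length(stage_to_bsl) == n_stages)
    as.numeric(stage_to_bsl)
  }
  if (is.unsorted(bsl)) stop("stage_to_bsl must be monotone non-decreasing",
                             call. = FALSE)
  state <- initialize_quadrant(params)
  state <- canine_update(state, params, bsl[1L])
  rows <- vector("list", n_stages)
  states <- if (keep_states) vector("list", n_stages) else NULL
  rows[[1L]] <- data.frame(stage = 1L, bsl_mm = bsl[1L],
                           functional_pc = functional_count(state),
                           active_loci = sum(!state$retired),
                           wave_initiated = NA_integer_, added = 0L,
                           retired = 0L, cycle_end = FALSE,
                           canine_generation = state$canine$generation,
                           canine_root = state$canine$root,
                           canine_replacing = state$canine$replacement_active)
  if (keep_states) states[[1L]] <- state
  for (t in seq_len(n_stages)[-1L]) {
    state <- advance_stage(state, params, bsl[t])
    rows[[t]] <- attr(state, "row")
    if (keep_states) states[[t]] <- state
  }
  traj <- do.call(rbind, rows)
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "params") <- params
  if (keep_states) attr(traj, "states") <- states
  traj
}

#' Net change in functional tooth count per replacement cycle
#'
#' Simulates under a constant skull size (so a single regime applies
#' throughout), locates cycle boundaries (stages at which a mesial locus
#' is retired), and returns the change in functional postcanine count
#' between consecutive boundaries after the initial transient. Under the
#' subadult "+3:-1" triplet this is exactly +2; under the adult "+2:-1"
#' regime exactly +1.
#'
#' @param params A [model_params()].
#' @param n_cycles Number of consecutive cycles to measure (>= 1).
#' @param regime \code{"subadult"} or \code{"adult"}.
#' @return Integer vector of per-cycle net gains, length \code{n_cycles}.
#' @export
net_gain_per_cycle <- function(params = model_params(), n_cycles = 5L,
                               regime = c("subadult", "adult")) {
  regime <- match.arg(regime)
  bsl_const <- if (regime == "subadult") {
    min(params$adult_onset_bsl_mm, params$canine_cessation_bsl_mm) - 10
  } else {
    params$adult_onset_bsl_mm + 10
  }
  wpc <- if (regime == "subadult") params$waves_per_cycle else params$adult_waves_per_cycle
  cycle_len <- wpc * params$wave_interval_stages
  # warm-up of two cycles, then n_cycles + 1 boundaries
  n_stages <- params$first_wave_stage + cycle_len * (n_cycles + 4L) + 10L
  traj <- simulate_ontogeny(params, n_stages, stage_to_bsl = rep(bsl_const, n_stages))
  boundaries <- traj$stage[traj$cycle_end]
  if (length(boundaries) < n_cycles + 2L) {
    stop("run too short to observe ", n_cycles, " steady-state cycles",
         call. = FALSE)
  }
  counts <- traj$functional_pc[match(boundaries, traj$stage)]
  gains <- diff(counts)
  utils::tail(gains, n_cycles)
}

#' Observation snapshot of a quadrant's running replacement episodes
#'
#' Emits one observation row per locus with an episode under way, using
#' the packaged flag vocabulary: an unfilled crypt maps to
#' \code{crypt_present}, a mineralized germ to \code{replacement_present},
#' and an erupting replacement (incumbent resorbing or shed) to
#' \code{replacement_present;resorbing}.
#'
#' @param state A \code{jaw_quadrant}.
#' @param specimen_id,jaw,side Identification columns for the rows.
#' @return A data.frame in the locus-observation schema.
#' @export
quadrant_observations <- function(state, specimen_id = "sim", jaw = "upper",
                                  side = "left") {
  phase <- successor_phase(state)
  idx <- which(!state$retired & !is.na(phase) & phase <= 2L)
  if (length(idx) == 0L) {
    return(data.frame(specimen_id = character(), jaw = character(),
                      side = character(), tooth_class = character(),
                      locus_index = integer(), flags = character(),
                      stringsAsFactors = FALSE))
  }
  flags <- c("crypt_present", "replacement_present",
             "replacement_present;resorbing")[phase[idx] + 1L]
  data.frame(specimen_id = specimen_id, jaw = jaw, side = side,
             tooth_class = "postcanine",
             locus_index = state$locus[idx],
             flags = flags, stringsAsFactors = FALSE)
}
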