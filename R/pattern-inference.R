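#' Periodicity score of replacement activity for a candidate wave spacing
#'
#' Active loci generated by a single replacement wave with spacing
#' \code{k} all fall in one residue class modulo \code{k}. The score is
#' the largest fraction of the active loci captured by any single residue
#' class: 1.0 means perfectly periodic with period \code{k}.
#'
#' @param active_loci Integer vector of locus indices with replacement
#'   evidence (replacement tooth or crypt), or a
#'   \code{locus_observations} table for one quadrant.
#' @param k Candidate spacing (>= 2).
#' @return Match fraction in [0, 1].
#' @export
score_spacing <- function(active_loci, k) {
  if (is.data.frame(active_loci)) {
    active_loci <- active_loci$locus_index[flags_active(active_loci$flags)]
  }
  active_loci <- unique(as.integer(active_loci))
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (length(active_loci) < 2L) {
    stop("need at least 2 active loci", call. = FALSE)
  }
  residues <- active_loci %% k
  max(table(residues)) / length(active_loci)
}

#' Spacing scores over a set of candidate wave spacings
#'
#' @inheritParams score_spacing
#' @param candidate_k Integer vector of candidate spacings.
#' @return Named numeric vector of scores; the best (smallest maximising)
#'   spacing is in \code{attr(, "best_k")}.
#' @export
spacing_profile <- function(active_loci, candidate_k = 2:4) {
  scores <- vapply(candidate_k, function(k) score_spacing(active_loci, k),
                   numeric(1))
  names(scores) <- as.character(candidate_k)
  attr(scores, "best_k") <- candidate_k[which.max(scores)]
  scores
}

#' Infer the travel direction of a replacement wave
#'
#' Under back-to-front waves the distal members of a wave are at more
#' advanced developmental stages than the mesial members. The inference is
#' an exact Kendall-style concordant/discordant pair count between locus
#' index and developmental ordinal (crypt = 1, mineralized germ = 2,
#' erupting = 3): a positive statistic means development increases
#' distally (back to front), negative the reverse, zero is reported as
#' indeterminate.
#'
#' @param locus_index Integer vector of active locus indices, or a
#'   \code{locus_observations} table for one quadrant (ordinals are then
#'   derived from the flags via [dev_ordinal()]).
#' @param dev Developmental ordinals aligned with \code{locus_index}
#'   (ignored when a table is given).
#' @param floor Minimum |statistic| below which the call is
#'   \code{"indeterminate"}; the default 0 reports any nonzero gradient
#'   with its sign.
#' @return A list with \code{direction} (\code{"back_to_front"},
#'   \code{"front_to_back"} or \code{"indeterminate"}) and
#'   \code{statistic} (normalized concordance in [-1, 1]).
#' @export
infer_direction <- function(locus_index, dev = NULL, floor = 0) {
  if (is.data.frame(locus_index)) {
    obs <- locus_index
    keep <- flags_active(obs$flags)
    dev <- dev_ordinal(obs$flags)[keep]
    locus_index <- obs$locus_index[keep]
  }
  keep <- !is.na(dev)
  locus_index <- locus_index[keep]
  dev <- dev[keep]
  n <- length(locus_index)
  if (n < 2L) stop("need at least 2 comparable active loci", call. = FALSE)
  pairs <- utils::combn(n, 2L)
  dl <- locus_index[pairs[2L, ]] - locus_index[pairs[1L, ]]
  dd <- dev[pairs[2L, ]] - dev[pairs[1L, ]]
  s <- sign(dl) * sign(dd)
  n_comparable <- sum(s != 0)
  if (n_comparable == 0L) {
    return(list(direction = "indeterminate", statistic = 0))
  }
  stat <- sum(s) / ncol(pairs)
  direction <- if (abs(stat) <= floor) {
    "indeterminate"
  } else if (stat > 0) "back_to_front" else "front_to_back"
  list(direction = direction, statistic = stat)
}

#' Left-right synchrony of replacement activity
#'
#' Fraction of loci whose replacement-activity flag agrees between the
#' left and right quadrant of the same jaw, over the union of loci
#' observed on either side (a locus observed on one side only is treated
#' as inactive on the unobserved side).
#'
#' @param left,right \code{locus_observations} tables (or data.frames
#'   with \code{locus_index} and \code{flags}) for the two sides.
#' @return Fraction in [0, 1]; symmetric in its arguments.
#' @export
synchrony_score <- function(left, right) {
  stopifnot(nrow(left) > 0L, nrow(right) > 0L)
  active_l <- unique(left$locus_index[flags_active(left$flags)])
  active_r <- unique(right$locus_index[flags_active(right$flags)])
  universe <- sort(unique(c(left$locus_index, right$locus_index)))
  match_at <- (universe %in% active_l) == (universe %in% active_r)
  mean(match_at)
}

#' Full replacement-pattern report for a set of observations
#'
#' Scores each quadrant (specimen, jaw, side) with at least two active
#' loci independently and pools quadrants by averaging, then reports the
#' best-supported wave spacing, the direction call, and the mean
#' left-right synchrony over jaws observed on both sides.
#'
#' @param observations A \code{locus_observations} table (postcanine rows
#'   are used).
#' @param candidate_k Candidate wave spacings.
#' @param direction_floor Passed to [infer_direction()].
#' @return A list of class \code{pattern_report}: \code{best_spacing_k},
#'   \code{spacing_scores}, \code{direction}, \code{direction_statistic},
#'   \code{synchrony}, \code{n_quadrants}.
#' @export
pattern_report <- function(observations, candidate_k = 2:4,
                           direction_floor = 0) {
  obs <- observations[observations$tooth_class == "postcanine", ]
  key <- interaction(obs$specimen_id, obs$jaw, obs$side, drop = TRUE)
  quads <- split(obs, key)
  usable <- Filter(function(q) sum(flags_active(q$flags)) >= 2L, quads)
  if (length(usable) == 0L) stop("no quadrant with >= 2 active loci",
                                 call. = FALSE)
  score_mat <- vapply(usable, function(q) {
    vapply(candidate_k, function(k) score_spacing(q, k), numeric(1))
  }, numeric(length(candidate_k)))
  score_mat <- matrix(score_mat, nrow = length(candidate_k))
  spacing_scores <- rowMeans(score_mat)
  names(spacing_scores) <- as.character(candidate_k)
  dir_stats <- vapply(usable, function(q) {
    keep <- flags_active(q$flags) & !is.na(dev_ordinal(q$flags))
    if (sum(keep) < 2L) return(NA_real_)
    infer_direction(q)$statistic
  }, numeric(1))
  mean_stat <- mean(dir_stats, na.rm = TRUE)
  if (is.nan(mean_stat)) mean_stat <- 0
  direction <- if (abs(mean_stat) <= direction_floor || mean_stat == 0) {
    "indeterminate"
  } else if (mean_stat > 0) "back_to_front" else "front_to_back"
  # synchrony over specimen-jaw pairs observed on both sides
  jaw_key <- interaction(obs$specimen_id, obs$jaw, drop = TRUE)
  sync <- vapply(split(obs, jaw_key), function(tbl) {
    l <- tbl[tbl$side == "left", ]
    r <- tbl[tbl$side == "right", ]
    if (nrow(l) == 0L || nrow(r) == 0L) return(NA_real_)
    synchrony_score(l, r)
  }, numeric(1))
  structure(list(best_spacing_k = candidate_k[which.max(spacing_scores)],
                 spacing_scores = spacing_scores,
                 direction = direction,
                 direction_statistic = mean_stat,
                 synchrony = mean(sync, na.rm = TRUE),
                 n_quadrants = length(usable)),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat("Replacement pattern report (", x$n_quadrants, " quadrants)\n", sep = "")
  cat("  spacing scores:",
      paste(sprintf("k=%s: %.3f", names(x$spacing_scores), x$spacing_scores),
            collapse = ", "), "\n")
  cat("  best spacing k:", x$best_spacing_k, "\n")
  cat(sprintf("  direction: %s (statistic %.3f)\n", x$direction,
              x$direction_statistic))
  cat(sprintf("  left-right synchrony: %.3f\n", x$synchrony))
  invisible(x)
}
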