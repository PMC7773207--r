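#' Ordinary least squares trend of tooth count against skull size
#'
#' Fits a straight line through (basal skull length, per-specimen summary
#' postcanine count) by ordinary least squares. With \code{normalize =
#' TRUE} the predictor is first rescaled to [0, 1] with the taxon's own
#' BSL range (see [normalize_bsl()] and [taxon_bsl_range()]), which
#' changes the slope by exactly the factor (max - min) and leaves the
#' residuals unchanged. The sign of the slope is the taxon's direction of
#' ontogenetic change in series length.
#'
#' @param records A \code{specimen_table} for a single taxon.
#' @param jaw \code{"maxilla"} or \code{"mandible"}.
#' @param normalize Normalize BSL to the taxon range before fitting.
#' @param strict Exclude counts flagged uncertain (\code{"?"}); by default
#'   they are included at face value, as plotted in the source series.
#' @param range BSL range used for normalization; defaults to the taxon's
#'   own range.
#' @return An object of class \code{trend_fit}: a list with \code{taxon},
#'   \code{jaw}, \code{slope}, \code{intercept}, \code{n},
#'   \code{residuals} and the underlying \code{lm} fit.
#' @export
fit_count_trend <- function(records, jaw = c("maxilla", "mandible"),
                            normalize = TRUE, strict = FALSE, range = NULL) {
  jaw <- match.arg(jaw)
  pts <- specimen_counts(records, jaw, include_uncertain = !strict)
  pts <- pts[!is.na(pts$count) & !is.na(pts$bsl_mm), ]
  if (nrow(pts) < 2L) stop("fewer than 2 usable points", call. = FALSE)
  taxon <- unique(pts$taxon)
  if (length(taxon) != 1L) {
    stop("fit one taxon at a time (found: ", paste(taxon, collapse = ", "),
         ")", call. = FALSE)
  }
  x <- pts$bsl_mm
  if (normalize) {
    if (is.null(range)) range <- taxon_bsl_range(taxon)
    x <- normalize_bsl(x, range)
  }
  fit <- stats::lm(count ~ x, data = data.frame(count = pts$count, x = x))
  structure(list(taxon = taxon, jaw = jaw,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n = nrow(pts),
                 residuals = unname(stats::residuals(fit)),
                 normalized = normalize,
                 fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Count trend (%s, %s): count = %.3f %+.3f * %s  [n = %d]\n",
              x$taxon, x$jaw, x$intercept, x$slope,
              if (x$normalized) "BSL'" else "BSL(mm)", x$n))
  invisible(x)
}

#' Minimum number of replacement waves implied by a count increase
#'
#' Under a wave model in which each successive replacement wave adds
#' exactly one locus to the distal end of the tooth row, growing a series
#' from \code{count_small} to \code{count_large} elements requires at
#' least \code{count_large - count_small} waves.
#'
#' @param count_small,count_large Non-negative integers with
#'   \code{count_large >= count_small}.
#' @return Integer: the minimum wave count.
#' @export
min_replacement_waves <- function(count_small, count_large) {
  stopifnot(is.numeric(count_small), is.numeric(count_large),
            count_small >= 0)
  if (count_large < count_small) {
    stop("count_large must be >= count_small", call. = FALSE)
  }
  as.integer(count_large - count_small)
}

#' Canine replacement flags per specimen
#'
#' Derives a per-specimen logical from a per-locus observation table:
#' \code{TRUE} if any canine observation of the specimen carries
#' replacement evidence (a replacement tooth or crypt), \code{FALSE} if
#' canine observations exist but none do, \code{NA} if the specimen has no
#' canine observations.
#'
#' @param records A \code{specimen_table}.
#' @param observations A \code{locus_observations} table.
#' @return Named logical vector along \code{records$specimen_id}.
#' @export
canine_replacement_flags <- function(records, observations) {
  can <- observations[observations$tooth_class == "canine", ]
  out <- vapply(records$specimen_id, function(id) {
    rows <- can[can$specimen_id == id, ]
    if (nrow(rows) == 0L) return(NA)
    any(flags_active(rows$flags))
  }, logical(1))
  names(out) <- records$specimen_id
  out
}

#' Skull size at which canine replacement ceases
#'
#' Returns the threshold BSL separating specimens with canine replacement
#' evidence from those without: the smallest BSL with no replacement
#' evidence, together with the largest BSL that still shows replacement.
#' In the packaged growth series these resolve to 90 mm and 88 mm, the
#' subadult-adult transition.
#'
#' @param records A \code{specimen_table}.
#' @param canine_flags Logical vector along \code{records} as from
#'   [canine_replacement_flags()]; \code{NA} entries are dropped.
#' @return A list with \code{threshold_mm} and
#'   \code{max_with_replacement_mm}.
#' @export
canine_cessation_threshold <- function(records, canine_flags) {
  stopifnot(length(canine_flags) == nrow(records))
  keep <- !is.na(canine_flags) & !is.na(records$bsl_mm)
  flags <- canine_flags[keep]
  bsl <- records$bsl_mm[keep]
  if (all(flags)) stop("no specimen without replacement evidence", call. = FALSE)
  if (!any(flags)) stop("no specimen with replacement evidence", call. = FALSE)
  list(threshold_mm = min(bsl[!flags]),
       max_with_replacement_mm = max(bsl[flags]))
}

#' Size ratio between two skulls, as an integer percentage
#'
#' \code{round(100 * bsl_a / bsl_b)} with half-up rounding (so 90.625
#' prints as 91).
#'
#' @param bsl_a,bsl_b Lengths in mm; \code{bsl_b > 0}.
#' @return Integer percent.
#' @export
size_ratio_percent <- function(bsl_a, bsl_b) {
  stopifnot(is.numeric(bsl_a), is.numeric(bsl_b))
  if (any(bsl_b <= 0)) stop("bsl_b must be positive", call. = FALSE)
  as.integer(floor(100 * bsl_a / bsl_b + 0.5))
}
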