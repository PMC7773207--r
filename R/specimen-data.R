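# Tokens accepted in count cells. The en-dash is the convention used in the
# packaged table; a plain ASCII hyphen is accepted as an alias on read.
.missing_tokens <- c("–", "-")
.stage_levels <- c("juvenile", "subadult", "adult")
.flag_tokens <- c("functional_present", "replacement_present", "crypt_present",
                  "root_open", "root_closed", "remnant_root",
                  "empty_alveolus", "resorbing")

#' Parse a tooth-count cell token
#'
#' Count cells in the specimen table use three conventions: a bare integer
#' is a firm count, a trailing question mark (\code{"11?"}) marks a count
#' made uncertain by damage or obstruction, and an en-dash (\code{"–"},
#' ASCII \code{"-"} accepted) marks an element that is not preserved. A
#' bare \code{"?"} records that the element is present but no count could
#' be made.
#'
#' @param token A single cell string, e.g. \code{"10"}, \code{"11?"},
#'   \code{"–"}, \code{"?"}.
#' @return A \code{count_value}: a list with fields \code{value} (integer or
#'   \code{NA}), \code{uncertain} and \code{missing} (logicals).
#' @examples
#' parse_count("15?")
#' parse_count("–")
#' @seealso [format_count()] for the inverse operation.
#' @export
parse_count <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- trimws(token)
  if (tok %in% .missing_tokens) {
    return(structure(list(value = NA_integer_, uncertain = FALSE, missing = TRUE),
                     class = "count_value"))
  }
  if (tok == "?") {
    return(structure(list(value = NA_integer_, uncertain = TRUE, missing = FALSE),
                     class = "count_value"))
  }
  uncertain <- grepl("\\?$", tok)
  num <- sub("\\?$", "", tok)
  if (!grepl("^[0-9]+$", num)) {
    stop("cannot parse count token: '", token, "'", call. = FALSE)
  }
  structure(list(value = as.integer(num), uncertain = uncertain, missing = FALSE),
            class = "count_value")
}

#' Format a count value back to its table token
#'
#' @param x A \code{count_value} as returned by [parse_count()].
#' @return A single string; round-trips exactly with [parse_count()]
#'   (the en-dash spelling is used for missing cells).
#' @export
format_count <- function(x) {
  stopifnot(inherits(x, "count_value"))
  if (x$missing) return("–")
  if (is.na(x$value)) return("?")
  paste0(x$value, if (x$uncertain) "?")
}

#' @export
print.count_value <- function(x, ...) {
  cat("<count>", format_count(x), "\n")
  invisible(x)
}

# Vectorised internal parser: returns a data.frame(value, uncertain, missing).
parse_count_vec <- function(tokens) {
  parsed <- lapply(tokens, parse_count)
  data.frame(value = vapply(parsed, `[[`, integer(1), "value"),
             uncertain = vapply(parsed, `[[`, logical(1), "uncertain"),
             missing = vapply(parsed, `[[`, logical(1), "missing"))
}

#' Load a specimen table
#'
#' Reads a CSV with columns \code{specimen_id, taxon, bsl_mm, stage, max_l,
#' max_r, mand_l, mand_r, source} and returns a validated specimen table.
#' Basal skull lengths printed with a tilde (\code{"~75"}) are stored as
#' their numeric value with \code{bsl_approx = TRUE}. The four count
#' columns keep their raw tokens; use [specimen_counts()] to extract
#' numbers.
#'
#' @param path Path to the CSV file.
#' @return A data.frame of class \code{specimen_table}, one row per
#'   specimen, with parsed \code{bsl_mm} (numeric, may be \code{NA} for
#'   literature records without a measurement) and \code{bsl_approx}.
#' @export
load_specimen_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         encoding = "UTF-8")
  needed <- c("specimen_id", "taxon", "bsl_mm", "stage",
              "max_l", "max_r", "mand_l", "mand_r", "source")
  if (!all(needed %in% names(raw))) {
    stop("specimen table is missing columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$specimen_id)) {
    stop("duplicate specimen_id: ",
         paste(unique(raw$specimen_id[duplicated(raw$specimen_id)]),
               collapse = ", "), call. = FALSE)
  }
  bsl_raw <- trimws(raw$bsl_mm)
  approx <- grepl("^~", bsl_raw)
  bsl_num <- suppressWarnings(as.numeric(sub("^~", "", bsl_raw)))
  bad <- !is.na(bsl_raw) & bsl_raw != "" & is.na(bsl_num)
  if (any(bad)) {
    stop("malformed BSL value(s): ", paste(bsl_raw[bad], collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(bsl_num) & bsl_num <= 0)) {
    stop("BSL must be positive", call. = FALSE)
  }
  stage <- trimws(raw$stage)
  stage[stage == ""] <- NA_character_
  if (any(!is.na(stage) & !stage %in% .stage_levels)) {
    stop("unknown stage token(s): ",
         paste(setdiff(stage, c(.stage_levels, NA)), collapse = ", "),
         call. = FALSE)
  }
  # validate every count token eagerly so malformed cells fail at load time
  for (col in c("max_l", "max_r", "mand_l", "mand_r")) {
    raw[[col]] <- trimws(raw[[col]])
    invisible(lapply(raw[[col]], parse_count))
  }
  out <- data.frame(specimen_id = raw$specimen_id,
                    taxon = raw$taxon,
                    bsl_mm = bsl_num,
                    bsl_approx = approx,
                    stage = stage,
                    max_l = raw$max_l, max_r = raw$max_r,
                    mand_l = raw$mand_l, mand_r = raw$mand_r,
                    source = raw$source,
                    stringsAsFactors = FALSE)
  class(out) <- c("specimen_table", "data.frame")
  out
}

#' Packaged Galesaurus specimen table
#'
#' The seventeen sufficiently prepared *Galesaurus planiceps* specimens
#' with basal skull length (BSL, mm), ontogenetic stage and left/right
#' maxillary and mandibular postcanine counts.
#'
#' @param literature If \code{TRUE}, also append the supplementary
#'   literature record (TM 83, maxillary count 12, no BSL measurement),
#'   which is reported in comparative discussions but absent from the main
#'   table.
#' @return A \code{specimen_table}.
#' @export
galesaurus_specimens <- function(literature = FALSE) {
  main <- load_specimen_table(system.file("extdata", "galesaurus_specimens.csv",
                                          package = "zahnreihe", mustWork = TRUE))
  if (!literature) return(main)
  extra <- load_specimen_table(system.file("extdata", "galesaurus_literature.csv",
                                           package = "zahnreihe", mustWork = TRUE))
  out <- rbind(main, extra)
  class(out) <- c("specimen_table", "data.frame")
  out
}

#' Construct a basal skull length range
#'
#' @param min_mm,max_mm Positive lengths in mm with \code{min_mm < max_mm}.
#' @return An object of class \code{bsl_range}.
#' @export
bsl_range <- function(min_mm, max_mm) {
  stopifnot(is.numeric(min_mm), is.numeric(max_mm),
            min_mm > 0, max_mm > 0)
  if (min_mm >= max_mm) stop("degenerate BSL range: min >= max", call. = FALSE)
  structure(list(min_mm = min_mm, max_mm = max_mm), class = "bsl_range")
}

#' Per-taxon default BSL range
#'
#' Galesaurus specimens span 62--114 mm; the Thrinaxodon comparative series
#' spans approximately 30--96 mm.
#'
#' @param taxon \code{"galesaurus"} or \code{"thrinaxodon"}.
#' @return A [bsl_range()].
#' @export
taxon_bsl_range <- function(taxon = c("galesaurus", "thrinaxodon")) {
  taxon <- match.arg(taxon)
  switch(taxon,
         galesaurus = bsl_range(62, 114),
         thrinaxodon = bsl_range(30, 96))
}

#' Min-max normalization of basal skull length
#'
#' Rescales a BSL measurement to the unit interval with min-max feature
#' scaling, \eqn{x' = (x - x_{min}) / (x_{max} - x_{min})}, so growth
#' series of taxa with different absolute size ranges can be compared on a
#' common axis. Values outside the range are allowed (they map outside
#' [0, 1]) and flagged with a warning.
#'
#' @param bsl_mm Numeric vector of measurements in mm.
#' @param range A [bsl_range()].
#' @return Numeric vector of unitless fractions.
#' @export
normalize_bsl <- function(bsl_mm, range) {
  stopifnot(inherits(range, "bsl_range"), is.numeric(bsl_mm))
  out_of_range <- !is.na(bsl_mm) &
    (bsl_mm < range$min_mm | bsl_mm > range$max_mm)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " BSL value(s) outside the normalization range",
            call. = FALSE)
  }
  (bsl_mm - range$min_mm) / (range$max_mm - range$min_mm)
}

#' Classify ontogenetic stage from basal skull length
#'
#' Stage classes follow the cranial ontogeny of the Galesaurus growth
#' series: juvenile below 69 mm, subadult from 69 mm up to (but not
#' including) 90 mm, adult from 90 mm. The 90 mm adult boundary is
#' inclusive so that the two 90 mm specimens of the packaged table are
#' classified as printed.
#'
#' @param bsl_mm Numeric vector of positive lengths in mm.
#' @return Character vector with values \code{"juvenile"},
#'   \code{"subadult"}, \code{"adult"}.
#' @export
classify_stage <- function(bsl_mm) {
  stopifnot(is.numeric(bsl_mm), all(is.na(bsl_mm) | bsl_mm > 0))
  ifelse(is.na(bsl_mm), NA_character_,
         ifelse(bsl_mm < 69, "juvenile",
                ifelse(bsl_mm < 90, "subadult", "adult")))
}

# Parsed per-side counts for one jaw of a specimen table, in long form.
side_counts <- function(records, jaw = c("maxilla", "mandible"),
                        include_uncertain = TRUE) {
  jaw <- match.arg(jaw)
  cols <- if (jaw == "maxilla") c("max_l", "max_r") else c("mand_l", "mand_r")
  out <- do.call(rbind, lapply(cols, function(col) {
    p <- parse_count_vec(records[[col]])
    data.frame(specimen_id = records$specimen_id,
               side = if (grepl("_l$", col)) "left" else "right",
               value = p$value, uncertain = p$uncertain, missing = p$missing)
  }))
  if (!include_uncertain) out$value[out$uncertain] <- NA_integer_
  out
}

#' Per-specimen summary count for one jaw
#'
#' The per-specimen summary is the maximum of the left and right present
#' counts: damage only ever removes teeth from observation, so the larger
#' side is the better estimate of the true series length.
#'
#' @param records A \code{specimen_table}.
#' @param jaw \code{"maxilla"} or \code{"mandible"}.
#' @param include_uncertain Include counts flagged \code{"?"} at face value
#'   (default) or drop them.
#' @return A data.frame with \code{specimen_id}, \code{bsl_mm},
#'   \code{taxon} and \code{count} (\code{NA} when neither side has a
#'   usable count).
#' @export
specimen_counts <- function(records, jaw = c("maxilla", "mandible"),
                            include_uncertain = TRUE) {
  jaw <- match.arg(jaw)
  sc <- side_counts(records, jaw, include_uncertain)
  agg <- tapply(sc$value, sc$specimen_id, function(v) {
    if (all(is.na(v))) NA_integer_ else max(v, na.rm = TRUE)
  })
  idx <- match(records$specimen_id, names(agg))
  data.frame(specimen_id = records$specimen_id,
             taxon = records$taxon,
             bsl_mm = records$bsl_mm,
             count = as.integer(agg[idx]),
             stringsAsFactors = FALSE)
}

#' Range of observed tooth counts for one jaw
#'
#' @inheritParams specimen_counts
#' @return Integer vector \code{c(min, max)} over all present per-side
#'   counts.
#' @export
count_range <- function(records, jaw = c("maxilla", "mandible"),
                        include_uncertain = TRUE) {
  jaw <- match.arg(jaw)
  sc <- side_counts(records, jaw, include_uncertain)
  v <- sc$value[!is.na(sc$value)]
  if (length(v) == 0L) stop("no usable counts after filtering", call. = FALSE)
  c(min(v), max(v))
}

#' Load a per-locus observation table
#'
#' Reads a CSV with columns \code{specimen_id, jaw, side, tooth_class,
#' locus_index, flags}, where \code{flags} is a semicolon-joined set of
#' lifecycle evidence tokens: \code{functional_present},
#' \code{replacement_present}, \code{crypt_present}, \code{root_open},
#' \code{root_closed}, \code{remnant_root}, \code{empty_alveolus},
#' \code{resorbing}.
#'
#' @param path Path to the CSV file.
#' @return A data.frame of class \code{locus_observations}.
#' @export
load_locus_observations <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  needed <- c("specimen_id", "jaw", "side", "tooth_class", "locus_index", "flags")
  if (!all(needed %in% names(raw))) {
    stop("observation table is missing columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "), call. = FALSE)
  }
  raw$locus_index <- as.integer(raw$locus_index)
  stopifnot(all(raw$jaw %in% c("upper", "lower")),
            all(raw$side %in% c("left", "right")),
            all(raw$tooth_class %in% c("incisor", "canine", "postcanine")),
            all(raw$locus_index >= 1L))
  flag_list <- strsplit(raw$flags, ";", fixed = TRUE)
  bad <- !vapply(flag_list, function(f) all(f %in% .flag_tokens), logical(1))
  if (any(bad)) {
    stop("unknown observation flag(s) in rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  both_roots <- vapply(flag_list, function(f)
    all(c("root_open", "root_closed") %in% f), logical(1))
  if (any(both_roots)) {
    stop("root_open and root_closed are mutually exclusive", call. = FALSE)
  }
  if (any(raw$tooth_class == "canine" & raw$locus_index != 1L)) {
    stop("canine observations must have locus_index 1", call. = FALSE)
  }
  class(raw) <- c("locus_observations", "data.frame")
  raw
}

#' Packaged Galesaurus per-locus observations
#'
#' Per-locus replacement evidence (replacement teeth, crypts, root state,
#' remnant roots) transcribed from the scanned-specimen descriptions of
#' the Galesaurus growth series, plus the canine annotations of the
#' non-scanned specimens where the evidence is recorded.
#'
#' @return A \code{locus_observations} data.frame.
#' @export
galesaurus_observations <- function() {
  load_locus_observations(system.file("extdata",
                                      "galesaurus_locus_observations.csv",
                                      package = "zahnreihe", mustWork = TRUE))
}

# Does a flag string carry replacement evidence (replacement tooth OR crypt)?
flags_active <- function(flags) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) any(c("replacement_present", "crypt_present") %in% f),
         logical(1))
}

#' Developmental ordinal of a replacement observation
#'
#' Maps lifecycle evidence to a comparable developmental score: an unfilled
#' crypt is the youngest state (1), a mineralized replacement germ is
#' intermediate (2), and a replacement whose incumbent is already resorbing
#' is the most advanced (3). Rows without replacement evidence get
#' \code{NA}.
#'
#' @param flags Character vector of semicolon-joined flag strings.
#' @return Integer vector of ordinals in \code{1:3} or \code{NA}.
#' @export
dev_ordinal <- function(flags) {
  fl <- strsplit(flags, ";", fixed = TRUE)
  vapply(fl, function(f) {
    if ("replacement_present" %in% f) {
      if ("resorbing" %in% f) 3L else 2L
    } else if ("crypt_present" %in% f) 1L
    else NA_integer_
  }, integer(1))
}

#' Serialize a specimen table back to CSV
#'
#' Writes the table in the exact fixture schema so that loading and
#' re-serializing a fixture round-trips.
#'
#' @param records A \code{specimen_table}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_specimen_table <- function(records, path) {
  out <- data.frame(specimen_id = records$specimen_id,
                    taxon = records$taxon,
                    bsl_mm = ifelse(is.na(records$bsl_mm), "",
                                    paste0(ifelse(records$bsl_approx, "~", ""),
                                           format(records$bsl_mm, trim = TRUE,
                                                  scientific = FALSE))),
                    stage = ifelse(is.na(records$stage), "", records$stage),
                    max_l = records$max_l, max_r = records$max_r,
                    mand_l = records$mand_l, mand_r = records$mand_r,
                    source = records$source,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
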