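test_that("count tokens parse and round-trip through the formatter", {
  cases <- list(
    list(tok = "7", value = 7L, uncertain = FALSE, missing = FALSE),
    list(tok = "15?", value = 15L, uncertain = TRUE, missing = FALSE),
    list(tok = "–", value = NA_integer_, uncertain = FALSE, missing = TRUE),
    list(tok = "?", value = NA_integer_, uncertain = TRUE, missing = FALSE),
    list(tok = "11?", value = 11L, uncertain = TRUE, missing = FALSE)
  )
  for (cs in cases) {
    cv <- parse_count(cs$tok)
    expect_identical(cv$value, cs$value)
    expect_identical(cv$uncertain, cs$uncertain)
    expect_identical(cv$missing, cs$missing)
    expect_identical(format_count(cv), cs$tok)
  }
  # ASCII hyphen alias normalizes to the en-dash on output
  expect_true(parse_count("-")$missing)
  expect_error(parse_count("abc"), "abc")
  expect_error(parse_count("1.5"), "1\\.5")
})

test_that("every count cell of the packaged table round-trips", {
  recs <- galesaurus_specimens()
  for (col in c("max_l", "max_r", "mand_l", "mand_r")) {
    for (tok in recs[[col]]) {
      expect_identical(format_count(parse_count(tok)), tok)
    }
  }
})

test_that("the packaged specimen table loads with full integrity", {
  recs <- galesaurus_specimens()
  expect_s3_class(recs, "specimen_table")
  expect_identical(nrow(recs), 17L)
  expect_true(all(recs$bsl_mm > 0))
  # approximate-BSL flag is carried for the two tilde records
  expect_identical(recs$specimen_id[recs$bsl_approx],
                   c("NMQR 655", "NMQR 3340"))
  # stage classification from BSL agrees with the printed stage column
  expect_identical(classify_stage(recs$bsl_mm), recs$stage)
  # the literature addendum brings the 12-count record with no BSL
  lit <- galesaurus_specimens(literature = TRUE)
  expect_identical(nrow(lit), 18L)
  expect_true(is.na(lit$bsl_mm[lit$specimen_id == "TM 83"]))
})

test_that("loader rejects malformed tables", {
  recs <- galesaurus_specimens()
  tmp <- withr::local_tempfile(fileext = ".csv")
  dup <- rbind(recs[1, ], recs)
  expect_error(
    {
      write_specimen_table(dup, tmp)
      load_specimen_table(tmp)
    },
    "duplicate"
  )
  bad_stage <- recs
  bad_stage$stage[3] <- "hatchling"
  write_specimen_table(bad_stage, tmp)
  expect_error(load_specimen_table(tmp), "stage")
  writeLines(
    c("specimen_id,taxon,bsl_mm,stage,max_l,max_r,mand_l,mand_r,source",
      "X 1,galesaurus,12a,adult,9,9,9,9,anatomical"), tmp)
  expect_error(load_specimen_table(tmp), "BSL")
  # header-only file gives an empty collection
  writeLines("specimen_id,taxon,bsl_mm,stage,max_l,max_r,mand_l,mand_r,source",
             tmp)
  expect_identical(nrow(load_specimen_table(tmp)), 0L)
})

test_that("loading then re-serializing the fixture preserves content", {
  recs <- galesaurus_specimens()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_specimen_table(recs, tmp)
  again <- load_specimen_table(tmp)
  expect_equal(as.data.frame(again), as.data.frame(recs))
})

test_that("min-max BSL normalization is affine and anchored", {
  r <- bsl_range(62, 114)
  expect_identical(normalize_bsl(62, r), 0)
  expect_identical(normalize_bsl(114, r), 1)
  expect_equal(normalize_bsl(88, r), 26 / 52)
  x <- sort(runif(20, 62, 114))
  expect_true(all(diff(normalize_bsl(x, r)) >= 0))
  # affine: equal spacing is preserved
  expect_equal(diff(normalize_bsl(c(70, 80, 90), r)),
               rep(10 / 52, 2))
  expect_warning(normalize_bsl(120, r), "outside")
  expect_error(bsl_range(90, 90), "degenerate")
})

test_that("stage classification uses the printed boundaries", {
  expect_identical(classify_stage(62), "juvenile")
  expect_identical(classify_stage(68.9), "juvenile")
  expect_identical(classify_stage(69), "subadult")
  expect_identical(classify_stage(88), "subadult")
  expect_identical(classify_stage(90), "adult")
  expect_identical(classify_stage(114), "adult")
})

test_that("count ranges scan all present per-side values", {
  recs <- galesaurus_specimens()
  expect_identical(count_range(recs, "maxilla"), c(7L, 11L))
  expect_identical(count_range(recs, "mandible"), c(9L, 15L))
  one <- recs[recs$specimen_id == "FMNH PR 1774", ]
  expect_identical(count_range(one, "maxilla"), c(7L, 7L))
  # strict mode drops "?" counts: the 15? mandible cell no longer caps it
  expect_identical(count_range(recs, "mandible", include_uncertain = FALSE),
                   c(9L, 14L))
})

test_that("per-specimen summary count is the max of the preserved sides", {
  recs <- galesaurus_specimens()
  sc <- specimen_counts(recs, "maxilla")
  expect_identical(sc$count[sc$specimen_id == "RC 845"], 10L)     # 10/9
  expect_identical(sc$count[sc$specimen_id == "SAM-PK-K9956"], 9L) # –/9
  md <- specimen_counts(recs, "mandible")
  expect_true(is.na(md$count[md$specimen_id == "NMQR 135"]))      # –
})

test_that("observation tables validate their flag vocabulary", {
  obs <- galesaurus_observations()
  expect_s3_class(obs, "locus_observations")
  expect_true(all(obs$locus_index >= 1L))
  expect_true(all(obs$locus_index[obs$tooth_class == "canine"] == 1L))
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,jaw,side,tooth_class,locus_index,flags",
               "X,upper,left,postcanine,3,levitating"), tmp)
  expect_error(load_locus_observations(tmp), "flag")
  writeLines(c("specimen_id,jaw,side,tooth_class,locus_index,flags",
               "X,upper,left,postcanine,3,root_open;root_closed"), tmp)
  expect_error(load_locus_observations(tmp), "mutually exclusive")
})

test_that("developmental ordinals rank crypt < germ < erupting", {
  expect_identical(dev_ordinal(c("crypt_present", "replacement_present",
                                 "replacement_present;resorbing", "root_open")),
                   c(1L, 2L, 3L, NA_integer_))
})
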