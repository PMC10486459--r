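test_that("serial split reproduces the chronological cohort block sizes", {
  recs <- lapply(seq_len(163), function(i)
    quick_record(sprintf("P%03d", i), 30,
                 date = as.Date("2006-01-01") + i * 25))
  sp <- serial_split(recs, c(0.56, 0.04, 0.40))
  expect_equal(as.integer(table(sp$split)), c(92L, 7L, 64L))
  # earliest block is training, latest is test
  dates <- as.Date("2006-01-01") + seq_len(163) * 25
  names(dates) <- sprintf("P%03d", seq_len(163))
  expect_true(max(dates[sp$patient_id[sp$split == "train"]]) <
                min(dates[sp$patient_id[sp$split == "test"]]))
})

test_that("serial split orders by date, is permutation invariant, and breaks ties by id", {
  dates <- as.Date("2000-01-01") + c(5, 3, 9, 1, 7, 2, 8, 4, 6, 0)
  recs <- lapply(seq_len(10), function(i)
    quick_record(paste0("p", i), 30, date = dates[i]))
  sp <- serial_split(recs, c(0.5, 0.2, 0.3))
  expect_equal(as.integer(table(sp$split)), c(5L, 2L, 3L))
  # last 3 by date are the test set
  last3 <- paste0("p", order(dates, decreasing = TRUE)[1:3])
  expect_setequal(sp$patient_id[sp$split == "test"], last3)
  # shuffling the input leaves the assignment unchanged
  set.seed(1)
  sp2 <- serial_split(recs[sample(10)], c(0.5, 0.2, 0.3))
  expect_equal(sp2[order(sp2$patient_id), ], sp[order(sp$patient_id), ],
               ignore_attr = TRUE)
  # date ties broken lexicographically by patient id
  tied <- lapply(c("b", "a", "d", "c"), function(id)
    quick_record(id, 30, date = "2001-01-01"))
  spt <- serial_split(tied, c(0.5, 0.25, 0.25))
  expect_equal(spt$patient_id, c("a", "b", "c", "d"))
  expect_error(serial_split(tied[1:2], c(0.5, 0.25, 0.25)),
               class = "bcsurv_split_error")
})

test_that("a cohort written to disk reloads field by field", {
  cohort <- generate_cohort(tiny_sim(4, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(dir, cohort$pairs, cohort$masks, cohort$records)
  re <- load_cohort(dir, file.path(dir, "clinical.csv"))
  expect_length(re$pairs, 4)
  expect_length(re$masks, 8)
  expect_length(re$records, 4)
  expect_length(re$unmatched, 0)
  for (i in seq_along(cohort$pairs)) {
    a <- cohort$pairs[[i]]
    b <- re$pairs[[which(vapply(re$pairs, `[[`, "", "patient_id") ==
                           a$patient_id)]]
    expect_equal(b$pre_volume, a$pre_volume, tolerance = 1e-6)
    expect_equal(b$post_volume, a$post_volume, tolerance = 1e-6)
    expect_equal(b$voxel_spacing_pre, a$voxel_spacing_pre, tolerance = 1e-6)
    expect_equal(b$exam_date_pre, a$exam_date_pre)
    expect_equal(b$contrast_phase, a$contrast_phase)
  }
  for (i in seq_along(cohort$records)) {
    a <- cohort$records[[i]]; b <- re$records[[i]]
    expect_equal(records_to_df(list(b)), records_to_df(list(a)))
  }
  ra <- cohort$masks[[1]]; rb <- re$masks[[1]]
  expect_equal(rb$mask, ra$mask)
  expect_equal(rb$voi_bbox, ra$voi_bbox)
})

test_that("schema and alignment violations are reported by name", {
  cohort <- generate_cohort(tiny_sim(4, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(dir, cohort$pairs, cohort$masks, cohort$records)
  # missing column
  df <- read.csv(file.path(dir, "clinical.csv"))
  df$lvi <- NULL
  broken <- file.path(dir, "broken.csv")
  write.csv(df, broken, row.names = FALSE)
  err <- expect_error(load_cohort(dir, broken),
                      class = "bcsurv_schema_error")
  expect_match(conditionMessage(err), "lvi")
  # mask/volume shape mismatch
  id <- cohort$pairs[[1]]$patient_id
  small <- cohort$masks[[1]]$mask[, , 1:20]
  bcsurv:::write_volume_nifti(small, c(1, 1, 1),
                              file.path(dir, paste0(id, "_pre_mask.nii.gz")))
  expect_error(load_cohort(dir, file.path(dir, "clinical.csv")),
               class = "bcsurv_alignment_error")
})

test_that("clinical record validates and derives the five-year label", {
  expect_equal(quick_record("a", 72, event = FALSE)$label_5yr, 1L)
  expect_equal(quick_record("b", 30, event = TRUE)$label_5yr, 0L)
  # censored before 60 months defaults to label 0 (documented choice)
  expect_equal(quick_record("c", 40, event = FALSE)$label_5yr, 0L)
  expect_error(quick_record("d", 30, event = TRUE, label = 1),
               class = "bcsurv_type_error")
  expect_error(quick_record("e", 70, event = FALSE, label = 0),
               class = "bcsurv_type_error")
  expect_error(
    clinical_record("f", "pT9", FALSE, "N0", TRUE, FALSE, 10, TRUE,
                    exam_date = "2010-01-01"))
})

test_that("volume pair and lesion mask enforce their invariants", {
  v <- array(0, c(4, 5, 6))
  expect_error(volume_pair("p", v, v, c(1, 1, 1), c(1, 1, 1),
                           "2010-05-01", "2010-01-01"),
               class = "bcsurv_type_error")
  expect_error(volume_pair("p", v[1, , ], v, c(1, 1, 1), c(1, 1, 1),
                           "2010-01-01", "2010-05-01"),
               class = "bcsurv_type_error")
  m <- array(0L, c(4, 5, 6))
  expect_error(lesion_mask("p", "pre", m), class = "bcsurv_type_error")
  m[2, 3, 4] <- 1L
  lm <- lesion_mask("p", "pre", m)
  expect_equal(unname(lm$voi_bbox["lo", ]), c(1L, 2L, 3L))
  expect_equal(unname(lm$voi_bbox["hi", ]), c(2L, 3L, 4L))
})

test_that("annotations enforce diameter ordering", {
  a <- lesion_annotation(30, 20, "bladder")
  expect_s3_class(a, "lesion_annotation")
  expect_error(lesion_annotation(20, 30), class = "bcsurv_type_error")
  expect_error(lesion_annotation(20, -1), class = "bcsurv_type_error")
})
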