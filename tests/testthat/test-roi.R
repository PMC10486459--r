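make_voi_volume <- function(h, w, value = 0, nz = 5) {
  vol <- array(value, c(nz, h + 10, w + 10))
  bbox <- rbind(lo = c(0L, 5L, 5L), hi = c(nz, 5L + h, 5L + w))
  colnames(bbox) <- c("z", "y", "x")
  list(vol = vol, bbox = bbox)
}

test_that("sliding windows enumerate the VOI at the configured stride", {
  v <- make_voi_volume(32, 16)
  expect_length(extract_subrois(v$vol, v$bbox, 3, stride = 7), 1)
  v2 <- make_voi_volume(32, 31)
  w2 <- extract_subrois(v2$vol, v2$bbox, 3, stride = 5)
  expect_length(w2, 4)
  cols <- vapply(w2, function(w) attr(w, "offset")[2], 0) - 5
  expect_equal(cols, c(0, 5, 10, 15))
  v3 <- make_voi_volume(32, 20)
  expect_length(extract_subrois(v3$vol, v3$bbox, 3, stride = 1), 5)
  # row-major order over both axes
  v4 <- make_voi_volume(36, 20)
  w4 <- extract_subrois(v4$vol, v4$bbox, 3, stride = 4)
  offs <- t(vapply(w4, function(w) attr(w, "offset"), c(0, 0)))
  expect_equal(offs[, 1] - 5, c(0, 0, 4, 4))
  expect_equal(offs[, 2] - 5, c(0, 4, 0, 4))
})

test_that("undersized VOIs give one centred zero-padded flagged window", {
  v <- make_voi_volume(10, 8)
  v$vol[] <- 9
  w <- extract_subrois(v$vol, v$bbox, 3, stride = 4)
  expect_length(w, 1)
  expect_true(attr(w[[1]], "padded"))
  expect_equal(dim(w[[1]]), c(32L, 16L))
  expect_equal(sum(w[[1]] == 9), 10 * 8)
  # the content sits centred
  expect_true(all(w[[1]][1:11, ] == 0))
})

test_that("hybrid composition keeps phases in their halves", {
  pre <- matrix(0, 32, 16); post <- matrix(1, 32, 16)
  h <- compose_hybrid(pre, post, intensity_window = c(0, 1))
  expect_equal(dim(h), c(32L, 32L))
  expect_true(all(h[, 1:16] == 0))
  expect_true(all(h[, 17:32] == 1))
  sw <- compose_hybrid(post, pre, intensity_window = c(0, 1))
  expect_true(all(sw[, 1:16] == 1))
  expect_true(all(sw[, 17:32] == 0))
  expect_error(compose_hybrid(matrix(0, 16, 16), post),
               class = "bcsurv_contract_error")
  # normalisation clamps to the window
  hw <- compose_hybrid(matrix(-50, 32, 16), matrix(500, 32, 16),
                       intensity_window = c(0, 100))
  expect_true(all(hw[, 1:16] == 0) && all(hw[, 17:32] == 1))
})

test_that("dataset construction pairs, caps and labels deterministically", {
  co <- generate_cohort(tiny_sim(6, seed = 13))
  cfg <- roi_config(stride = 4L, max_hybrids_per_case = 5L, seed = 2L)
  ds1 <- build_roi_dataset(co$pairs, co$masks, co$records, cfg)
  ds2 <- build_roi_dataset(co$pairs, co$masks, co$records, cfg)
  expect_identical(ds1$patches, ds2$patches)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_true(all(table(ds1$manifest$patient_id) <= 5))
  # labels propagate from the case
  labels <- setNames(vapply(co$records, `[[`, 0L, "label_5yr"),
                     vapply(co$records, `[[`, "", "patient_id"))
  expect_equal(ds1$manifest$label, unname(labels[ds1$manifest$patient_id]))
  # uncapped cross product count for one case
  cfg_big <- roi_config(stride = 4L, max_hybrids_per_case = 10000L)
  one <- build_roi_dataset(co$pairs[1], co$masks, co$records[1], cfg_big)
  m1 <- co$masks[[1]]; m2 <- co$masks[[2]]
  n_pre <- length(extract_subrois(co$pairs[[1]]$pre_volume, m1$voi_bbox,
                                  select_central_slice(m1), 4L))
  n_post <- length(extract_subrois(co$pairs[[1]]$post_volume, m2$voi_bbox,
                                   select_central_slice(m2), 4L))
  expect_equal(nrow(one$manifest), n_pre * n_post)
})

test_that("no patch mixes phases within one half", {
  # constant-0 pre scan and constant-100 post scan expose any leakage;
  # the VOI exceeds the window so no zero padding is involved
  mask <- array(0L, c(3, 50, 40)); mask[2, 5:44, 5:28] <- 1L
  pre_m <- lesion_mask("px", "pre", mask)
  post_m <- lesion_mask("px", "post", mask)
  pair <- volume_pair("px", array(0, c(3, 50, 40)),
                      array(100, c(3, 50, 40)), c(1, 1, 1), c(1, 1, 1),
                      "2010-01-01", "2010-04-01")
  rec <- list(quick_record("px", 70))
  ds <- build_roi_dataset(list(pair), list(pre_m, post_m), rec,
                          roi_config(stride = 6L,
                                     max_hybrids_per_case = 50L,
                                     intensity_window = c(0, 100)))
  expect_gt(nrow(ds$manifest), 1)
  expect_false(any(ds$manifest$padded))
  expect_true(all(ds$patches[, , 1:16] == 0))
  expect_true(all(ds$patches[, , 17:32] == 1))
})

test_that("patches of one patient never span split boundaries", {
  co <- generate_cohort(tiny_sim(10, seed = 15))
  ds <- build_roi_dataset(co$pairs, co$masks, co$records,
                          roi_config(stride = 8L, max_hybrids_per_case = 4L))
  split <- serial_split(co$records, c(0.5, 0.2, 0.3))
  for (s in levels(split$split)) {
    sub <- bcsurv:::subset_roi_dataset(ds, bcsurv:::split_ids(split, s))
    expect_true(all(sub$manifest$patient_id %in%
                      bcsurv:::split_ids(split, s)))
  }
  sets <- lapply(levels(split$split), function(s)
    unique(bcsurv:::subset_roi_dataset(
      ds, bcsurv:::split_ids(split, s))$manifest$patient_id))
  expect_length(Reduce(intersect, sets), 0)
})

test_that("capping preserves the case-level label balance", {
  co <- generate_cohort(tiny_sim(12, seed = 16))
  capped <- build_roi_dataset(co$pairs, co$masks, co$records,
                              roi_config(stride = 4L,
                                         max_hybrids_per_case = 3L))
  full <- build_roi_dataset(co$pairs, co$masks, co$records,
                            roi_config(stride = 4L,
                                       max_hybrids_per_case = 100000L))
  case_labels <- function(ds)
    ds$manifest$label[!duplicated(ds$manifest$patient_id)]
  expect_equal(sort(table(case_labels(capped))),
               sort(table(case_labels(full))))
})
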