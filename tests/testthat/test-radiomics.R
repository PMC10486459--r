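test_that("the feature catalog is frozen at 91 names in three families", {
  cat_df <- feature_catalog()
  expect_equal(nrow(cat_df), 91L)
  expect_false(any(duplicated(cat_df$name)))
  expect_setequal(unique(cat_df$family),
                  c("morphology", "intensity", "texture_glcm",
                    "texture_glrlm", "texture_gradient"))
  img <- textured_slice(disk_mask(8), seed = 2)
  f <- extract_base_features(img, disk_mask(8), c(1, 1))
  expect_equal(names(f), cat_df$name)
  expect_true(all(is.finite(f)))
})

test_that("a case yields 273 namespaced features", {
  cohort <- generate_cohort(tiny_sim(4, seed = 6))
  f <- assemble_case_features(cohort$pairs[[1]], cohort$masks)
  expect_length(f, 273L)
  expect_equal(sum(startsWith(names(f), "pre.")), 91L)
  expect_equal(sum(startsWith(names(f), "post.")), 91L)
  expect_equal(sum(startsWith(names(f), "diff.")), 91L)
  # missing phase is reported by name
  pre_only <- Filter(function(m) m$phase == "pre", cohort$masks)
  err <- expect_error(assemble_case_features(cohort$pairs[[1]], pre_only),
                      class = "bcsurv_extraction_error")
  expect_match(conditionMessage(err), "post")
})

test_that("degenerate texture collapses on a constant-intensity disk", {
  m <- disk_mask(10)
  img <- matrix(55, nrow(m), ncol(m))
  f <- extract_base_features(img, m, c(1, 1))
  expect_equal(f[["int_sd"]], 0)
  expect_equal(f[["int_entropy"]], 0)
  expect_equal(f[["glcm_d1_contrast"]], 0)
  expect_equal(f[["glcm_d2_contrast"]], 0)
  expect_error(extract_base_features(img, m * 0 + diag(c(1, rep(0, nrow(m) - 1))),
                                     c(1, 1)),
               class = "bcsurv_extraction_error")
})

test_that("circularity of rasterised circles is within 2% of 1", {
  for (r in c(20, 30, 40)) {
    f <- extract_base_features(
      textured_slice(disk_mask(r), seed = r), disk_mask(r), c(1, 1))
    expect_lt(abs(f[["morph_circularity"]] - 1), 0.02)
    expect_lt(f[["morph_eccentricity"]], 0.2)
  }
  # an elongated ellipse is clearly less circular
  e <- ellipse_mask(8, 24)
  fe <- extract_base_features(textured_slice(e, seed = 1), e, c(1, 1))
  expect_lt(fe[["morph_circularity"]], 0.9)
  expect_gt(fe[["morph_eccentricity"]], 0.8)
  expect_gt(fe[["morph_aspect_ratio"]], 2)
})

test_that("difference features follow the relative-change definition", {
  nm <- feature_catalog()$name
  f_pre <- setNames(rep(2, 91), nm)
  f_post <- setNames(rep(1, 91), nm)
  d <- compute_difference_features(f_pre, f_post)
  expect_true(all(d == 0.5))
  expect_true(all(compute_difference_features(f_pre, f_pre) == 0))
  f0 <- f_pre; f0[1] <- 0
  d0 <- compute_difference_features(f0, f_post)
  expect_true(is.na(d0[1]))
  expect_false(any(is.infinite(d0)))
  expect_error(compute_difference_features(f_pre[-1], f_post),
               class = "bcsurv_contract_error")
})

test_that("identical pre and post scans zero out the difference namespace", {
  co <- generate_cohort(tiny_sim(4, seed = 8))
  p <- co$pairs[[1]]
  p$post_volume <- p$pre_volume
  masks <- co$masks
  masks[[2]] <- lesion_mask(p$patient_id, "post", masks[[1]]$mask)
  f <- assemble_case_features(p, masks)
  d <- f[startsWith(names(f), "diff.")]
  expect_true(all(d[!is.na(d)] == 0))
})

test_that("features are translation invariant and shift-covariant only in location", {
  m <- ellipse_mask(7, 10)
  img <- textured_slice(m, seed = 3)
  f0 <- extract_base_features(img, m, c(1, 1))
  # whole-pixel translation
  pad <- matrix(0, nrow(m) + 6, ncol(m) + 6)
  m2 <- pad; m2[4 + seq_len(nrow(m)) - 1, 5 + seq_len(ncol(m)) - 1] <- m
  i2 <- pad + min(img)
  i2[4 + seq_len(nrow(m)) - 1, 5 + seq_len(ncol(m)) - 1] <- img
  f1 <- extract_base_features(i2, m2, c(1, 1))
  expect_equal(f1, f0, tolerance = 1e-9)
  # adding a constant moves only the documented location features
  f2 <- extract_base_features(img + 100, m, c(1, 1))
  location <- c("int_mean", "int_median", "int_min", "int_max", "int_p5",
                "int_p10", "int_p25", "int_p75", "int_p90", "int_p95",
                "int_energy", "int_rms", "int_cv")
  moved <- names(f0)[abs(f2 - f0) > 1e-9]
  expect_true(all(moved %in% location))
  expect_equal(f2[["int_mean"]], f0[["int_mean"]] + 100)
  expect_equal(f2[["int_sd"]], f0[["int_sd"]])
  expect_equal(f2[["glcm_d1_entropy"]], f0[["glcm_d1_entropy"]])
  expect_equal(f2[["morph_area"]], f0[["morph_area"]])
})

test_that("extraction is repeatable to full precision", {
  m <- disk_mask(9)
  img <- textured_slice(m, seed = 7)
  f1 <- extract_base_features(img, m, c(0.9, 0.9))
  f2 <- extract_base_features(img, m, c(0.9, 0.9))
  expect_identical(f1, f2)
})

test_that("the central slice maximises in-mask area with lower-index ties", {
  m <- array(0L, c(9, 12, 12))
  m[3, 5:6, 5:6] <- 1L   # area 4
  m[5, 4:8, 4:8] <- 1L   # area 25 (max)
  m[7, 5:7, 5:7] <- 1L   # area 9
  expect_equal(select_central_slice(lesion_mask("p", "pre", m)), 5L)
  single <- array(0L, c(9, 12, 12)); single[4, 5:7, 5:7] <- 1L
  expect_equal(select_central_slice(lesion_mask("p", "pre", single)), 4L)
  tied <- array(0L, c(9, 12, 12))
  tied[4, 5:7, 5:7] <- 1L; tied[6, 5:7, 5:7] <- 1L
  expect_equal(select_central_slice(lesion_mask("p", "pre", tied)), 4L)
  expect_error(select_central_slice(array(0L, c(3, 3, 3))),
               class = "bcsurv_extraction_error")
})

test_that("GLCM contrast matches a brute-force pair scan", {
  m <- disk_mask(6)
  img <- textured_slice(m, seed = 10)
  q <- bcsurv:::quantize_slice(img, m)
  # brute force over all horizontal/vertical/diagonal distance-1 pairs
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  num <- 0; den <- 0
  for (o in offs) for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q) &&
        q[r, cc] > 0 && q[r2, c2] > 0) {
      num <- num + 2 * (q[r, cc] - q[r2, c2])^2
      den <- den + 2
    }
  }
  st <- bcsurv:::glcm_stats(q, 1L)
  expect_equal(st[["contrast"]], num / den, tolerance = 1e-12)
})
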