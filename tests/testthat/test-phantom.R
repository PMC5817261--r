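test_that("voxel grids validate their invariants", {
  g <- voxel_grid(c(16, 16, 32), spacing = 4)
  expect_s3_class(g, "voxel_grid")
  expect_error(voxel_grid(c(4, 16, 16)), "8")
  expect_error(voxel_grid(c(16, 16, 16), spacing = c(4, -1, 4)), "positive")
})

test_that("anatomy contains the expected organs and is deterministic", {
  g <- voxel_grid(c(24, 24, 48), spacing = 8)
  ph <- build_anatomy(g, seed = 3)
  codes <- tissue_codes()
  present <- unique(as.integer(ph$labels))
  for (organ in c("liver", "spleen", "kidney", "bone"))
    expect_true(codes[[organ]] %in% present, label = organ)
  ph2 <- build_anatomy(g, seed = 3)
  expect_identical(ph$ct, ph2$ct)
  expect_identical(ph$labels, ph2$labels)
  expect_identical(ph$activity, ph2$activity)
  ph3 <- build_anatomy(g, seed = 4)
  expect_false(identical(ph$ct, ph3$ct))
  expect_true(all(ph$activity >= 0))
  expect_error(build_anatomy(voxel_grid(c(8, 8, 8), 4), seed = 1),
               "skeleton")
})

test_that("the skeleton is one 26-connected component at study scale", {
  ph <- build_anatomy(voxel_grid(c(64, 64, 96), spacing = 4), seed = 0)
  skel <- skeleton_mask(ph)
  expect_gt(sum(skel), 1000)
  expect_identical(oracle_n_components26(skel), 1L)
})

test_that("lesion sampling respects count range, skeleton and seeds", {
  ph <- build_anatomy(voxel_grid(c(24, 24, 48), spacing = 8), seed = 1)
  expect_identical(sample_lesions(ph, c(0, 0), seed = 1), list())

  les <- sample_lesions(ph, c(5, 15), seed = 7)
  skel <- skeleton_mask(ph)
  for (l in les) {
    expect_true(skel[l$center[1], l$center[2], l$center[3]])
    expect_gt(l$uptake, 1)
    expect_true(all(l$semi_axes > 0))
  }
  expect_identical(sample_lesions(ph, c(5, 15), seed = 7), les)
  ids <- vapply(les, `[[`, integer(1), "id")
  expect_identical(ids, seq_along(les))
})

test_that("lesion counts are uniform over the configured range", {
  ph <- build_anatomy(voxel_grid(c(20, 20, 32), spacing = 8), seed = 2)
  cfg <- phantom_config()
  cfg$min_center_dist_factor <- 0 # no rejection: count distribution pure
  counts <- vapply(1:150, function(s)
    length(sample_lesions(ph, c(3, 6), seed = s, config = cfg)),
    numeric(1))
  tab <- table(factor(counts, levels = 3:6))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("applying lesions modifies activity, CT and labels as specified", {
  ph <- make_bone_phantom(c(24, 24, 24), spacing = 4)
  codes <- tissue_codes()
  expect_identical(apply_lesions(ph, list()), ph)

  cfg <- phantom_config()
  cfg$deform_amp <- 0
  les <- list(list(id = 1L, center = c(12L, 12L, 12L),
                   semi_axes = c(12, 12, 12), uptake = 5,
                   ct_delta = -300, deform = NULL))
  ph2 <- apply_lesions(ph, les, config = cfg)
  mask <- ph2$labels == codes[["lesion"]]
  expect_gt(sum(mask), 0)
  # uptake multiplies the pre-insertion activity
  expect_equal(mean(ph2$activity[mask]) / mean(ph$activity[mask]), 5,
               tolerance = 1e-12)
  # lytic lesion lowers CT
  expect_lt(mean(ph2$ct[mask]), mean(ph$ct[mask]))
  # re-applying the same lesion id is a no-op
  ph3 <- apply_lesions(ph2, les, config = cfg)
  expect_identical(ph3$activity, ph2$activity)
  expect_true(all(ph2$activity >= 0))
})

test_that("undeformed lesion volume matches the analytic ellipsoid", {
  ph <- make_bone_phantom(c(32, 32, 32), spacing = 4)
  cfg <- phantom_config()
  cfg$deform_amp <- 0
  ax <- c(20, 16, 12)
  les <- list(list(id = 1L, center = c(16L, 16L, 16L), semi_axes = ax,
                   uptake = 3, ct_delta = -100, deform = NULL))
  ph2 <- apply_lesions(ph, les, config = cfg)
  v_vox <- sum(ph2$labels == tissue_codes()[["lesion"]]) * prod(ph2$grid$spacing)
  h <- 2 * max(ph2$grid$spacing) # two voxel shells of discretisation slack
  v_lo <- 4 / 3 * pi * prod(pmax(ax - h, 0))
  v_hi <- 4 / 3 * pi * prod(ax + h)
  expect_gt(v_vox, v_lo)
  expect_lt(v_vox, v_hi)
})

test_that("full phantom generation is reproducible and label-consistent", {
  g <- voxel_grid(c(24, 24, 48), spacing = 8)
  ph <- generate_phantom(g, seed = 9)
  ph2 <- generate_phantom(g, seed = 9)
  expect_identical(ph$labels, ph2$labels)
  expect_identical(ph$ct, ph2$ct)
  codes <- tissue_codes()
  # lesion label overrides bone; no negative activity anywhere
  expect_true(all(ph$activity >= 0))
  expect_gt(sum(ph$labels == codes[["lesion"]]), 0)
})
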