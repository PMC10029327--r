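test_that("threshold extremes saturate or empty the mask", {
  set.seed(1)
  vg <- voxel_grid(array(runif(4096), c(16, 16, 16)), 1)
  lo <- threshold_segment(vg, min(vg$data))
  expect_true(all(lo$data))
  hi <- threshold_segment(vg, max(vg$data) + 1e-9)
  expect_false(any(hi$data))
  expect_error(threshold_segment(vg, NA_real_), "finite")
  auto <- threshold_segment(vg)
  expect_true(is.numeric(attr(auto, "threshold")))
})

test_that("segment sets enforce disjointness", {
  m <- binary_mask(array(TRUE, c(4, 4, 4)), 1)
  e <- binary_mask(array(FALSE, c(4, 4, 4)), 1)
  expect_error(segment_set(m, m, e), "disjoint")
  expect_silent(segment_set(m, e, e))
})

test_that("a solid ball with an enclosed cavity segments cleanly", {
  n <- 64
  ball <- ball_mask(16, n)
  cav <- ball_mask(5, n)
  m <- binary_mask(ball$data & !cav$data, 1)
  segs <- build_segments(m, closing_radius_um = 6, on_opening_radius_um = 6,
                         consolidate_radius_um = 0)
  # cavity removed into the ON, SAS empty, CSF is the outside
  expect_true(all(segs$on_mask$data[cav$data]))
  expect_false(any(segs$sas_mask$data))
  expect_true(all(segs$csf_mask$data[!dilate_ball(ball, 2)$data]))
  expect_false(any(segs$csf_mask$data & ball$data))
})

test_that("the main CSF candidate wins over small pockets", {
  # two empty pockets tunnelling to the z-faces inside a solid block:
  # 1000-voxel and 8-voxel cross-sections; CSF must be the large one
  n <- 48
  m <- array(TRUE, c(n, n, n))
  m[11:20, 11:30, ] <- FALSE     # 10 x 20 shaft
  m[35:36, 35:38, ] <- FALSE     # 2 x 4 shaft
  segs <- build_segments(binary_mask(m, 1), closing_radius_um = 4,
                         on_opening_radius_um = 4,
                         consolidate_radius_um = 0)
  expect_true(all(segs$csf_mask$data[11:20, 11:30, ]))
  expect_false(any(segs$csf_mask$data[35:36, 35:38, ]))
})

test_that("the pipeline recovers the phantom compartments", {
  fx <- pipeline_fixture(6)
  segs <- fx$segs
  tr <- fx$phantom$truth

  # ON: essentially the whole nerve, nothing else
  expect_gt(mean(segs$on_mask$data[tr$nerve_mask$data]), 0.95)
  expect_lt(sum(segs$on_mask$data & tr$csf_mask$data) /
              sum(segs$on_mask$data), 0.05)

  # CSF: one 26-connected component closely matching the annulus
  lab <- label_components(segs$csf_mask, 26)
  expect_equal(max(lab), 1L)
  dice <- 2 * sum(segs$csf_mask$data & tr$csf_mask$data) /
    (sum(segs$csf_mask$data) + sum(tr$csf_mask$data))
  expect_gt(dice, 0.95)

  # SAS microstructure: mid-span trabecular recovery >= 95%; the junction
  # cones near the walls are partly absorbed by the ON/dura envelopes
  d <- dim(tr$micro_mask$data)
  v <- tr$spec
  ax <- (seq_len(d[1]) - 1) - (d[1] - 1) / 2
  rho <- array(rep(sqrt(outer(ax^2, ax^2, `+`)), times = d[3]), d)
  midgap <- (v$nerve_radius_um + v$dura_radius_um) / 2
  mid <- tr$micro_mask$data & abs(rho - midgap) < 8
  expect_gt(mean(segs$sas_mask$data[mid]), 0.95)
  expect_gt(mean(segs$sas_mask$data[tr$micro_mask$data]), 0.7)
  # and almost no nerve voxels leak into the microstructure
  expect_lt(sum(segs$sas_mask$data & tr$nerve_mask$data) /
              sum(tr$nerve_mask$data), 0.02)

  # invariants: disjoint, and SAS within the CSF envelope reach
  expect_false(any(segs$sas_mask$data & segs$csf_mask$data))
  expect_false(any(segs$sas_mask$data & segs$on_mask$data))
  reach <- dilate_ball(segs$csf_mask, segs$params$closing_radius_um)
  expect_true(all(reach$data[segs$sas_mask$data]))
})

test_that("microstructure removal conserves voxels and is idempotent", {
  fx <- truth_segs_fixture(16)
  segs <- fx$segs
  nm <- remove_microstructure(segs)
  expect_false(any(nm$sas_mask$data))
  expect_identical(sum(nm$csf_mask$data),
                   sum(segs$csf_mask$data) + sum(segs$sas_mask$data))
  expect_identical(nm$on_mask$data, segs$on_mask$data)
  again <- remove_microstructure(nm)
  expect_identical(again$csf_mask$data, nm$csf_mask$data)
})

test_that("sector exclusion behaves at 0, 60 and 360 degrees", {
  fx <- fixture("symmetric_truth", function() {
    spec <- phantom_spec(trabecula_count = 0L, septum_count = 0L,
                         artifact_count = 0L, rng_seed = 3)
    segments_from_truth(generate_phantom(spec)$truth)
  })
  s0 <- apply_sector_exclusion(fx, 0)
  expect_identical(s0$csf_mask$data, fx$csf_mask$data)
  expect_equal(s0$excluded_sector$angle_deg, 0)

  s60 <- apply_sector_exclusion(fx, 60, center_um = c(0, 0))
  expect_equal(sum(s60$csf_mask$data) / sum(fx$csf_mask$data), 300 / 360,
               tolerance = 0.01)

  s360 <- apply_sector_exclusion(fx, 360)
  expect_false(any(s360$csf_mask$data))
  expect_false(any(s360$on_mask$data))

  expect_error(apply_sector_exclusion(fx, 400), "360")
})
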