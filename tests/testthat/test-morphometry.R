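test_that("a digitized ball reads its own diameter everywhere inside", {
  tm <- local_thickness(ball_mask(10, 27))
  inside <- ball_mask(10, 27)$data
  th <- tm$thickness[inside]
  expect_true(all(abs(th - 20) <= 1.2))
})

test_that("a slab reads its own thickness everywhere", {
  tm <- local_thickness(slab_mask(20, 29, 48))
  th <- tm$thickness[slab_mask(20, 29, 48)$data]
  expect_true(all(abs(th - 10) <= 1))
})

test_that("a lone voxel reads one ball of its own distance scale", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  tm <- local_thickness(binary_mask(m, 1))
  expect_equal(tm$thickness[4, 4, 4], 2)  # 2 * distance to background
  tb <- brute_force_thickness(binary_mask(m, 1))
  expect_equal(tb$thickness[4, 4, 4], 2)
})

test_that("disjoint balls each read their own diameter", {
  m <- array(FALSE, c(40, 20, 20))
  ax1 <- (1:40); ay <- (1:20)
  for (i in 1:40) for (j in 1:20) for (k in 1:20) {
    if ((i - 10)^2 + (j - 10)^2 + (k - 10)^2 <= 16) m[i, j, k] <- TRUE
    if ((i - 30)^2 + (j - 10)^2 + (k - 10)^2 <= 64) m[i, j, k] <- TRUE
  }
  tm <- local_thickness(binary_mask(m, 1))
  small <- tm$thickness[1:19, , ][m[1:19, , ]]
  big <- tm$thickness[21:40, , ][m[21:40, , ]]
  expect_true(all(abs(small - 8) <= 1.5))
  expect_true(all(abs(big - 16) <= 1.5))
})

test_that("the fast path equals the brute-force oracle voxel-exactly", {
  # seeded random masks
  for (s in 1:10) {
    set.seed(s)
    m <- array(runif(24^3) < 0.4, c(24, 24, 24))
    if (!any(m)) next
    bm <- binary_mask(m, 1)
    expect_identical(local_thickness(bm)$thickness,
                     brute_force_thickness(bm)$thickness)
  }
  # analytic shapes up to 48^3
  shapes <- list(ball_mask(10, 28),
                 ball_mask(20, 48),
                 slab_mask(10, 21, 32),
                 cylinder_mask(8, 40),
                 {
                   set.seed(99)
                   b <- close_ball(binary_mask(array(runif(40^3) < 0.45,
                                                     c(40, 40, 40)), 1), 2)
                   b$data[c(1:2, 39:40), , ] <- FALSE
                   b$data[, c(1:2, 39:40), ] <- FALSE
                   b$data[, , c(1:2, 39:40)] <- FALSE
                   b
                 })
  for (bm in shapes) {
    expect_identical(local_thickness(bm)$thickness,
                     brute_force_thickness(bm)$thickness)
  }
})

test_that("oracle output satisfies the thickness-map invariants", {
  set.seed(5)
  m <- array(runif(20^3) < 0.45, c(20, 20, 20))
  bm <- binary_mask(m, 1)
  tb <- brute_force_thickness(bm)
  dt <- sqrt(sasmorph:::edt_sq_vox(!m))
  th <- tb$thickness[m]
  expect_true(all(th >= 2 * dt[m] - 1 - 1e-9))
  expect_true(all(th <= 2 * max(dt[m]) + 1e-9))
})

test_that("thickness is monotone under dilation", {
  for (s in 1:5) {
    set.seed(s)
    m <- array(runif(20^3) < 0.2, c(20, 20, 20))
    if (!any(m)) next
    bm <- binary_mask(m, 1)
    t1 <- local_thickness(bm)$thickness
    t2 <- local_thickness(dilate_ball(bm, 1.5))$thickness
    expect_true(all(t2[m] >= t1[m] - 1e-9))
  }
})

test_that("the brute-force oracle refuses oversized grids", {
  m <- binary_mask(array(TRUE, c(70, 70, 70)), 1)
  m$data[1] <- FALSE
  expect_error(brute_force_thickness(m), "too large")
})

test_that("separation reads the annulus gap and shrinks with trabeculae", {
  empty <- small_truth_fixture(0)
  sep0 <- separation(empty$segs)
  gap <- empty$truth$spec$dura_radius_um - empty$truth$spec$nerve_radius_um
  th <- sep0$thickness[sep0$mask]
  expect_true(all(abs(th - gap) <= 2.5))

  full <- small_truth_fixture(5)
  sep1 <- separation(full$segs)
  expect_lt(mean(sep1$thickness[sep1$mask]), mean(th))

  empty_csf <- segment_set(
    binary_mask(array(FALSE, c(4, 4, 4)), 1),
    binary_mask(array(FALSE, c(4, 4, 4)), 1),
    binary_mask(array(FALSE, c(4, 4, 4)), 1))
  expect_error(separation(empty_csf), "empty")
})

test_that("thickness density functions are normalized and peak correctly", {
  tm <- local_thickness(slab_mask(15, 24, 40))
  pdf <- thickness_pdf(tm, bin_width_um = 2)
  expect_equal(sum(pdf$density) * 2, 1, tolerance = 1e-9)
  # uniform thickness: one occupied bin at density 1 / bin width
  expect_equal(max(pdf$density), 1 / 2, tolerance = 1e-9)
  expect_equal(sum(pdf$density > 0), 1)
  expect_error(thickness_pdf(tm, 0), "positive")

  # parameter recovery from truth masks: trabeculae of radius 6
  fx <- pipeline_fixture(6)
  tmm <- local_thickness(fx$phantom$truth$micro_mask, "micro")
  expect_lte(abs(pdf_mode(thickness_pdf(tmm, 1)) - 12), 1)
})

test_that("the census finds constructed chambers at their diameters", {
  ch <- fixture("chambers", function() generate_chamber_phantom(c(150, 300)))
  sm <- fixture("chambers_sep", function() {
    local_thickness(fixture("chambers", function()
      generate_chamber_phantom(c(150, 300)))$mask, "csf")
  })
  cen <- count_intertrabecular_spaces(sm, 130)
  expect_equal(nrow(cen), 2L)
  got <- sort(cen$diameter_um)
  expect_lt(abs(got[1] / 150 - 1), 0.05)
  expect_lt(abs(got[2] / 300 - 1), 0.05)
  expect_true(all(cen$volume_mm3 > 0))

  # a threshold above the global maximum yields an empty census
  empty <- count_intertrabecular_spaces(sm, 1000)
  expect_equal(nrow(empty), 0L)

  # halving the h-maxima depth never decreases the count
  c2 <- count_intertrabecular_spaces(sm, 130, h_um = 6)
  c1 <- count_intertrabecular_spaces(sm, 130, h_um = 3)
  expect_gte(nrow(c1), nrow(c2))
})
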