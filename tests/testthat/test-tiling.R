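smooth_noise <- function(n, seed, sigma = 2) {
  set.seed(seed)
  x <- array(rnorm(n^3), c(n, n, n))
  array(sasmorph:::cpp_gauss3(x, c(n, n, n), sigma), c(n, n, n))
}

test_that("register_pair recovers a known shift to sub-voxel accuracy", {
  base <- smooth_noise(64, seed = 2)
  s <- c(5, -3, 2)
  A <- voxel_grid(base[6:53, 6:53, 6:53], 1)
  B <- voxel_grid(base[(6 + s[1]):(53 + s[1]), (6 + s[2]):(53 + s[2]),
                       (6 + s[3]):(53 + s[3])], 1)
  for (nom in list(s, s + c(1, -1, 2), s + c(-2, 2, 0))) {
    r <- register_pair(A, B, nom, search_halfwidth = 5)
    expect_lt(max(abs(r$shift - s)), 0.1)
    expect_gte(r$confidence, 0)
    expect_lte(r$confidence, 1)
  }
})

test_that("registration survives noise with exact integer part", {
  base <- smooth_noise(64, seed = 3, sigma = 1)
  s <- c(4, -2, 3)
  A0 <- base[6:53, 6:53, 6:53]
  B0 <- base[(6 + s[1]):(53 + s[1]), (6 + s[2]):(53 + s[2]),
             (6 + s[3]):(53 + s[3])]
  rng <- diff(range(A0))
  clean <- register_pair(voxel_grid(A0, 1), voxel_grid(B0, 1), s)
  confs <- numeric(20)
  for (k in 1:20) {
    set.seed(100 + k)
    A <- voxel_grid(A0 + array(rnorm(length(A0), 0, 0.1 * rng), dim(A0)), 1)
    B <- voxel_grid(B0 + array(rnorm(length(B0), 0, 0.1 * rng), dim(B0)), 1)
    r <- register_pair(A, B, s, search_halfwidth = 5)
    expect_identical(round(r$shift), s)
    confs[k] <- r$confidence
  }
  expect_lt(mean(confs), clean$confidence)
})

test_that("register_pair rejects unusable overlaps", {
  A <- voxel_grid(array(rnorm(20^3), c(20, 20, 20)), 1)
  expect_error(register_pair(A, A, c(15, 0, 0)), "fewer than 10")
  Bf <- voxel_grid(array(1, c(20, 20, 20)), 1)
  expect_error(register_pair(Bf, Bf, c(0, 0, 0)), "zero-variance")
})

test_that("offset reconciliation solves trivial and perturbed graphs", {
  s12 <- c(10, 0, 2)
  one <- resolve_offsets(data.frame(tile_a = 1, tile_b = 2,
                                    sx = s12[1], sy = s12[2], sz = s12[3]))
  expect_equal(as.numeric(one[2, c("x", "y", "z")]), s12)
  expect_equal(as.numeric(one[1, c("x", "y", "z")]), c(0, 0, 0))

  # consistent 3-cycle: zero residual
  e <- data.frame(tile_a = c(1, 2, 3), tile_b = c(2, 3, 1),
                  sx = c(10, 5, -15), sy = c(0, 2, -2), sz = c(1, 1, -2))
  out <- resolve_offsets(e)
  expect_lt(max(abs(attr(out, "residuals"))), 1e-9)

  # one edge perturbed by +3: the hand-solved normal equations give
  # offset errors of 2e/3 and e/3 (e/3 and -e/3 after gauge alignment)
  e2 <- e; e2$sx[1] <- e2$sx[1] + 3
  out2 <- resolve_offsets(e2)
  expect_equal(out2$x, c(0, 12, 16), tolerance = 1e-8)
  est <- out2$x - mean(out2$x - c(0, 10, 15))
  expect_lte(max(abs(est - c(0, 10, 15))), 1.5)
})

test_that("disconnected tile graphs are reported with their components", {
  e <- data.frame(tile_a = c(1, 3), tile_b = c(2, 4),
                  sx = 1, sy = 0, sz = 0)
  expect_error(resolve_offsets(e, n_tiles = 4), "disconnected")
  expect_error(resolve_offsets(e, n_tiles = 4), "\\{3,4\\}")
})

test_that("stitching is idempotent on a single clean tile", {
  x <- smooth_noise(32, seed = 5)
  tile <- voxel_grid(x, 1)
  st <- stitch(list(tile))
  expect_equal(st$data, x, tolerance = 1e-12)
})

test_that("identical-background tiles stitch to the naive mosaic", {
  base <- smooth_noise(48, seed = 6)
  t1 <- voxel_grid(base[1:32, , ], 1, origin = c(0, 0, 0))
  t2 <- voxel_grid(base[17:48, , ], 1, origin = c(16, 0, 0))
  sp <- stitch(list(t1, t2))
  nv <- stitch(list(t1, t2), method = "naive")
  expect_equal(sp$data, nv$data, tolerance = 1e-6)
  expect_equal(sp$data, base, tolerance = 1e-6)
})

test_that("output geometry is set by layout, not content", {
  t1 <- voxel_grid(array(rnorm(8000), c(20, 20, 20)), 1, origin = c(0, 0, 0))
  t2 <- voxel_grid(array(rnorm(8000), c(20, 20, 20)), 1, origin = c(12, 0, 0))
  t3 <- voxel_grid(array(runif(8000), c(20, 20, 20)), 1, origin = c(0, 0, 0))
  t4 <- voxel_grid(array(runif(8000), c(20, 20, 20)), 1, origin = c(12, 0, 0))
  expect_identical(dim(stitch(list(t1, t2))$data),
                   dim(stitch(list(t3, t4))$data))
})

test_that("stitching reports coverage gaps", {
  t1 <- voxel_grid(array(1, c(10, 10, 10)), 1, origin = c(0, 0, 0))
  t2 <- voxel_grid(array(1, c(10, 10, 10)), 1, origin = c(30, 0, 0))
  expect_error(stitch(list(t1, t2), method = "naive"), "gaps")
})

test_that("phantom tiles register and stitch seamlessly", {
  fx <- fixture("tiled_phantom", function() {
    ph <- generate_phantom(small_phantom_spec(seed = 5))
    tiles <- add_tile_backgrounds_and_split(ph$volume, c(56, 56, 64), 0.2,
                                            gradient_amplitude = 0.15,
                                            rng_seed = 9)
    list(ph = ph, tiles = tiles)
  })
  tiles <- fx$tiles
  src <- fx$ph$volume$data
  true_off <- do.call(rbind, lapply(tiles, `[[`, "true_offset"))
  shape <- dim(tiles[[1]]$tile$data)
  edges <- NULL
  set.seed(42)
  for (i in 1:(length(tiles) - 1)) for (j in (i + 1):length(tiles)) {
    nom <- true_off[j, ] - true_off[i, ]
    ov <- pmin(true_off[i, ] + shape, true_off[j, ] + shape) -
      pmax(true_off[i, ], true_off[j, ])
    if (any(ov < 10)) next
    r <- register_pair(tiles[[i]]$tile, tiles[[j]]$tile,
                       nom + sample(-2:2, 3, replace = TRUE),
                       search_halfwidth = 5)
    expect_lt(max(abs(r$shift - nom)), 0.5)
    edges <- rbind(edges, data.frame(tile_a = i, tile_b = j,
                                     sx = r$shift[1], sy = r$shift[2],
                                     sz = r$shift[3],
                                     confidence = r$confidence))
  }
  off <- resolve_offsets(edges, n_tiles = length(tiles))
  est <- as.matrix(off[, c("x", "y", "z")])
  est <- sweep(est, 2, est[1, ] - true_off[1, ])
  expect_lt(max(abs(est - true_off)), 0.5)

  st <- stitch(tiles, offsets = est)
  nv <- stitch(tiles, method = "naive")
  seam_jump <- function(res) {
    m <- 0
    seams <- setdiff(unique(true_off[, 1]), 0)
    for (x in c(seams, seams + shape[1] - max(seams)))
      m <- max(m, max(abs(res[x + 1, , ] - res[x, , ])))
    for (y in c(seams, seams + shape[2] - max(seams)))
      m <- max(m, max(abs(res[, y + 1, ] - res[, y, ])))
    m
  }
  res_s <- st$data - src
  res_n <- nv$data - src
  expect_lt(seam_jump(res_s), 0.2 * seam_jump(res_n))
  # global fidelity: rms residual bounded by noise + 10% of the gradient
  spec <- fx$ph$truth$spec
  expect_lt(sqrt(mean(res_s^2)),
            spec$noise_sigma + 0.1 * spec$gradient_amplitude)
})

test_that("trilinear resampling refines a coarse grid consistently", {
  x <- smooth_noise(24, seed = 8)
  g <- voxel_grid(x, 2)
  f <- resample_trilinear(g, 1)
  expect_equal(f$voxel_size_um, 1)
  # original samples are reproduced at even positions
  expect_equal(f$data[seq(1, 47, by = 2), 1, 1], x[, 1, 1],
               tolerance = 1e-9)
})
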