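test_that("signed distance follows the half-voxel convention", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  sdf <- signed_distance(binary_mask(m, 1))
  expect_equal(sdf$phi[5, 5, 5], 0.5)
  expect_equal(sdf$phi[6, 5, 5], -0.5)
  expect_equal(sdf$phi[5, 5, 7], -1.5)

  expect_error(signed_distance(binary_mask(array(FALSE, c(4, 4, 4)), 1)),
               "empty")
  expect_error(signed_distance(binary_mask(array(TRUE, c(4, 4, 4)), 1)),
               "full")
})

test_that("phi at a ball center matches a brute-force distance scan", {
  n <- 51
  mask <- ball_mask(20, n)
  sdf <- signed_distance(mask)
  ctr <- (n + 1) / 2
  # independent oracle: minimum distance from the center to any
  # background voxel, computed by direct enumeration
  bg <- which(!mask$data, arr.ind = TRUE)
  dmin <- min(sqrt(rowSums(sweep(bg, 2, rep(ctr, 3))^2)))
  expect_equal(sdf$phi[ctr, ctr, ctr], dmin - 0.5, tolerance = 1e-9)
  expect_lt(abs(sdf$phi[ctr, ctr, ctr] - 20), 0.5 + 1e-9)
})

test_that("phi is 1-Lipschitz up to the digital interface slack", {
  # same-sign pairs satisfy the bound exactly; opposite-sign pairs can
  # exceed it by at most (sqrt(3) - 1) voxels with this convention
  slack <- sqrt(3) - 1
  for (s in 1:10) {
    set.seed(s)
    d <- c(12, 12, 12)
    m <- array(runif(prod(d)) < 0.45, d)
    if (!any(m) || all(m)) next
    sdf <- signed_distance(binary_mask(m, 1))
    idx <- which(array(TRUE, d), arr.ind = TRUE)
    phi <- as.vector(sdf$phi)
    n <- nrow(idx)
    for (i in seq(1, n, by = 432)) {
      j <- i:min(i + 431, n)
      D <- sqrt(outer(idx[j, 1], idx[, 1], `-`)^2 +
                  outer(idx[j, 2], idx[, 2], `-`)^2 +
                  outer(idx[j, 3], idx[, 3], `-`)^2)
      P <- abs(outer(phi[j], phi, `-`))
      same <- outer(phi[j] >= 0, phi >= 0, `==`)
      expect_lte(max((P - D)[same]), 1e-9)
      expect_lte(max(P - D), slack + 1e-9)
    }
  }
})

test_that("mollified volume is accurate and first-order convergent", {
  ctr <- c(0.3, 0.17, 0.41)
  v1 <- volume_mollified(signed_distance(ball_mask(20, 51, ctr)))
  ref <- 4 / 3 * pi * 20^3
  expect_lt(abs(v1$um3 / ref - 1), 0.01)
  # halving the voxel size (same physical ball) at least halves the error
  m2 <- ball_mask(40, 101, ctr * 2, voxel_size_um = 0.5)
  v2 <- volume_mollified(signed_distance(m2), epsilon_um = 0.5)
  expect_lte(abs(v2$um3 / (0.5^3 * 4 / 3 * pi * 40^3) - 1),
             0.5 * abs(v1$um3 / ref - 1))
  expect_equal(v1$mm3, v1$um3 * 1e-12)
})

test_that("deep background integrates to zero volume", {
  m <- array(FALSE, c(16, 16, 16)); m[2, 2, 2] <- TRUE
  sdf <- signed_distance(binary_mask(m, 1))
  far <- sdf$phi[8:16, 8:16, 8:16]
  expect_true(all(far < -1))
  u <- pmin(pmax((far + 1) / 2, 0), 1)
  expect_equal(sum(u), 0)
})

test_that("zero level-set of a ball is a closed mesh with the right area", {
  sdf <- signed_distance(ball_mask(20, 51))
  mesh <- extract_zero_levelset(sdf)
  expect_true(sasmorph:::mesh_is_closed(mesh))
  a <- mesh_area(mesh)
  expect_lt(abs(a$um2 / (4 * pi * 20^2) - 1), 0.02)
  expect_equal(a$mm2, a$um2 * 1e-6)
})

test_that("planar half-spaces mesh exactly", {
  n <- 21
  z <- array(rep(0:(n - 1), each = n * n), c(n, n, n))
  phi <- 9.3 - z
  sdf <- structure(list(phi = phi, voxel_size_um = 1,
                        origin = c(0, 0, 0), source = "plane"),
                   class = "signed_distance_field")
  mesh <- extract_zero_levelset(sdf, regularize_sigma_vox = 0)
  expect_equal(mesh_area(mesh)$um2, (n - 1)^2, tolerance = 1e-6)
  expect_equal(range(mesh$vertices[, 3]), c(9.3, 9.3), tolerance = 1e-9)
})

test_that("capsule lateral area matches the closed form", {
  r <- 6; L <- 60
  n <- c(96, 28, 28)
  x <- (seq_len(n[1]) - 1) - (n[1] - 1) / 2
  y <- (seq_len(n[2]) - 1) - (n[2] - 1) / 2
  X <- array(rep(x, times = n[2] * n[3]), n)
  Y <- array(rep(rep(y, each = n[1]), times = n[3]), n)
  Z <- array(rep(y, each = n[1] * n[2]), n)
  t <- pmin(pmax(X, -L / 2), L / 2)
  mask <- binary_mask(sqrt((X - t)^2 + Y^2 + Z^2) <= r, 1)
  mesh <- extract_zero_levelset(signed_distance(mask))
  ref <- 2 * pi * r * L + 4 * pi * r^2
  expect_lt(abs(mesh_area(mesh)$um2 / ref - 1), 0.03)
})

test_that("single-signed fields yield an empty mesh with a warning", {
  m <- ball_mask(5, 21)
  sdf <- signed_distance(m)
  sdf$phi <- sdf$phi - 100  # all negative
  expect_warning(mesh <- extract_zero_levelset(sdf), "sign")
  expect_equal(nrow(mesh$triangles), 0)
  expect_equal(mesh_area(mesh)$um2, 0)
})

test_that("triangle areas follow the cross-product formula", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                       matrix(c(1, 2, 3), 1))
  expect_equal(mesh_area(tri)$um2, 6)
  # unit cube as 12 triangles
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  expect_equal(mesh_area(triangle_mesh(v, f))$um2, 6)
})

test_that("volume and area are invariant under axis permutations and flips", {
  set.seed(14)
  base <- array(runif(32^3) < 0.4, c(32, 32, 32))
  base <- close_ball(binary_mask(base, 1), 1.5)$data  # give it structure
  base[c(1:2, 31:32), , ] <- FALSE
  base[, c(1:2, 31:32), ] <- FALSE
  base[, , c(1:2, 31:32)] <- FALSE
  measure <- function(m) {
    sdf <- signed_distance(binary_mask(m, 1))
    c(volume_mollified(sdf)$um3,
      mesh_area(extract_zero_levelset(sdf))$um2)
  }
  ref <- measure(base)
  for (tf in list(function(a) aperm(a, c(2, 1, 3)),
                  function(a) aperm(a, c(3, 2, 1)),
                  function(a) a[32:1, , ],
                  function(a) a[, , 32:1])) {
    got <- measure(tf(base))
    # volume is exactly invariant; the mesh area only up to the (tiny)
    # triangulation dependence of the fixed-diagonal cell decomposition
    expect_equal(got[1], ref[1], tolerance = 1e-12)
    expect_equal(got[2], ref[2], tolerance = 1e-3)
  }
})
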