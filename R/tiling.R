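# Tile registration by phase correlation and seamless blending.
#
# Offsets are 0-based voxel triples locating each tile's first voxel in the
# global frame. register_pair() estimates the offset of tile_b relative to
# tile_a (o_b - o_a) to sub-voxel accuracy.

fft_nd <- function(x, inverse = FALSE) {
  stats::fft(x, inverse = inverse)
}

# radial raised-cosine high-pass that suppresses wavelengths longer than
# half the crop extent: the stabilizing preprocessing before correlation
bandpass_weights <- function(d) {
  ks <- lapply(d, function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
    if (n == 1) k <- 0
    k
  })
  kmag <- sqrt(outer(outer(ks[[1]]^2, ks[[2]]^2, `+`), ks[[3]]^2, `+`))
  lam_max <- min(d[d > 1]) / 2
  t <- log2(pmax(kmag, 1e-12) * lam_max)
  w <- ifelse(t >= 1, 1, ifelse(t <= 0, 0, sin(pi / 2 * t)^2))
  array(w, d)
}

#' Register two overlapping tiles by phase correlation
#'
#' Crops the overlap implied by `nominal_shift`, optionally suppresses the
#' lowest-frequency content of both crops (robustness to smooth per-tile
#' background gradients), computes the normalized cross-power spectrum, and
#' locates its peak within `search_halfwidth` voxels of the nominal shift.
#' The integer peak is refined per axis with a 3-point parabolic fit.
#'
#' @param tile_a,tile_b [voxel_grid] tiles.
#' @param nominal_shift expected offset of `tile_b` relative to `tile_a`
#'   (voxel triple).
#' @param search_halfwidth search range around the nominal shift, voxels.
#' @param band_pass suppress the lowest-frequency octave before
#'   correlating (default TRUE).
#' @return A list with `shift` (sub-voxel triple) and `confidence`
#'   (normalized correlation peak in `[0, 1]`).
#' @export
register_pair <- function(tile_a, tile_b, nominal_shift,
                          search_halfwidth = 5, band_pass = TRUE) {
  stopifnot(inherits(tile_a, "voxel_grid"), inherits(tile_b, "voxel_grid"))
  da <- dim(tile_a$data); db <- dim(tile_b$data)
  s <- round(nominal_shift)
  # overlap window in tile_a local coordinates
  lo <- pmax(rep(0, 3), s)
  hi <- pmin(da, s + db)
  ov <- hi - lo
  if (any(ov < 10))
    stop("tiles overlap by fewer than 10 voxels along some axis")
  A <- tile_a$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                   drop = FALSE]
  blo <- lo - s
  B <- tile_b$data[(blo[1] + 1):(blo[1] + ov[1]),
                   (blo[2] + 1):(blo[2] + ov[2]),
                   (blo[3] + 1):(blo[3] + ov[3]), drop = FALSE]
  if (var(as.vector(A)) == 0 || var(as.vector(B)) == 0)
    stop("flat (zero-variance) overlap: content cannot be registered")

  A <- A - mean(A); B <- B - mean(B)
  # Hann window: crop borders sit at identical positions in both crops, so
  # without tapering their spectral leakage correlates coherently at zero
  # lag and can mask the true displacement peak
  hann <- function(n) {
    if (n == 1) return(1)
    0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  }
  W <- array(rep(hann(ov[1]), times = ov[2] * ov[3]), ov) *
    array(rep(rep(hann(ov[2]), each = ov[1]), times = ov[3]), ov) *
    array(rep(hann(ov[3]), each = ov[1] * ov[2]), ov)
  A <- A * W; B <- B * W
  FA <- fft_nd(A); FB <- fft_nd(B)
  if (band_pass) {
    w <- bandpass_weights(ov)
    FA <- FA * w; FB <- FB * w
  }
  CP <- FA * Conj(FB)
  mag <- Mod(CP)
  R <- CP / (mag + 1e-9 * max(mag))
  r <- Re(fft_nd(R, inverse = TRUE)) / prod(ov)

  # admissible residual shifts: within +/- search_halfwidth, wrapped
  idx_axis <- function(n, hw) {
    hw <- min(hw, floor((n - 1) / 2))
    c(0:hw, (n - hw):(n - 1))  # 0-based circular indices
  }
  hw <- search_halfwidth
  ix <- idx_axis(ov[1], hw); iy <- idx_axis(ov[2], hw); iz <- idx_axis(ov[3], hw)
  sub <- r[ix + 1, iy + 1, iz + 1, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)
  if (nrow(pk) > 1) {  # tie-break: smallest shift magnitude, then lexicographic
    tosh <- function(i, n) ifelse(i > n / 2, i - n, i)
    cand <- cbind(tosh(ix[pk[, 1]], ov[1]), tosh(iy[pk[, 2]], ov[2]),
                  tosh(iz[pk[, 3]], ov[3]))
    o <- order(rowSums(cand^2), cand[, 1], cand[, 2], cand[, 3])
    pk <- pk[o[1], , drop = FALSE]
  }
  p0 <- c(ix[pk[1, 1]], iy[pk[1, 2]], iz[pk[1, 3]])  # 0-based in r

  # separable 3-point parabolic refinement around the integer peak
  delta <- numeric(3)
  for (a in 1:3) {
    n <- ov[a]
    get_r <- function(off) {
      q <- p0; q[a] <- (q[a] + off) %% n
      r[q[1] + 1, q[2] + 1, q[3] + 1]
    }
    ym <- get_r(-1); y0 <- get_r(0); yp <- get_r(1)
    den <- ym - 2 * y0 + yp
    delta[a] <- if (abs(den) > 1e-12) 0.5 * (ym - yp) / den else 0
    if (!is.finite(delta[a]) || abs(delta[a]) > 1) delta[a] <- 0
  }
  wrap <- ifelse(p0 > ov / 2, p0 - ov, p0)
  resid <- wrap + delta
  # r peaks at (true shift - nominal): correct the nominal by the residual
  list(shift = as.numeric(s + resid),
       confidence = max(0, min(1, max(sub))))
}

#' Reconcile pairwise shifts into global tile offsets
#'
#' Solves the weighted least-squares system `o_b - o_a = shift_ab` per
#' axis, with the first tile pinned at the origin.
#'
#' @param edges a data frame with columns `tile_a`, `tile_b` (integer tile
#'   ids), `sx`, `sy`, `sz` (estimated shifts) and optionally `confidence`
#'   (edge weights).
#' @param n_tiles total number of tiles (defaults to the largest id seen).
#' @return A tibble with columns `tile`, `x`, `y`, `z`; the attribute
#'   `residuals` carries per-edge residuals.
#' @export
resolve_offsets <- function(edges, n_tiles = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("tile_a", "tile_b", "sx", "sy", "sz") %in% names(edges)))
  if (is.null(n_tiles)) n_tiles <- max(edges$tile_a, edges$tile_b)

  # connectivity check (union-find)
  parent <- seq_len(n_tiles)
  find <- function(i) {
    i <- as.integer(i)
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges$tile_a[e]); rb <- find(edges$tile_b[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n_tiles), find, integer(1))
  if (length(unique(roots)) > 1) {
    comps <- split(seq_len(n_tiles), roots)
    stop("tile graph is disconnected; components: ",
         paste(vapply(comps, function(cc) paste0("{", paste(cc, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }

  w <- if ("confidence" %in% names(edges)) pmax(edges$confidence, 1e-6)
       else rep(1, nrow(edges))
  ne <- nrow(edges)
  X <- matrix(0, ne, n_tiles)
  X[cbind(seq_len(ne), edges$tile_a)] <- -1
  X[cbind(seq_len(ne), edges$tile_b)] <- 1
  Xr <- X[, -1, drop = FALSE] * sqrt(w)
  solve_axis <- function(s) {
    y <- s * sqrt(w)
    beta <- qr.coef(qr(Xr), y)
    beta[is.na(beta)] <- 0
    c(0, beta)
  }
  O <- cbind(solve_axis(edges$sx), solve_axis(edges$sy), solve_axis(edges$sz))
  out <- tibble::tibble(tile = seq_len(n_tiles),
                        x = O[, 1], y = O[, 2], z = O[, 3])
  res <- cbind(edges$sx, edges$sy, edges$sz) -
    (O[edges$tile_b, , drop = FALSE] - O[edges$tile_a, , drop = FALSE])
  attr(out, "residuals") <- res
  out
}

# ---- stitching -----------------------------------------------------------

tile_monomials <- function(tile_shape, degree) {
  u <- lapply(1:3, function(a) {
    if (tile_shape[a] == 1) return(0)
    seq(-1, 1, length.out = tile_shape[a])
  })
  terms <- list()
  for (i in 0:degree) for (j in 0:degree) for (k in 0:degree)
    if (i + j + k <= degree)
      terms[[length(terms) + 1]] <- c(i, j, k)
  list(powers = terms, u = u)
}

eval_monomials_at <- function(mono, idx) {
  # idx: matrix of 1-based tile-local voxel coordinates
  u1 <- mono$u[[1]][idx[, 1]]; u2 <- mono$u[[2]][idx[, 2]]
  u3 <- mono$u[[3]][idx[, 3]]
  vapply(mono$powers, function(p) u1^p[1] * u2^p[2] * u3^p[3],
         numeric(nrow(idx)))
}

eval_background <- function(mono, coef, tile_shape) {
  U1 <- array(rep(mono$u[[1]], times = prod(tile_shape[2:3])), tile_shape)
  U2 <- array(rep(rep(mono$u[[2]], each = tile_shape[1]),
                  times = tile_shape[3]), tile_shape)
  U3 <- array(rep(mono$u[[3]], each = prod(tile_shape[1:2])), tile_shape)
  out <- array(0, tile_shape)
  for (m in seq_along(mono$powers)) {
    p <- mono$powers[[m]]
    out <- out + coef[m] * U1^p[1] * U2^p[2] * U3^p[3]
  }
  out
}

#' Blend registered tiles into a single seamless volume
#'
#' Jointly fits a low-order polynomial background per tile by least squares
#' on overlap differences (with a small ridge penalty that pins the overall
#' gauge), subtracts the fitted backgrounds, and blends with separable
#' raised-cosine feathering. With `method = "naive"` tiles are averaged in
#' overlaps with no correction — the reference "before" state for
#' seamlessness comparisons.
#'
#' @param tiles list of [voxel_grid] tiles (or the output of
#'   [add_tile_backgrounds_and_split()]).
#' @param offsets matrix/data frame of per-tile global offsets (voxels), or
#'   NULL to use each tile's origin.
#' @param method `"spectral"` (background-corrected, feathered) or
#'   `"naive"`.
#' @param poly_degree background polynomial degree.
#' @param sample_stride subsampling stride for the background fit.
#' @return A [voxel_grid] covering the union of tile footprints.
#' @export
stitch <- function(tiles, offsets = NULL, method = c("spectral", "naive"),
                   poly_degree = 2L, sample_stride = 2L) {
  method <- match.arg(method)
  if (!is.null(tiles[[1]]$tile))
    tiles <- lapply(tiles, `[[`, "tile")
  nt <- length(tiles)
  vsz <- tiles[[1]]$voxel_size_um
  if (is.null(offsets)) {
    offsets <- do.call(rbind, lapply(tiles, function(t) t$origin))
  } else {
    offsets <- as.matrix(as.data.frame(offsets)[, intersect(
      c("x", "y", "z"), names(as.data.frame(offsets))), drop = FALSE])
    if (ncol(offsets) != 3) offsets <- as.matrix(offsets)[, 1:3]
  }
  offsets <- round(offsets)
  shapes <- lapply(tiles, function(t) dim(t$data))

  lo <- apply(offsets, 2, min)
  hi <- sapply(1:3, function(a) max(offsets[, a] + sapply(shapes, `[`, a)))
  dd <- as.integer(hi - lo)

  # background estimation on overlaps
  data_arr <- lapply(tiles, function(t) t$data)
  if (method == "spectral" && nt > 1) {
    mono <- lapply(shapes, tile_monomials, degree = poly_degree)
    nm <- length(mono[[1]]$powers)
    XtX <- matrix(0, nt * nm, nt * nm)
    Xty <- numeric(nt * nm)
    nobs <- 0
    for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
      alo <- pmax(offsets[i, ], offsets[j, ])
      ahi <- pmin(offsets[i, ] + shapes[[i]], offsets[j, ] + shapes[[j]])
      if (any(ahi - alo < 2)) next
      gs <- lapply(1:3, function(a)
        seq(alo[a] + 1, ahi[a], by = sample_stride))
      gidx <- as.matrix(expand.grid(gs[[1]], gs[[2]], gs[[3]]))
      ii <- sweep(gidx, 2, offsets[i, ])  # 1-based local in tile i
      jj <- sweep(gidx, 2, offsets[j, ])
      di <- data_arr[[i]][ii]
      dj <- data_arr[[j]][jj]
      Mi <- eval_monomials_at(mono[[i]], ii)
      Mj <- eval_monomials_at(mono[[j]], jj)
      bi <- (i - 1) * nm + seq_len(nm); bj <- (j - 1) * nm + seq_len(nm)
      XtX[bi, bi] <- XtX[bi, bi] + crossprod(Mi)
      XtX[bj, bj] <- XtX[bj, bj] + crossprod(Mj)
      XtX[bi, bj] <- XtX[bi, bj] - crossprod(Mi, Mj)
      XtX[bj, bi] <- XtX[bj, bi] - crossprod(Mj, Mi)
      y <- di - dj
      Xty[bi] <- Xty[bi] + crossprod(Mi, y)
      Xty[bj] <- Xty[bj] - crossprod(Mj, y)
      nobs <- nobs + length(y)
    }
    if (nobs > 0) {
      lambda <- 1e-3 * max(diag(XtX))
      coef <- solve(XtX + lambda * diag(nt * nm), Xty)
      for (i in seq_len(nt)) {
        ci <- coef[(i - 1) * nm + seq_len(nm)]
        data_arr[[i]] <- data_arr[[i]] -
          eval_background(mono[[i]], ci, shapes[[i]])
      }
    }
  }

  # feathering weights: separable raised-cosine ramps at tile borders
  acc <- array(0, dd); wacc <- array(0, dd)
  for (i in seq_len(nt)) {
    sh <- shapes[[i]]
    if (method == "spectral" && nt > 1) {
      wt <- lapply(1:3, function(a) {
        n <- sh[a]
        ramp <- min(max(4L, n %/% 4L), n %/% 2L)
        w <- rep(1, n)
        t <- seq_len(ramp) / (ramp + 1)
        w[seq_len(ramp)] <- sin(pi / 2 * t)^2
        w[n + 1 - seq_len(ramp)] <- sin(pi / 2 * t)^2
        w
      })
      W <- array(rep(wt[[1]], times = sh[2] * sh[3]), sh) *
        array(rep(rep(wt[[2]], each = sh[1]), times = sh[3]), sh) *
        array(rep(wt[[3]], each = sh[1] * sh[2]), sh)
    } else {
      W <- array(1, sh)
    }
    s <- offsets[i, ] - lo
    xi <- (s[1] + 1):(s[1] + sh[1]); yi <- (s[2] + 1):(s[2] + sh[2])
    zi <- (s[3] + 1):(s[3] + sh[3])
    acc[xi, yi, zi] <- acc[xi, yi, zi] + data_arr[[i]] * W
    wacc[xi, yi, zi] <- wacc[xi, yi, zi] + W
  }
  if (any(wacc == 0)) {
    holes <- which(wacc == 0, arr.ind = TRUE)
    rng <- apply(holes, 2, range)
    stop(sprintf(
      "tile layout leaves gaps in coverage, e.g. box [%d..%d, %d..%d, %d..%d]",
      rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  voxel_grid(acc / wacc, vsz, origin = lo)
}

#' Resample a coarse overview grid onto a finer grid
#'
#' Trilinear interpolation used when blending overview tiles with
#' high-resolution tiles.
#'
#' @param grid a [voxel_grid].
#' @param target_voxel_size_um desired spacing (must be finer or equal).
#' @return A [voxel_grid] at the target spacing covering the same extent.
#' @export
resample_trilinear <- function(grid, target_voxel_size_um) {
  stopifnot(inherits(grid, "voxel_grid"),
            target_voxel_size_um <= grid$voxel_size_um)
  f <- grid$voxel_size_um / target_voxel_size_um
  d <- dim(grid$data)
  nd <- pmax(2L, as.integer(round((d - 1) * f)) + 1L)
  pos <- lapply(1:3, function(a) {
    p <- seq(0, d[a] - 1, length.out = nd[a])
    pmin(p, d[a] - 1 - 1e-9)
  })
  lo <- lapply(pos, function(p) floor(p))
  fr <- Map(function(p, l) p - l, pos, lo)
  l1 <- lapply(1:3, function(a) pmin(lo[[a]] + 1, d[a] - 1))
  g <- grid$data
  idx <- function(ax, ay, az) {
    g[cbind(rep(ax + 1, times = nd[2] * nd[3]),
            rep(rep(ay + 1, each = nd[1]), times = nd[3]),
            rep(az + 1, each = nd[1] * nd[2]))]
  }
  fx <- rep(fr[[1]], times = nd[2] * nd[3])
  fy <- rep(rep(fr[[2]], each = nd[1]), times = nd[3])
  fz <- rep(fr[[3]], each = nd[1] * nd[2])
  v000 <- idx(lo[[1]], lo[[2]], lo[[3]]); v100 <- idx(l1[[1]], lo[[2]], lo[[3]])
  v010 <- idx(lo[[1]], l1[[2]], lo[[3]]); v110 <- idx(l1[[1]], l1[[2]], lo[[3]])
  v001 <- idx(lo[[1]], lo[[2]], l1[[3]]); v101 <- idx(l1[[1]], lo[[2]], l1[[3]])
  v011 <- idx(lo[[1]], l1[[2]], l1[[3]]); v111 <- idx(l1[[1]], l1[[2]], l1[[3]])
  out <- (1 - fx) * (1 - fy) * (1 - fz) * v000 + fx * (1 - fy) * (1 - fz) * v100 +
    (1 - fx) * fy * (1 - fz) * v010 + fx * fy * (1 - fz) * v110 +
    (1 - fx) * (1 - fy) * fz * v001 + fx * (1 - fy) * fz * v101 +
    (1 - fx) * fy * fz * v011 + fx * fy * fz * v111
  voxel_grid(array(out, nd), target_voxel_size_um, grid$origin)
}
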