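# Brute-force oracles, written as plain loops independent of the package's
# vectorized builders.

# All 2D (8-neighborhood) or 3D (26-neighborhood) integer offsets, full set.
all_offsets <- function(ndim) {
  grid <- do.call(expand.grid, rep(list(-1:1), ndim))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# half set matching the package's direction convention
half_offsets <- function(ndim) {
  Filter(function(v) v[v != 0][1] > 0, all_offsets(ndim))
}

in_bounds <- function(ix, d) all(ix >= 1) && all(ix <= d)

# symmetric GLCM counts by exhaustive pair enumeration; lev has NA outside ROI
bf_glcm <- function(lev, directions, n_levels, distance = 1L) {
  d <- dim(lev)
  counts <- matrix(0, n_levels, n_levels)
  coords <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    ix <- coords[r, ]
    a <- lev[matrix(ix, 1)]
    for (dir in directions) {
      jx <- ix + dir * distance
      if (!in_bounds(jx, d)) next
      b <- lev[matrix(jx, 1)]
      if (is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
    }
  }
  counts
}

# run-length matrix by scanning every line in direction `dir`
bf_glrlm <- function(lev, dir, n_levels) {
  d <- dim(lev)
  maxlen <- max(d)
  R <- matrix(0, n_levels, maxlen)
  starts <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(starts))) {
    ix <- starts[r, ]
    prev <- ix - dir
    # only start a run where the predecessor breaks it
    if (in_bounds(prev, d)) {
      pv <- lev[matrix(prev, 1)]
      if (!is.na(pv) && pv == lev[matrix(ix, 1)]) next
    }
    v <- lev[matrix(ix, 1)]
    len <- 1
    nxt <- ix + dir
    while (in_bounds(nxt, d)) {
      nv <- lev[matrix(nxt, 1)]
      if (is.na(nv) || nv != v) break
      len <- len + 1
      nxt <- nxt + dir
    }
    R[v + 1, len] <- R[v + 1, len] + 1
  }
  R
}

# connected equal-level zones by stack-based flood fill (8/26-connectivity)
bf_zones <- function(lev) {
  d <- dim(lev)
  offs <- all_offsets(length(d))
  seen <- array(FALSE, d)
  zones <- list()
  coords <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    ix <- coords[r, ]
    if (seen[matrix(ix, 1)]) next
    v <- lev[matrix(ix, 1)]
    stack <- list(ix)
    seen[matrix(ix, 1)] <- TRUE
    size <- 0
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (off in offs) {
        nb <- cur + off
        if (!in_bounds(nb, d)) next
        if (seen[matrix(nb, 1)]) next
        nv <- lev[matrix(nb, 1)]
        if (is.na(nv) || nv != v) next
        seen[matrix(nb, 1)] <- TRUE
        stack[[length(stack) + 1]] <- nb
      }
    }
    zones[[length(zones) + 1]] <- c(level = v, size = size)
  }
  do.call(rbind, zones)
}

# NGTDM n_i / s_i over strict-interior voxels
bf_ngtdm <- function(lev, n_levels) {
  d <- dim(lev)
  offs <- all_offsets(length(d))
  n_i <- numeric(n_levels); s_i <- numeric(n_levels)
  n_valid <- 0
  coords <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    ix <- coords[r, ]
    nb <- numeric(0)
    ok <- TRUE
    for (off in offs) {
      jx <- ix + off
      if (!in_bounds(jx, d) || is.na(lev[matrix(jx, 1)])) { ok <- FALSE; break }
      nb <- c(nb, lev[matrix(jx, 1)])
    }
    if (!ok) next
    v <- lev[matrix(ix, 1)]
    n_valid <- n_valid + 1
    n_i[v + 1] <- n_i[v + 1] + 1
    s_i[v + 1] <- s_i[v + 1] + abs(v - mean(nb))
  }
  list(n = n_i, s = s_i, n_valid = n_valid)
}

# GLGCM joint histogram by direct convolution + binning, mirroring the
# definition: bounding-box crop, background level 0, Sobel on interior
# pixels, gradient quantized to 16 bins over [0, max].
bf_glgcm_hist <- function(lev_full, mask, n_levels, nbins = 16L) {
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  img <- lev_full[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  msk <- mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  img[!msk] <- 0
  d <- dim(img)
  if (any(d < 3)) return(matrix(0, n_levels, nbins))
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # [di, dj]
  sy <- t(sx)
  g <- matrix(NA_real_, d[1], d[2])
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) {
    gx <- 0; gy <- 0
    for (a in -1:1) for (b in -1:1) {
      gx <- gx + sx[a + 2, b + 2] * img[i + a, j + b]
      gy <- gy + sy[a + 2, b + 2] * img[i + a, j + b]
    }
    g[i, j] <- sqrt(gx^2 + gy^2)
  }
  gin <- g[2:(d[1] - 1), 2:(d[2] - 1)]
  lin <- img[2:(d[1] - 1), 2:(d[2] - 1)]
  gmax <- max(gin)
  H <- matrix(0, n_levels, nbins)
  for (i in seq_along(gin)) {
    gb <- if (gmax > 0) min(floor(nbins * gin[i] / gmax), nbins - 1) else 0
    H[lin[i] + 1, gb + 1] <- H[lin[i] + 1, gb + 1] + 1
  }
  H
}

# AUC by explicit pair counting
bf_auc <- function(scores, positive) {
  x <- scores[positive]; y <- scores[!positive]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# third/fourth standardized moments by definition
bf_moments <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  list(mean = m, var = m2,
       skew = (sum((x - m)^3) / length(x)) / m2^1.5,
       kurt = (sum((x - m)^4) / length(x)) / m2^2)
}

random_roi <- function(d, n_levels, seed, na_frac = 0) {
  withr::with_seed(seed, {
    lev <- array(sample(0:(n_levels - 1), prod(d), replace = TRUE), d)
    if (na_frac > 0) {
      drop <- sample(prod(d), round(na_frac * prod(d)))
      lev[drop] <- NA_integer_
    }
    lev
  })
}

# small deterministic sphere mask
sphere_mask <- function(r_vox, pad = 2L) {
  n <- 2 * (r_vox + pad) + 1
  ax <- seq_len(n) - (r_vox + pad + 1)
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  d2 <= r_vox^2
}

# synthetic feature table with planted class effects (features directly,
# no images): n1 positives, n0 negatives, `effect` in sd units on the first
# `n_inform` columns, `n_noise` pure-noise columns.
planted_feature_table <- function(n1, n0, n_inform, n_noise, effect, seed) {
  withr::with_seed(seed, {
    n <- n1 + n0
    y <- rep(c(TRUE, FALSE), c(n1, n0))
    x <- matrix(rnorm(n * (n_inform + n_noise)), n)
    for (j in seq_len(n_inform)) x[y, j] <- x[y, j] + effect
    colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
    list(table = data.frame(case_id = sprintf("c%02d", 1:n), x), y = y)
  })
}

small_cohort_spec <- function(n1 = 3, n0 = 2, seed = 11, perturb = 1) {
  cohort_spec(n_responders = n1, n_nonresponders = n0,
              volume_shape = c(32, 32, 14), voxel_spacing = c(0.97, 0.97, 2.5),
              tumor_radius_range = c(5, 8),
              contour_perturbation_mm = perturb, seed = seed)
}
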