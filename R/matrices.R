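# Gray-level matrix builders: GLCM, GLRLM, GLSZM, NGTDM.
# All operate on a `quantized_roi` (levels array with NA outside the ROI).
# Level indices are 1-based gray values i = level + 1 inside feature
# formulas, so low-gray-level emphases never divide by zero.

# Unique direction vectors covering half the neighborhood (symmetric pairs
# are accumulated by the builders themselves).
directions_2d <- function() list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))

directions_3d <- function() {
  dirs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    # keep one of each +/- pair: first nonzero component positive
    nz <- v[v != 0][1]
    if (nz > 0) dirs[[length(dirs) + 1]] <- v
  }
  dirs  # 13 directions
}

roi_directions <- function(roi) {
  if (roi$dimensionality == "2D") directions_2d() else directions_3d()
}

# Shift an array's index grid by `off`; returns the paired (source, target)
# linear indices that both remain inside the array bounds.
shifted_pairs <- function(d, off) {
  rng <- lapply(seq_along(d), function(ax) {
    o <- off[ax]
    src <- if (o >= 0) seq_len(d[ax] - o) else seq(1 - o, d[ax])
    src
  })
  src_idx <- as.matrix(expand.grid(rng))
  dst_idx <- sweep(src_idx, 2, off, `+`)
  mult <- cumprod(c(1, d[-length(d)]))
  list(src = as.vector((src_idx - 1) %*% mult) + 1,
       dst = as.vector((dst_idx - 1) %*% mult) + 1)
}

#' Build a gray-level co-occurrence matrix
#'
#' Symmetric co-occurrence counts of level pairs at the given voxel distance,
#' accumulated over all directions (4 in 2D, 13 in 3D, each counted in both
#' orientations).
#'
#' @param roi A [quantize_gray_levels()] result.
#' @param distance Offset length in voxels (default 1).
#' @param directions List of offset vectors (default: the full 4/13
#'   direction set for the ROI's dimensionality).
#' @return A `gray_level_matrix` with `kind = "GLCM"`, integer `counts`
#'   (n_levels x n_levels) and normalized `p`.
#' @export
glcm_matrix <- function(roi, distance = 1L, directions = roi_directions(roi)) {
  lev <- roi$levels
  d <- dim(lev)
  n <- roi$n_levels
  counts <- matrix(0, n, n)
  for (dir in directions) {
    sp <- shifted_pairs(d, dir * distance)
    a <- lev[sp$src]; b <- lev[sp$dst]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    code <- a[ok] * n + b[ok]           # 0-based (a,b) code
    tab <- tabulate(code + 1L, n * n)
    m <- matrix(tab, n, n, byrow = TRUE) # row = a, col = b
    counts <- counts + m + t(m)          # symmetric accumulation
  }
  total <- sum(counts)
  structure(list(kind = "GLCM", counts = counts, n_levels = n,
                 p = if (total > 0) counts / total else counts),
            class = "gray_level_matrix")
}

#' Build a gray-level run-length matrix for one direction
#'
#' Counts maximal runs of equal level along lines of the given direction;
#' rows index gray level, columns run length.
#'
#' @param roi A quantized ROI.
#' @param direction Integer offset vector (components in -1..1).
#' @return A `gray_level_matrix` with `kind = "GLRLM"`.
#' @export
glrlm_matrix <- function(roi, direction) {
  lev <- roi$levels
  d <- dim(lev)
  idx <- which(!is.na(lev), arr.ind = TRUE)
  if (is.vector(idx)) idx <- matrix(idx, ncol = length(d))
  vals <- lev[!is.na(lev)]
  ax <- which(direction != 0)[1]
  s <- idx[, ax] * direction[ax]                  # position along the line
  line <- idx - outer(s, direction)               # line anchor coordinates
  base <- 4 * max(d) + 4  # line coords lie in [1 - max(d), 2 max(d)]
  key <- as.vector((line + max(d)) %*% cumprod(c(1, rep(base, ncol(line) - 1))))
  o <- order(key, s)
  key <- key[o]; s <- s[o]; v <- vals[o]
  n <- length(v)
  maxlen <- max(d)
  R <- matrix(0, roi$n_levels, maxlen)
  if (n > 0) {
    newrun <- c(TRUE, key[-1] != key[-n] | s[-1] != s[-n] + 1 | v[-1] != v[-n])
    starts <- which(newrun)
    lens <- diff(c(starts, n + 1L))
    lv <- v[starts] + 1L
    for (r in seq_along(starts)) R[lv[r], lens[r]] <- R[lv[r], lens[r]] + 1
  }
  structure(list(kind = "GLRLM", counts = R, n_levels = roi$n_levels,
                 n_pixels = n),
            class = "gray_level_matrix")
}

# Connected components of equal-level voxels (8-connectivity in 2D,
# 26-connectivity in 3D). Returns a data.frame of zone (level, size).
label_zones <- function(roi) {
  lev <- roi$levels
  d <- dim(lev)
  in_roi <- which(!is.na(lev))
  n <- length(in_roi)
  rank <- integer(length(lev)); rank[in_roi] <- seq_len(n)
  edges <- vector("list", 0)
  for (dir in roi_directions(roi)) {
    sp <- shifted_pairs(d, dir)
    a <- lev[sp$src]; b <- lev[sp$dst]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (any(ok))
      edges[[length(edges) + 1]] <- cbind(rank[sp$src[ok]], rank[sp$dst[ok]])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  data.frame(level = lev[in_roi][match(seq_len(comp$no), comp$membership)],
             size = as.integer(comp$csize))
}

#' Build a gray-level size zone matrix
#'
#' Zones are connected components of equal gray level (8-connectivity in 2D,
#' 26 in 3D); rows index gray level, columns zone size.
#'
#' @param roi A quantized ROI.
#' @return A `gray_level_matrix` with `kind = "GLSZM"`.
#' @export
glszm_matrix <- function(roi) {
  zones <- label_zones(roi)
  n_pix <- sum(!is.na(roi$levels))
  maxsz <- max(zones$size)
  Z <- matrix(0, roi$n_levels, maxsz)
  for (r in seq_len(nrow(zones)))
    Z[zones$level[r] + 1L, zones$size[r]] <- Z[zones$level[r] + 1L, zones$size[r]] + 1
  structure(list(kind = "GLSZM", counts = Z, n_levels = roi$n_levels,
                 n_pixels = n_pix),
            class = "gray_level_matrix")
}

#' Build a neighborhood gray-tone difference matrix
#'
#' For voxels whose full neighborhood (8 in 2D, 26 in 3D) lies inside the
#' ROI, accumulates per-level occupancy `n_i` and the summed absolute
#' difference `s_i` between each voxel's level and its neighborhood mean.
#'
#' @param roi A quantized ROI.
#' @return List with `n` (per-level counts), `s` (per-level difference sums),
#'   `n_valid` (number of interior voxels) and `n_levels`.
#' @export
ngtdm_matrix <- function(roi) {
  lev <- roi$levels
  d <- dim(lev)
  nb_sum <- array(0, d)
  nb_cnt <- array(0L, d)
  dirs <- roi_directions(roi)
  for (dir in dirs) for (sgn in c(1, -1)) {
    sp <- shifted_pairs(d, dir * sgn)
    v <- lev[sp$dst]
    ok <- !is.na(v)
    nb_sum[sp$src[ok]] <- nb_sum[sp$src[ok]] + v[ok]
    nb_cnt[sp$src[ok]] <- nb_cnt[sp$src[ok]] + 1L
  }
  full <- 2L * length(dirs)
  valid <- !is.na(lev) & nb_cnt == full
  nL <- roi$n_levels
  n_i <- numeric(nL); s_i <- numeric(nL)
  if (any(valid)) {
    lv <- lev[valid] + 1L
    dif <- abs(lev[valid] - nb_sum[valid] / full)
    n_i <- tabulate(lv, nL)
    for (l in unique(lv)) s_i[l] <- sum(dif[lv == l])
  }
  list(kind = "NGTDM", n = n_i, s = s_i, n_valid = sum(valid), n_levels = nL)
}
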