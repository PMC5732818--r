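# Shape features: tumor volume, longest 3D diameter, solidity, eccentricity.

# --- 3D convex hull (beneath-beyond incremental construction) -------------
# Returns hull volume; 0 for degenerate (coplanar/collinear) point sets.
# Points are reduced beforehand by the caller; complexity is O(n * facets).
convex_hull_volume <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4) return(0)
  # initial simplex: extreme points along coordinate axes + farthest pair
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  if (i1 == i2) return(0)
  d12 <- pts[i2, ] - pts[i1, ]
  # farthest from the line i1-i2
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
              rel[, 3] * d12[1] - rel[, 1] * d12[3],
              rel[, 1] * d12[2] - rel[, 2] * d12[1])
  dline <- rowSums(cr^2)
  i3 <- which.max(dline)
  if (dline[i3] < 1e-18) return(0)
  nrm <- crossp(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dplane <- abs(rel %*% nrm)
  i4 <- which.max(dplane)
  if (dplane[i4] < 1e-12) return(0)

  V <- rbind(pts[i1, ], pts[i2, ], pts[i3, ], pts[i4, ])
  centroid <- colMeans(V)
  facets <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  verts <- V
  orient_facet <- function(f) {
    nn <- crossp(verts[f[2], ] - verts[f[1], ], verts[f[3], ] - verts[f[1], ])
    if (sum(nn * (centroid - verts[f[1], ])) > 0) f <- f[c(1, 3, 2)]
    f
  }
  facets <- lapply(facets, orient_facet)
  facet_norm <- function(f) {
    nn <- crossp(verts[f[2], ] - verts[f[1], ], verts[f[3], ] - verts[f[1], ])
    list(n = nn, off = sum(nn * verts[f[1], ]))
  }
  geom <- lapply(facets, facet_norm)

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (pi in rest) {
    p <- pts[pi, ]
    Nm <- do.call(rbind, lapply(geom, `[[`, "n"))
    off <- vapply(geom, `[[`, numeric(1), "off")
    vis <- as.vector(Nm %*% p) > off + 1e-9 * (1 + abs(off))
    if (!any(vis)) next
    # horizon: edges of visible facets not shared with another visible facet
    edge_key <- function(a, b) paste(min(a, b), max(a, b))
    tabs <- new.env(parent = emptyenv())
    for (fi in which(vis)) {
      f <- facets[[fi]]
      for (e in list(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])) {
        k <- edge_key(e[1], e[2])
        tabs[[k]] <- if (is.null(tabs[[k]])) list(e) else c(tabs[[k]], list(e))
      }
    }
    horizon <- list()
    for (k in ls(tabs)) if (length(tabs[[k]]) == 1) horizon <- c(horizon, tabs[[k]])
    verts <- rbind(verts, p)
    pv <- nrow(verts)
    facets <- facets[!vis]
    geom <- geom[!vis]
    for (e in horizon) {
      f <- orient_facet(c(e[1], e[2], pv))
      facets[[length(facets) + 1]] <- f
      geom[[length(geom) + 1]] <- facet_norm(f)
    }
  }
  vol <- 0
  for (f in facets) {
    a <- verts[f[1], ] - centroid; b <- verts[f[2], ] - centroid
    cc <- verts[f[3], ] - centroid
    vol <- vol + abs(sum(crossp(a, b) * cc)) / 6
  }
  vol
}

crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Candidate hull points of a voxel mask: per-axial-slice 2D hull vertices of
# voxel centers (pooling slice hulls is exact for the full point cloud).
hull_candidate_points <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx - 0.5, 2, spacing, `*`)
  keep <- unlist(lapply(split(seq_len(nrow(pts)), idx[, 3]), function(rows) {
    if (length(rows) <= 3) return(rows)
    rows[grDevices::chull(pts[rows, 1], pts[rows, 2])]
  }))
  pts[keep, , drop = FALSE]
}

#' Shape features of a 3D tumor mask
#'
#' `volume` is voxel count times voxel volume (mm^3); `size` is the longest
#' 3D diameter, the maximum pairwise distance between in-mask voxel centers
#' (mm); `solidity` is mask volume over convex-hull volume (capped at 1;
#' defined as 1 for degenerate hulls); `eccentricity` is
#' `sqrt(1 - minor/major)` in terms of the principal-axis variances of the
#' voxel point cloud, i.e. `sqrt(1 - (minor_axis/major_axis)^2)` for the
#' fitted ellipsoid.
#'
#' @param mask Logical 3D array, nonempty.
#' @param spacing Voxel spacing (mm).
#' @return Named numeric vector: `volume`, `size`, `solidity`,
#'   `eccentricity`.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim(mask))
  nvox <- sum(mask)
  if (nvox == 0) stopf("shape features need a nonempty mask")
  vol <- nvox * prod(spacing)
  if (nvox == 1)
    return(c(volume = vol, size = 0, solidity = 1, eccentricity = 0))
  pts <- hull_candidate_points(mask, spacing)
  size <- max(stats::dist(pts))
  hull_vol <- convex_hull_volume(pts)
  solidity <- if (hull_vol > 0) min(1, vol / hull_vol) else 1
  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx - 0.5, 2, spacing, `*`)
  ev <- eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ecc <- if (ev[1] > 0) sqrt(1 - ev[3] / ev[1]) else 0
  c(volume = vol, size = size, solidity = solidity, eccentricity = ecc)
}
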