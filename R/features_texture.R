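# Gray-level texture matrices (GLCM, GLRLM, GLSZM, GLDM) and their features.
#
# All matrices are computed on a discretized level image (see discretize()),
# restricted to in-mask voxels; counts involving out-of-mask neighbors are
# simply dropped. Levels are 1..L.

# The 13 unique 3D offsets at Chebyshev distance 1 (one per direction pair).
offsets_3d <- function() {
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    o <- c(dx, dy, dz)
    if (all(o == 0)) next
    if (any(vapply(offs, function(p) all(p == -o), logical(1)))) next
    offs[[length(offs) + 1L]] <- o
  }
  offs
}

# Co-occurrence counts for one offset on a 2D or 3D level image.
glcm_matrix_single <- function(levels, mask, offset, n_levels,
                               symmetric = TRUE) {
  d <- dim(levels)
  if (length(d) == 2L) { d <- c(d, 1L); offset <- c(offset, 0L) }
  lv <- array(levels, dim = d)
  mk <- array(mask, dim = d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  vx <- xs[xs + offset[1] >= 1 & xs + offset[1] <= d[1]]
  vy <- ys[ys + offset[2] >= 1 & ys + offset[2] <= d[2]]
  vz <- zs[zs + offset[3] >= 1 & zs + offset[3] <= d[3]]
  if (!length(vx) || !length(vy) || !length(vz)) {
    return(matrix(0, n_levels, n_levels))
  }
  a <- lv[vx, vy, vz, drop = FALSE]
  b <- lv[vx + offset[1], vy + offset[2], vz + offset[3], drop = FALSE]
  ok <- mk[vx, vy, vz, drop = FALSE] &
        mk[vx + offset[1], vy + offset[2], vz + offset[3], drop = FALSE]
  a <- a[ok]; b <- b[ok]
  P <- matrix(0, n_levels, n_levels)
  if (length(a)) {
    tab <- table(factor(a, levels = seq_len(n_levels)),
                 factor(b, levels = seq_len(n_levels)))
    P <- P + unclass(tab)
  }
  if (symmetric) P <- P + t(P)
  dimnames(P) <- NULL
  P
}

#' Gray-level co-occurrence matrix features
#'
#' Builds one symmetric co-occurrence matrix per offset (default: the 13
#' unique 3D direction pairs at distance 1), normalizes each to a joint
#' probability, computes contrast, correlation, joint energy, joint entropy
#' and homogeneity (inverse difference moment), and averages the features
#' over offsets.
#'
#' @param levels integer level image from [discretize()].
#' @param mask logical array; needs at least one in-mask voxel pair.
#' @param offsets list of integer offset vectors; default [offsets_3d()]
#'   (or the right-neighbor offset for 2D input).
#' @param symmetric add the transposed counts (default TRUE).
#' @return named numeric vector of GLCM features.
#' @export
glcm_features <- function(levels, mask, offsets = NULL, symmetric = TRUE) {
  n_levels <- attr(levels, "n_levels")
  if (is.null(n_levels)) n_levels <- max(levels[mask], na.rm = TRUE)
  if (is.null(offsets)) {
    offsets <- if (length(dim(levels)) == 2L) list(c(0L, 1L)) else offsets_3d()
  }
  per_off <- lapply(offsets, function(off) {
    P <- glcm_matrix_single(levels, mask, off, n_levels, symmetric)
    tot <- sum(P)
    if (tot == 0) return(NULL)
    glcm_features_from_matrix(P / tot)
  })
  per_off <- per_off[!vapply(per_off, is.null, logical(1))]
  if (!length(per_off)) stop("no co-occurring in-mask pairs", call. = FALSE)
  colMeans(do.call(rbind, per_off))
}

# Features from one probability-normalized co-occurrence matrix.
glcm_features_from_matrix <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  } else 1
  pnz <- P[P > 0]
  c(contrast = sum((i - j)^2 * P),
    correlation = corr,
    joint_energy = sum(P^2),
    joint_entropy = -sum(pnz * log2(pnz)),
    homogeneity = sum(P / (1 + (i - j)^2)))
}

# Enumerate maximal runs along one direction; returns counts matrix
# (level x run length). Out-of-mask voxels break runs.
glrlm_matrix_single <- function(levels, mask, direction) {
  d <- dim(levels)
  if (length(d) == 2L) { d <- c(d, 1L); direction <- c(direction, 0L) }
  lv <- array(levels, dim = d)
  mk <- array(mask, dim = d)
  n_levels <- max(lv[mk], na.rm = TRUE)
  max_len <- max(d)
  M <- matrix(0, n_levels, max_len)
  # run start voxels: in-mask voxels whose predecessor along `direction` is
  # out of bounds, out of mask, or a different level
  coords <- which(mk, arr.ind = TRUE)
  if (is.vector(coords)) coords <- matrix(coords, ncol = 3)
  for (r in seq_len(nrow(coords))) {
    p <- coords[r, ]
    q <- p - direction
    inside <- all(q >= 1) && all(q <= d)
    if (inside && mk[q[1], q[2], q[3]] &&
        lv[q[1], q[2], q[3]] == lv[p[1], p[2], p[3]]) next  # not a run start
    len <- 1L
    g <- lv[p[1], p[2], p[3]]
    nxt <- p + direction
    while (all(nxt >= 1) && all(nxt <= d) && mk[nxt[1], nxt[2], nxt[3]] &&
           lv[nxt[1], nxt[2], nxt[3]] == g) {
      len <- len + 1L
      nxt <- nxt + direction
    }
    M[g, len] <- M[g, len] + 1
  }
  # trim trailing all-zero run lengths only (interior zeros must stay so
  # column index == run length)
  last <- max(c(1L, which(colSums(M) > 0)))
  M[, seq_len(last), drop = FALSE]
}

#' Gray-level run-length matrix features
#'
#' Runs are maximal same-level voxel sequences along each of the 13 unique
#' 3D directions (or the horizontal direction for 2D input); features are
#' averaged over directions: short/long-run emphasis, gray-level and
#' run-length non-uniformity, and run percentage.
#'
#' @inheritParams glcm_features
#' @param directions list of direction vectors; default [offsets_3d()].
#' @return named numeric vector of GLRLM features.
#' @export
glrlm_features <- function(levels, mask, directions = NULL) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (is.null(directions)) {
    directions <- if (length(dim(levels)) == 2L) list(c(0L, 1L)) else offsets_3d()
  }
  n_vox <- sum(mask)
  feats <- lapply(directions, function(dir) {
    M <- glrlm_matrix_single(levels, mask, dir)
    glrlm_features_from_matrix(M, n_vox)
  })
  colMeans(do.call(rbind, feats))
}

glrlm_features_from_matrix <- function(M, n_vox) {
  Nr <- sum(M)
  jl <- col(M)
  c(short_run_emphasis = sum(M / jl^2) / Nr,
    long_run_emphasis = sum(M * jl^2) / Nr,
    gray_level_nonuniformity = sum(rowSums(M)^2) / Nr,
    run_length_nonuniformity = sum(colSums(M)^2) / Nr,
    run_percentage = Nr / n_vox)
}

# 26-connected components of one gray level inside the mask (BFS on voxel
# indices; masks here are small ROIs).
connected_zones <- function(levels, mask, level) {
  d <- dim(levels)
  if (length(d) == 2L) d <- c(d, 1L)
  lv <- array(levels, dim = d)
  mk <- array(mask, dim = d) & !is.na(lv) & lv == level
  sizes <- integer(0)
  seen <- array(FALSE, dim = d)
  idx <- which(mk)
  if (!length(idx)) return(sizes)
  coord <- arrayInd(idx, d)
  key <- function(p) (p[3] - 1L) * d[1] * d[2] + (p[2] - 1L) * d[1] + p[1]
  in_set <- array(FALSE, dim = d)
  in_set[idx] <- TRUE
  for (start in seq_along(idx)) {
    if (seen[idx[start]]) next
    queue <- list(coord[start, ])
    seen[idx[start]] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1L
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (any(q < 1) || any(q > d)) next
        k <- key(q)
        if (in_set[k] && !seen[k]) {
          seen[k] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal level; the matrix counts
#' zones by (level, size). Features: small/large-area emphasis, gray-level
#' and zone-size non-uniformity, zone percentage.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of GLSZM features.
#' @export
glszm_features <- function(levels, mask) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  lvls <- sort(unique(levels[mask]))
  zones <- list()
  for (g in lvls) {
    sz <- connected_zones(levels, mask, g)
    if (length(sz)) zones[[as.character(g)]] <- sz
  }
  all_sizes <- unlist(zones)
  Nz <- length(all_sizes)
  n_vox <- sum(mask)
  sre <- sum(1 / all_sizes^2) / Nz
  lre <- sum(all_sizes^2) / Nz
  gln <- sum(vapply(zones, length, integer(1))^2) / Nz
  size_tab <- table(all_sizes)
  szn <- sum(as.numeric(size_tab)^2) / Nz
  c(small_area_emphasis = sre,
    large_area_emphasis = lre,
    gray_level_nonuniformity = gln,
    size_zone_nonuniformity = szn,
    zone_percentage = Nz / n_vox)
}

#' Gray-level dependence matrix features
#'
#' For each in-mask voxel, the dependence count is the number of 26-connected
#' in-mask neighbors whose level differs by at most \code{alpha} (default 0).
#' The matrix counts voxels by (level, dependence count + 1); features:
#' small/large dependence emphasis, gray-level and dependence
#' non-uniformity.
#'
#' @inheritParams glcm_features
#' @param alpha dependence similarity threshold on level difference.
#' @return named numeric vector of GLDM features.
#' @export
gldm_features <- function(levels, mask, alpha = 0L) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  d <- dim(levels)
  if (length(d) == 2L) d <- c(d, 1L)
  lv <- array(levels, dim = d)
  mk <- array(mask, dim = d)
  coords <- which(mk, arr.ind = TRUE)
  if (is.vector(coords)) coords <- matrix(coords, ncol = 3)
  dep <- integer(nrow(coords))
  gl <- integer(nrow(coords))
  for (r in seq_len(nrow(coords))) {
    p <- coords[r, ]
    g <- lv[p[1], p[2], p[3]]
    gl[r] <- g
    cnt <- 0L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1) || any(q > d)) next
      if (mk[q[1], q[2], q[3]] && abs(lv[q[1], q[2], q[3]] - g) <= alpha) {
        cnt <- cnt + 1L
      }
    }
    dep[r] <- cnt + 1L  # dependence count including the voxel itself
  }
  Nd <- length(dep)
  c(small_dependence_emphasis = sum(1 / dep^2) / Nd,
    large_dependence_emphasis = sum(dep^2) / Nd,
    gray_level_nonuniformity = sum(as.numeric(table(gl))^2) / Nd,
    dependence_nonuniformity = sum(as.numeric(table(dep))^2) / Nd,
    dependence_entropy = {
      pr <- as.numeric(table(dep)) / Nd
      -sum(pr * log2(pr))
    })
}
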