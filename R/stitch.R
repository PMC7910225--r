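# Non-rigid pairwise stitching of reconstructed tile volumes.
#
# Conventions: tile i maps local (1-based) voxel coordinates l to world
# coordinates w = origin_i + l, with origin_i in voxels.  The "offset" of a
# pair (A, B) is origin_B - origin_A, so a feature at A-local coordinate lA
# appears at B-local coordinate lB = lA - offset.  Displacement fields store
# the total mapping lB = lA + shift at control points in A's frame.

tileArray <- function(x) if (is(x, "TileVolume")) x@vol else x

#' Coarse rigid alignment of a tile pair by phase correlation
#'
#' Refines the nominal origin offset of two overlapping tiles: the overlap
#' blocks at the nominal offset are phase-correlated, the correlation peak is
#' searched within the given radius (wrap-aware) and refined to sub-voxel
#' precision by separable parabolic interpolation.
#'
#' @param tileA,tileB \linkS4class{TileVolume} or 3-D arrays.
#' @param nominalOffsetVox numeric (3): nominal origin_B - origin_A, voxels.
#' @param searchRadiusVox maximum deviation from the nominal offset.
#' @param minOverlapVox minimum overlap voxel count required.
#' @param scoreThreshold normalized peak height below which the refinement is
#'   flagged low-confidence and the nominal offset kept.
#' @return list: \code{offset} (refined origin_B - origin_A),
#'   \code{score} (normalized correlation peak), \code{low_confidence}.
#' @export
coarsePairwiseShift <- function(tileA, tileB, nominalOffsetVox,
                                searchRadiusVox = 10, minOverlapVox = 1000,
                                scoreThreshold = 0.1) {
  A <- tileArray(tileA); B <- tileArray(tileB)
  off <- round(nominalOffsetVox)
  dA <- dim(A); dB <- dim(B)
  lo <- pmax(1, 1 + off)
  hi <- pmin(dA, dB + off)
  if (any(hi - lo + 1 <= 0) || prod(hi - lo + 1) < minOverlapVox)
    stop("overlap at nominal offset below the minimum voxel count")
  a0 <- A[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  b0 <- B[(lo[1]:hi[1]) - off[1], (lo[2]:hi[2]) - off[2],
          (lo[3]:hi[3]) - off[3], drop = FALSE]
  d <- dim(a0)
  FA <- stats::fft(a0 - mean(a0))
  FB <- stats::fft(b0 - mean(b0))
  X <- FA * Conj(FB)
  R <- X / (Mod(X) + 1e-12 * max(Mod(X)))
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  # restrict the peak search to |shift| <= searchRadius (wrap-aware)
  idx <- lapply(d, function(n) {
    s <- c(0:min(searchRadiusVox, n - 1),
           if (searchRadiusVox > 0) seq(n - 1, max(n - searchRadiusVox, 1)))
    unique(s[s >= 0 & s < n]) + 1
  })
  sub <- r[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  peak <- vapply(1:3, function(k) idx[[k]][pk[k]] - 1, numeric(1))
  disp <- ifelse(peak > sapply(d, function(n) n / 2), peak - d, peak)
  # sub-voxel parabolic refinement per axis on the full wrap-around surface
  val <- max(sub)
  for (k in 1:3) {
    p <- peak
    pm <- p; pm[k] <- (p[k] - 1) %% d[k]
    pp <- p; pp[k] <- (p[k] + 1) %% d[k]
    sm <- r[pm[1] + 1, pm[2] + 1, pm[3] + 1]
    sp <- r[pp[1] + 1, pp[2] + 1, pp[3] + 1]
    den <- sm - 2 * val + sp
    if (den < 0) disp[k] <- disp[k] + 0.5 * (sm - sp) / den
  }
  score <- val # normalized cross-power peak: 1 for a pure shift
  low <- score < scoreThreshold
  # the peak location satisfies b0(x) = a0(x + disp): the blocks agree once
  # B is placed disp voxels further along, so refined offset = nominal + disp
  offset <- if (low) as.numeric(nominalOffsetVox) else
    as.numeric(off) + disp
  if (low) warning("phase-correlation peak below threshold; keeping nominal offset")
  list(offset = offset, score = score, low_confidence = low)
}

#' Local displacement field between two tiles by block matching
#'
#' Places control points on a regular grid over the overlap region (in the
#' reference tile A's frame) and finds, for each, the displacement maximizing
#' normalized cross-correlation of local blocks, searching around the rigid
#' alignment.  Points are valid when the NCC score reaches
#' \code{scoreThreshold} and the non-rigid part of the displacement does not
#' exceed \code{maxDisplacementVox}.
#'
#' @param tileA,tileB tiles (reference and moving).
#' @param rigidOffsetVox refined origin_B - origin_A, voxels.
#' @param gridSpacingVox control point spacing.
#' @param blockRadiusVox matching block radius.
#' @param searchRadiusVox search radius around the rigid alignment.
#' @param scoreThreshold NCC validity threshold.
#' @param maxDisplacementVox maximum allowed non-rigid displacement.
#' @return A \linkS4class{DisplacementField} (shifts are total: lB - lA).
#' @export
blockMatchField <- function(tileA, tileB, rigidOffsetVox,
                            gridSpacingVox = 32, blockRadiusVox = 12,
                            searchRadiusVox = 6, scoreThreshold = 0.5,
                            maxDisplacementVox = 10) {
  A <- tileArray(tileA); B <- tileArray(tileB)
  dA <- dim(A); dB <- dim(B)
  off <- rigidOffsetVox
  rigidShift <- -off                     # lB = lA - offset
  lo <- pmax(1, 1 + ceiling(off))
  hi <- pmin(dA, dB + floor(off))
  if (any(hi - lo + 1 <= 0)) stop("overlap region is empty")
  # control points inset so the matching blocks fit inside both volumes
  br <- blockRadiusVox
  lo2 <- pmax(lo, 1 + br, 1 + br + ceiling(off))
  hi2 <- pmin(hi, dA - br, dB - br + floor(off))
  grids <- lapply(1:3, function(k) {
    if (hi2[k] < lo2[k]) return(round((lo[k] + hi[k]) / 2))
    s <- seq(lo2[k], hi2[k], by = gridSpacingVox)
    if (length(s) == 0) s <- round((lo2[k] + hi2[k]) / 2)
    s
  })
  pts <- as.matrix(expand.grid(x = grids[[1]], y = grids[[2]],
                               z = grids[[3]]))
  res <- ncc_search_cpp(A, B, pts - 1, rigidShift,
                        as.integer(searchRadiusVox),
                        as.integer(blockRadiusVox))
  shifts <- res[, 1:3, drop = FALSE]
  scores <- res[, 4]
  nonrigid <- sweep(shifts, 2, rigidShift)
  valid <- scores >= scoreThreshold &
    sqrt(rowSums(nonrigid^2)) <= maxDisplacementVox
  if (!any(valid))
    warning("no valid control points (block radius may exceed the overlap)")
  if (any(!valid))
    shifts[!valid, ] <- matrix(rigidShift, sum(!valid), 3, byrow = TRUE)
  new("DisplacementField", points = pts, shifts = shifts, valid = valid,
      scores = scores, spacingVox = gridSpacingVox)
}

#' Outlier rejection and smoothing of a displacement field
#'
#' Removes outliers by a per-component median/MAD rule
#' (\code{|d - median| > madK * MAD} invalidates the point), then replaces
#' every control point's shift with a Gaussian-weighted average over the
#' remaining valid points (bandwidth one grid spacing), which fills gaps and
#' bounds the field's gradient.  Constant fields pass through unchanged.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param madK MAD multiplier of the outlier rule.
#' @param bandwidthVox Gaussian bandwidth; default the grid spacing.
#' @param fallbackShift shift used when no point survives (pair flagged with
#'   a warning); defaults to zero (identity field).
#' @return regularized \linkS4class{DisplacementField} (all points valid).
#' @export
filterAndSmoothField <- function(field, madK = 5, bandwidthVox = NULL,
                                 fallbackShift = c(0, 0, 0)) {
  valid <- field@valid
  sh <- field@shifts
  if (any(valid)) {
    for (k in 1:3) {
      v <- sh[valid, k]
      med <- median(v)
      madv <- max(mad(v), 1e-3)  # floor so exact-constant fields still
                                 # reject gross outliers
      valid[valid] <- valid[valid] & (abs(sh[valid, k] - med) <=
                                        madK * madv)
    }
  }
  if (!any(valid)) {
    warning("all control points invalid; returning identity field")
    out <- field
    out@shifts <- matrix(fallbackShift, nrow(sh), 3, byrow = TRUE)
    out@valid <- rep(TRUE, nrow(sh))
    out@scores <- rep(0, nrow(sh))
    return(out)
  }
  if (is.null(bandwidthVox)) bandwidthVox <- field@spacingVox
  sm <- fieldInterp(field@points[valid, , drop = FALSE],
                    sh[valid, , drop = FALSE], field@points, bandwidthVox)
  out <- field
  out@shifts <- sm
  out@valid <- rep(TRUE, nrow(sh))
  out
}

# Gaussian-weighted scattered interpolation of shifts at query points
# (vectorized with chunking to bound memory).
fieldInterp <- function(points, shifts, query, bandwidth) {
  n <- nrow(points)
  if (n == 1) return(matrix(shifts, nrow(query), 3, byrow = TRUE))
  nq <- nrow(query)
  out <- matrix(0, nq, 3)
  p2 <- rowSums(points^2)
  chunk <- max(1L, floor(5e6 / n))
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), p2, "+") - 2 * q %*% t(points)
    W <- exp(-0.5 * pmax(d2, 0) / bandwidth^2)
    rs <- rowSums(W)
    deg <- rs < 1e-12
    if (any(deg)) {
      nearest <- max.col(-d2[deg, , drop = FALSE])
      W[deg, ] <- 0
      W[cbind(which(deg), nearest)] <- 1
      rs[deg] <- 1
    }
    out[s:e, ] <- (W %*% shifts) / rs
  }
  out
}

# Evaluate a (smoothed) field at arbitrary A-frame coordinates: total shift.
fieldShiftAt <- function(field, query, bandwidth = NULL) {
  if (is.null(bandwidth)) bandwidth <- field@spacingVox
  v <- field@valid
  fieldInterp(field@points[v, , drop = FALSE],
              field@shifts[v, , drop = FALSE], query, bandwidth)
}

# Dense-query variant: evaluates the Gaussian interpolation on a coarse
# lattice over the query bounding box and resamples trilinearly.
fieldShiftDense <- function(field, query, latticeStep = 4, bandwidth = NULL) {
  lo <- floor(apply(query, 2, min)) - latticeStep
  hi <- ceiling(apply(query, 2, max)) + latticeStep
  axes <- lapply(1:3, function(k) seq(lo[k], hi[k], by = latticeStep))
  nl <- vapply(axes, length, integer(1))
  nodes <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  sh <- fieldShiftAt(field, nodes, bandwidth)
  out <- matrix(0, nrow(query), 3)
  for (k in 1:3) {
    comp <- array(sh[, k], nl)
    out[, k] <- sample_trilinear_cpp(
      comp, (query[, 1] - lo[1]) / latticeStep,
      (query[, 2] - lo[2]) / latticeStep,
      (query[, 3] - lo[3]) / latticeStep, 0)
  }
  out
}

#' Globally consistent tile origins from pairwise offsets
#'
#' Weighted least squares: minimizes
#' \code{sum conf_ab * |origin_b - origin_a - offset_ab|^2} with the first
#' tile (lowest index in the first connected component) anchored at its
#' nominal origin; disconnected components are anchored at their nominal
#' positions with a warning.
#'
#' @param pairs data.frame with columns \code{a}, \code{b} (1-based tile
#'   indices), \code{dx}, \code{dy}, \code{dz} (measured origin_b - origin_a)
#'   and \code{confidence}.
#' @param nominalOrigins n x 3 matrix of nominal origins (voxels).
#' @return n x 3 matrix of refined origins.
#' @export
globallyPositionTiles <- function(pairs, nominalOrigins) {
  n <- nrow(nominalOrigins)
  origins <- nominalOrigins
  if (n == 1 || nrow(pairs) == 0) return(origins)
  # connected components of the measurement graph
  compId <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$a[r]; b <- pairs$b[r]
      m <- min(compId[a], compId[b])
      if (compId[a] != m || compId[b] != m) {
        compId[compId == compId[a] | compId == compId[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(compId)) > 1)
    warning("tile adjacency graph disconnected; anchoring each component")
  offs <- as.matrix(pairs[, c("dx", "dy", "dz")])
  for (cid in unique(compId)) {
    tilesIn <- which(compId == cid)
    if (length(tilesIn) == 1) next
    anchor <- tilesIn[1]
    sel <- pairs$a %in% tilesIn & pairs$b %in% tilesIn
    pr <- pairs[sel, , drop = FALSE]
    po <- offs[sel, , drop = FALSE]
    free <- setdiff(tilesIn, anchor)
    idx <- match(free, free)
    M <- matrix(0, nrow(pr), length(free))
    for (r in seq_len(nrow(pr))) {
      if (pr$a[r] != anchor) M[r, match(pr$a[r], free)] <- -1
      if (pr$b[r] != anchor) M[r, match(pr$b[r], free)] <- 1
    }
    W <- sqrt(pmax(pr$confidence, 1e-6))
    for (k in 1:3) {
      rhs <- po[, k] -
        ifelse(pr$a == anchor, -nominalOrigins[anchor, k], 0) -
        ifelse(pr$b == anchor, nominalOrigins[anchor, k], 0)
      sol <- qr.solve(M * W, rhs * W)
      origins[free, k] <- sol
    }
  }
  origins
}

#' Fuse tile volumes into one mosaic with an overlap standard-deviation map
#'
#' Every output voxel is the weight-averaged value of the contributing
#' (optionally warped) tiles, with separable linear ramp weights falling to
#' zero at each tile's borders.  Where two or more tiles contribute, the
#' per-voxel standard deviation of the contributing values (population
#' convention) is recorded in the std map.
#'
#' @param tiles list of \linkS4class{TileVolume} or arrays.
#' @param originsVox n x 3 matrix: world position (voxels, 0-based offset) of
#'   each tile's voxel (1,1,1).
#' @param localCoordFuns optional list of functions; \code{f(w)} maps an
#'   m x 3 matrix of world coordinates to tile-local coordinates (non-rigid
#'   warps).  NULL entries mean rigid placement.
#' @param rampVox ramp width of the blending weights, voxels.
#' @param circularFov if TRUE, each tile's weight also falls to zero at the
#'   edge of its inscribed x-y circle (the valid region of an extended-FOV
#'   reconstruction).
#' @param fill value for voxels covered by no tile.
#' @param voxelSizeUm voxel size recorded in the result.
#' @param originMm world mm position of fused voxel (1,1,1).
#' @param stats extra entries for the result's stats list.
#' @return A \linkS4class{StitchResult}.
#' @export
blendMosaic <- function(tiles, originsVox, localCoordFuns = NULL,
                        rampVox = 8, circularFov = FALSE, fill = 0,
                        voxelSizeUm = 1, originMm = c(0, 0, 0),
                        stats = list()) {
  arrs <- lapply(tiles, tileArray)
  dims <- t(vapply(arrs, dim, integer(3)))
  stopifnot(nrow(originsVox) == length(arrs))
  lo <- floor(apply(originsVox, 2, min))
  hi <- ceiling(apply(originsVox + dims, 2, max))
  D <- as.integer(hi - lo)
  wsum <- array(0, D); vsum <- array(0, D)
  cnt <- array(0L, D); s1 <- array(0, D); s2 <- array(0, D)
  for (i in seq_along(arrs)) {
    o <- originsVox[i, ]
    di <- dims[i, ]
    wl <- pmax(1L, floor(o - lo) + 1L)
    wh <- pmin(D, ceiling(o - lo + di))
    g <- expand.grid(x = wl[1]:wh[1], y = wl[2]:wh[2], z = wl[3]:wh[3])
    w <- as.matrix(g) + matrix(lo, nrow(g), 3, byrow = TRUE)  # world coords
    l <- if (!is.null(localCoordFuns) && !is.null(localCoordFuns[[i]]))
      localCoordFuns[[i]](w) else sweep(w, 2, o)
    vals <- sample_trilinear_cpp(arrs[[i]], l[, 1] - 1, l[, 2] - 1,
                                 l[, 3] - 1, NA_real_)
    # separable linear ramp to zero at tile borders
    wt <- rep(1, nrow(l))
    for (k in 1:3) {
      dedge <- pmin(l[, k] - 0.5, di[k] + 0.5 - l[, k])
      wt <- wt * pmin(1, pmax(0, dedge / rampVox))
    }
    if (circularFov) {
      rr <- sqrt((l[, 1] - (di[1] + 1) / 2)^2 + (l[, 2] - (di[2] + 1) / 2)^2)
      wt <- wt * pmin(1, pmax(0, (min(di[1:2]) / 2 - rr) / rampVox))
    }
    inside <- !is.na(vals) & wt > 0
    fi <- (g$x[inside]) + D[1] * (g$y[inside] - 1L) +
      D[1] * D[2] * (g$z[inside] - 1L)
    vv <- vals[inside]; ww <- wt[inside]
    wsum[fi] <- wsum[fi] + ww
    vsum[fi] <- vsum[fi] + ww * vv
    cnt[fi] <- cnt[fi] + 1L
    s1[fi] <- s1[fi] + vv
    s2[fi] <- s2[fi] + vv^2
  }
  fused <- array(fill, D)
  nz <- wsum > 0
  fused[nz] <- vsum[nz] / wsum[nz]
  stdMap <- array(0, D)
  m2 <- cnt >= 2L
  mu <- s1[m2] / cnt[m2]
  varr <- pmax(s2[m2] / cnt[m2] - mu^2, 0)
  stdMap[m2] <- sqrt(varr)
  new("StitchResult", fused = fused, voxelSizeUm = voxelSizeUm,
      originMm = originMm, stdMap = stdMap, provenance = cnt, stats = stats)
}

#' Artifact statistics from an overlap standard-deviation map
#'
#' Fraction of overlap voxels whose std exceeds the threshold, globally and
#' per axial (z) slice.
#'
#' @param stdMap std map array.
#' @param threshold artifact threshold (> 0), same units as the map.
#' @param overlapMask logical array marking overlap voxels; default: voxels
#'   with positive std-map support (provenance >= 2 when available).
#' @return list: \code{global_fraction}, \code{slice_fractions},
#'   \code{max_slice_fraction}.
#' @export
artifactStatistics <- function(stdMap, threshold, overlapMask = NULL) {
  stopifnot(threshold > 0)
  if (is.null(overlapMask)) overlapMask <- array(TRUE, dim(stdMap))
  nz <- dim(stdMap)[3]
  above <- stdMap > threshold & overlapMask
  denom <- sum(overlapMask)
  slice <- vapply(seq_len(nz), function(z) {
    d <- sum(overlapMask[, , z])
    if (d == 0) 0 else sum(above[, , z]) / d
  }, numeric(1))
  list(global_fraction = if (denom == 0) 0 else sum(above) / denom,
       slice_fractions = slice,
       max_slice_fraction = max(slice))
}

# Does warping by the field reduce the pair's overlap RMS difference
# compared to the rigid alignment?  Validated on a subsample of overlap
# voxels; fields that do not improve the match are discarded.
warpImproves <- function(tileA, tileB, off, field, nSample = 20000,
                         seed = 1) {
  A <- tileArray(tileA); B <- tileArray(tileB)
  dA <- dim(A); dB <- dim(B)
  lo <- pmax(1, 1 + ceiling(off)); hi <- pmin(dA, dB + floor(off))
  if (any(hi - lo < 1)) return(FALSE)
  set.seed(seed)
  pts <- cbind(runif(nSample, lo[1], hi[1]), runif(nSample, lo[2], hi[2]),
               runif(nSample, lo[3], hi[3]))
  va <- sample_trilinear_cpp(A, pts[, 1] - 1, pts[, 2] - 1, pts[, 3] - 1,
                             NA_real_)
  lr <- sweep(pts, 2, off)
  vr <- sample_trilinear_cpp(B, lr[, 1] - 1, lr[, 2] - 1, lr[, 3] - 1,
                             NA_real_)
  lw <- pts + fieldShiftAt(field, pts)
  vw <- sample_trilinear_cpp(B, lw[, 1] - 1, lw[, 2] - 1, lw[, 3] - 1,
                             NA_real_)
  okR <- !is.na(va) & !is.na(vr)
  okW <- !is.na(va) & !is.na(vw)
  if (sum(okR) < 100 || sum(okW) < 100) return(FALSE)
  sqrt(mean((va - vw)^2, na.rm = TRUE)) <
    sqrt(mean((va - vr)^2, na.rm = TRUE))
}

#' Full non-rigid stitching of a tile set
#'
#' Runs the stitching chain: phase-correlation refinement of every adjacent
#' pair's nominal offset, globally consistent positioning, block-matching
#' displacement fields (reference = earlier tile of each pair, since
#' deformation grows with time separation), outlier filtering/smoothing,
#' sequential warp composition in acquisition order, and ramp-weighted
#' fusion.
#'
#' @param tiles list of \linkS4class{TileVolume}.
#' @param nonRigid logical; FALSE fuses with rigid alignment only.
#' @param gridSpacingVox,blockRadiusVox,searchRadiusVox,scoreThreshold,maxDisplacementVox
#'   see \code{\link{blockMatchField}}.
#' @param coarseSearchVox see \code{\link{coarsePairwiseShift}}.
#' @param minWarpVox median non-rigid displacement (voxels) below which a
#'   pair's field is dropped in favour of the rigid alignment: on a static
#'   sample the matched displacements are measurement noise and warping by
#'   them only degrades the fusion.
#' @param rampVox blending ramp width.
#' @param stdThreshold artifact threshold applied to the std map (units of
#'   the reconstructed values); NULL skips artifact statistics.
#' @return A \linkS4class{StitchResult}; \code{stats} carries the pair table,
#'   displacement summaries and artifact statistics.
#' @export
stitchMosaic <- function(tiles, nonRigid = TRUE, gridSpacingVox = 16,
                         blockRadiusVox = 8, searchRadiusVox = 6,
                         scoreThreshold = 0.5, maxDisplacementVox = 10,
                         coarseSearchVox = 8, minWarpVox = 0.5, rampVox = 8,
                         stdThreshold = NULL) {
  n <- length(tiles)
  vox_mm <- tiles[[1]]@voxelSizeUm * 1e-3
  nominal <- t(vapply(tiles, function(t) t@originMm / vox_mm, numeric(3)))
  dims <- t(vapply(tiles, function(t) dim(t@vol), integer(3)))
  times <- vapply(tiles, function(t) t@timestampS, numeric(1))

  # adjacent pairs: nominal boxes overlapping; reference = earlier tile
  pairRows <- list()
  fields <- list()
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b) next
    lo <- pmax(nominal[a, ], nominal[b, ])
    hi <- pmin(nominal[a, ] + dims[a, ], nominal[b, ] + dims[b, ])
    if (any(hi - lo < 2)) next
    e <- if (times[a] <= times[b]) c(a, b) else c(b, a)
    off <- nominal[e[2], ] - nominal[e[1], ]
    cs <- tryCatch(
      coarsePairwiseShift(tiles[[e[1]]], tiles[[e[2]]], off,
                          searchRadiusVox = coarseSearchVox),
      error = function(err) list(offset = off, score = 0,
                                 low_confidence = TRUE))
    pairRows[[length(pairRows) + 1L]] <- data.frame(
      a = e[1], b = e[2], dx = cs$offset[1], dy = cs$offset[2],
      dz = cs$offset[3], confidence = max(cs$score, 1e-3),
      low_confidence = cs$low_confidence)
  }
  pairs <- if (length(pairRows)) do.call(rbind, pairRows) else
    data.frame(a = integer(), b = integer(), dx = numeric(),
               dy = numeric(), dz = numeric(), confidence = numeric(),
               low_confidence = logical())
  origins <- globallyPositionTiles(pairs, nominal)

  localFuns <- vector("list", n)
  fieldList <- list()
  if (nonRigid && nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$a[r]; b <- pairs$b[r]
      off <- origins[b, ] - origins[a, ]
      # overlap too thin for the matching blocks: rigid only
      ovExt <- pmin(dims[a, ], dims[b, ] + off) - pmax(1, 1 + off) + 1
      if (any(ovExt < 2 * blockRadiusVox + 1)) next
      f <- tryCatch({
        f0 <- blockMatchField(tiles[[a]], tiles[[b]], off,
                              gridSpacingVox = gridSpacingVox,
                              blockRadiusVox = blockRadiusVox,
                              searchRadiusVox = searchRadiusVox,
                              scoreThreshold = scoreThreshold,
                              maxDisplacementVox = maxDisplacementVox)
        if (!any(f0@valid)) NULL else {
          fs <- filterAndSmoothField(f0, fallbackShift = -off)
          nonrigid <- sweep(fs@shifts, 2, -off)
          small <- median(sqrt(rowSums(nonrigid^2))) < minWarpVox
          if (small || !warpImproves(tiles[[a]], tiles[[b]], off, fs))
            NULL else fs
        }
      }, error = function(err) NULL)
      fieldList[[paste(a, b)]] <- f
    }
    # warp composition in acquisition order; earliest tile is the reference
    ord <- order(times)
    placed <- rep(FALSE, n)
    placed[ord[1]] <- TRUE
    for (b in ord[-1]) {
      inc <- pairs[pairs$b == b & placed[pairs$a], , drop = FALSE]
      if (nrow(inc) == 0) { placed[b] <- TRUE; next }
      inc <- inc[which.max(inc$confidence), ]
      a <- inc$a
      f <- fieldList[[paste(a, b)]]
      if (!is.null(f)) {
        aFun <- localFuns[[a]]
        oA <- origins[a, ]
        localFuns[[b]] <- local({
          fld <- f; aF <- aFun; originA <- oA
          function(w) {
            lA <- if (is.null(aF)) sweep(w, 2, originA) else aF(w)
            lA + fieldShiftDense(fld, lA)
          }
        })
      }
      placed[b] <- TRUE
    }
  }

  res <- blendMosaic(tiles, origins, localCoordFuns = localFuns,
                     rampVox = rampVox, circularFov = TRUE,
                     voxelSizeUm = tiles[[1]]@voxelSizeUm,
                     originMm = floor(apply(origins, 2, min)) * vox_mm)
  usedWarps <- !all(vapply(localFuns, is.null, logical(1)))
  if (usedWarps) {
    # keep the warped fusion only if it lowers the global overlap std:
    # on an effectively static mosaic the matched displacements are
    # reconstruction artifacts and rigid fusion is the better estimate
    res0 <- blendMosaic(tiles, origins, rampVox = rampVox,
                        circularFov = TRUE,
                        voxelSizeUm = tiles[[1]]@voxelSizeUm,
                        originMm = floor(apply(origins, 2, min)) * vox_mm)
    mW <- mean(res@stdMap[res@provenance >= 2L])
    mR <- mean(res0@stdMap[res0@provenance >= 2L])
    if (is.finite(mR) && (!is.finite(mW) || mR <= mW)) {
      res <- res0
      usedWarps <- FALSE
    }
  }
  st <- res@stats
  st$non_rigid_applied <- usedWarps
  st$pairs <- pairs
  st$origins_vox <- origins
  if (!is.null(stdThreshold))
    st$artifacts <- artifactStatistics(res@stdMap, stdThreshold,
                                       res@provenance >= 2L)
  res@stats <- st
  res
}

setMethod("show", "StitchResult", function(object) {
  d <- dim(object@fused)
  ov <- mean(object@provenance >= 2L)
  cat(sprintf("StitchResult: %d x %d x %d voxels at %.3g um\n", d[1], d[2],
              d[3], object@voxelSizeUm))
  cat(sprintf("  overlap volume fraction %.3f; mean overlap std %.4g\n", ov,
              mean(object@stdMap[object@provenance >= 2L])))
})

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf("DisplacementField: %d control points (%d valid), spacing %g vox\n",
              nrow(object@points), sum(object@valid), object@spacingVox))
})
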