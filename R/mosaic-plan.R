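#' Build a zigzag mosaic acquisition plan
#'
#' Lays out \code{prod(gridShape)} overlapping tiles on a regular lattice and
#' orders them column-wise (vertical axis fastest) with zigzag traversal along
#' every axis, so that each translation between consecutive scans moves to an
#' adjacent unmeasured tile.  Columns in the horizontal plane are visited in
#' serpentine order starting at grid index (0,0).  Predicted start times are
#' filled in from the timing model: one-off calibration first, then
#' alternating scans and stage motions.
#'
#' @param gridShape integer (nx, ny, nz): tiles along width, length, height.
#' @param tileExtentMm numeric (w, l, h): physical tile extent, mm.
#' @param stepMm numeric (horizontal, vertical) lattice steps, mm; must be
#'   positive and no larger than the corresponding tile extent.
#' @param pixelSizeUm pixel size, micrometres.
#' @param timing a \linkS4class{TimingModel} used for predicted start times.
#' @return A \linkS4class{MosaicPlan}.
#' @examples
#' plan <- buildPlan(c(3, 3, 7), c(10.8, 10.8, 3.0), c(7.2, 2.75))
#' nTiles(plan)  # 63
#' @export
buildPlan <- function(gridShape, tileExtentMm, stepMm, pixelSizeUm = 2.75,
                      timing = TimingModel()) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3, all(gridShape >= 1),
            length(tileExtentMm) == 3, length(stepMm) == 2)
  if (any(stepMm <= 0)) stop("steps must be > 0")
  if (stepMm[1] > min(tileExtentMm[1:2]) || stepMm[2] > tileExtentMm[3])
    stop("no overlap: step larger than tile extent")
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]

  # serpentine over the horizontal plane, i fastest within each j row
  cols <- do.call(rbind, lapply(seq_len(ny) - 1L, function(j) {
    is <- seq_len(nx) - 1L
    if (j %% 2L == 1L) is <- rev(is)
    cbind(i = is, j = j)
  }))
  # vertical zigzag within each column
  tiles <- do.call(rbind, lapply(seq_len(nrow(cols)), function(ci) {
    ks <- seq_len(nz) - 1L
    if ((ci - 1L) %% 2L == 1L) ks <- rev(ks)
    data.frame(i = as.integer(cols[ci, "i"]), j = as.integer(cols[ci, "j"]),
               k = as.integer(ks), row.names = NULL)
  }))
  tiles$order_index <- seq_len(nrow(tiles)) - 1L
  tiles$x_mm <- tiles$i * stepMm[1]
  tiles$y_mm <- tiles$j * stepMm[1]
  tiles$z_mm <- tiles$k * stepMm[2]

  # predicted timeline: calibration, then scan / move / scan / ...
  t <- timing@calibrationTimeS
  starts <- numeric(nrow(tiles))
  for (r in seq_len(nrow(tiles))) {
    if (r > 1) {
      mv <- moveDuration(tiles[r - 1, ], tiles[r, ], stepMm, timing)
      t <- t + mv
    }
    starts[r] <- t
    t <- t + timing@scanTimeS
  }
  tiles$predicted_start_s <- starts
  new("MosaicPlan", gridShape = gridShape,
      tileExtentMm = as.numeric(tileExtentMm), stepMm = as.numeric(stepMm),
      pixelSizeUm = pixelSizeUm, tiles = tiles)
}

# duration of the single-axis motion between two consecutive tiles
moveDuration <- function(a, b, stepMm, timing) {
  di <- abs(b$i - a$i); dj <- abs(b$j - a$j); dk <- abs(b$k - a$k)
  if (di + dj + dk != 1L)
    stop("consecutive tiles must be grid-adjacent")
  if (dk == 1L) {
    stepMm[2] * 1000 / timing@verticalSpeedUmS + timing@moveOverheadS
  } else {
    stepMm[1] * 1000 / timing@horizontalSpeedUmS + timing@moveOverheadS
  }
}

#' Number of tiles in a plan
#' @param plan a \linkS4class{MosaicPlan}.
#' @export
nTiles <- function(plan) nrow(plan@tiles)

#' Tile pose table of a plan
#' @param plan a \linkS4class{MosaicPlan}.
#' @return data.frame of tile poses in acquisition order.
#' @export
planTiles <- function(plan) plan@tiles[order(plan@tiles$order_index), ]

#' Total physical extent covered by a plan
#' @param plan a \linkS4class{MosaicPlan}.
#' @return numeric (x, y, z) extent in mm:
#'   \code{(n - 1) * step + tile_extent} per axis.
#' @export
planExtentMm <- function(plan) {
  g <- plan@gridShape
  st <- c(plan@stepMm[1], plan@stepMm[1], plan@stepMm[2])
  (g - 1) * st + plan@tileExtentMm
}

#' Predict the duration of a mosaic acquisition
#'
#' Sums per-event durations over the plan's zigzag order: one scan per tile,
#' one stage motion between consecutive tiles (vertical or horizontal
#' depending on which grid coordinate changes, each costing
#' distance/speed + overhead), plus the one-off calibration time.
#'
#' @param plan a \linkS4class{MosaicPlan}.
#' @param timing a \linkS4class{TimingModel}.
#' @return list with \code{total_s} and a per-event breakdown data.frame
#'   (\code{event}, \code{count}, \code{each_s}, \code{total_s}).
#' @examples
#' plan <- buildPlan(c(3, 3, 7), c(10.8, 10.8, 3.0), c(7.2, 2.75))
#' estimateDuration(plan, TimingModel())$total_s  # under 22 minutes
#' @export
estimateDuration <- function(plan, timing = TimingModel()) {
  tiles <- planTiles(plan)
  n <- nrow(tiles)
  vmove <- timing@moveOverheadS + plan@stepMm[2] * 1000 / timing@verticalSpeedUmS
  hmove <- timing@moveOverheadS + plan@stepMm[1] * 1000 / timing@horizontalSpeedUmS
  nv <- nh <- 0L
  if (n > 1) {
    dk <- abs(diff(tiles$k))
    nv <- sum(dk == 1L)
    nh <- (n - 1L) - nv
  }
  breakdown <- data.frame(
    event = c("calibration", "scan", "vertical_move", "horizontal_move"),
    count = c(1L, n, nv, nh),
    each_s = c(timing@calibrationTimeS, timing@scanTimeS, vmove, hmove)
  )
  breakdown$total_s <- breakdown$count * breakdown$each_s
  list(total_s = sum(breakdown$total_s), breakdown = breakdown)
}

#' Valid-data regions of a wide-field reconstruction
#'
#' An extended-FOV reconstruction is complete inside a circle of the given
#' diameter; the largest inscribed square has side \code{diameter / sqrt(2)}
#' (rounded to whole pixels).
#'
#' @param tileDiameterPx reconstruction circle diameter, pixels.
#' @return list with \code{circle_diameter_px} and \code{square_side_px}.
#' @examples
#' validRegions(3927)$square_side_px  # 2777
#' @export
validRegions <- function(tileDiameterPx) {
  stopifnot(tileDiameterPx > 0)
  list(circle_diameter_px = tileDiameterPx,
       square_side_px = round(tileDiameterPx / sqrt(2)))
}

#' Overlap regions between adjacent tiles
#'
#' For every grid-adjacent tile pair reports the shared region's extent along
#' the adjacency axis, in mm and pixels, together with the overlap interval in
#' both tiles' local coordinates (local frame: [0, extent] per axis, origin at
#' the tile's lower corner).  Rows come in both orientations (a,b) and (b,a),
#' so the map is symmetric by construction.  Pairs whose step equals the tile
#' extent are reported with zero overlap.
#'
#' @param plan a \linkS4class{MosaicPlan}.
#' @return data.frame with columns \code{a}, \code{b} (order indices),
#'   \code{axis}, \code{overlap_mm}, \code{overlap_px}, \code{a_lo_mm},
#'   \code{a_hi_mm}, \code{b_lo_mm}, \code{b_hi_mm}.
#' @export
overlapMap <- function(plan) {
  tiles <- plan@tiles
  g <- plan@gridShape
  ext <- plan@tileExtentMm
  st <- c(plan@stepMm[1], plan@stepMm[1], plan@stepMm[2])
  px_mm <- plan@pixelSizeUm * 1e-3
  rows <- list()
  axes <- c("i", "j", "k")
  axname <- c("x", "y", "z")
  for (ax in 1:3) {
    ov <- ext[ax] - st[ax]
    key <- tiles[[axes[ax]]]
    other <- setdiff(1:3, ax)
    for (r in seq_len(nrow(tiles))) {
      # neighbour one step up along this axis
      sel <- tiles[[axes[ax]]] == key[r] + 1L
      for (oa in other) sel <- sel & tiles[[axes[oa]]] == tiles[[axes[oa]]][r]
      nb <- which(sel)
      if (length(nb) != 1L) next
      # a below b along axis: overlap at a's top, b's bottom
      rows[[length(rows) + 1L]] <- data.frame(
        a = tiles$order_index[r], b = tiles$order_index[nb],
        axis = axname[ax], overlap_mm = ov, overlap_px = ov / px_mm,
        a_lo_mm = ext[ax] - ov, a_hi_mm = ext[ax],
        b_lo_mm = 0, b_hi_mm = ov)
      rows[[length(rows) + 1L]] <- data.frame(
        a = tiles$order_index[nb], b = tiles$order_index[r],
        axis = axname[ax], overlap_mm = ov, overlap_px = ov / px_mm,
        a_lo_mm = 0, a_hi_mm = ov,
        b_lo_mm = ext[ax] - ov, b_hi_mm = ext[ax])
    }
  }
  if (!length(rows)) {
    return(data.frame(a = integer(), b = integer(), axis = character(),
                      overlap_mm = numeric(), overlap_px = numeric(),
                      a_lo_mm = numeric(), a_hi_mm = numeric(),
                      b_lo_mm = numeric(), b_hi_mm = numeric()))
  }
  do.call(rbind, rows)
}

#' Physical extent of a voxel run
#'
#' Bookkeeping helper: the physical length spanned by \code{n} voxels of the
#' given size.
#' @param nVox voxel count.
#' @param pixelSizeUm voxel size, micrometres.
#' @return length in mm.
#' @export
voxelExtentMm <- function(nVox, pixelSizeUm) nVox * pixelSizeUm * 1e-3

#' Storage size of a voxel grid
#'
#' @param dimsVox integer voxel dimensions.
#' @param bytesPerVoxel bytes per stored voxel (2 for 16-bit).
#' @return size in terabytes (decimal, 1 TB = 1e12 bytes).
#' @export
storageTb <- function(dimsVox, bytesPerVoxel = 2) {
  prod(as.numeric(dimsVox)) * bytesPerVoxel / 1e12
}

setMethod("show", "MosaicPlan", function(object) {
  g <- object@gridShape
  cat(sprintf("MosaicPlan: %d x %d x %d grid (%d tiles)\n", g[1], g[2], g[3],
              nTiles(object)))
  cat(sprintf("  tile extent: %s mm; steps: %.3g (h) / %.3g (v) mm\n",
              paste(object@tileExtentMm, collapse = " x "),
              object@stepMm[1], object@stepMm[2]))
  cat(sprintf("  total extent: %s mm; pixel %.3g um\n",
              paste(sprintf("%.3g", planExtentMm(object)), collapse = " x "),
              object@pixelSizeUm))
})
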