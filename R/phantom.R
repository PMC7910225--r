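#' Generate a foam-like lung phantom
#'
#' Builds a synthetic attenuation phantom emulating an intact small-animal
#' chest: a cylindrical tissue "body", a cylindrical "lung" region filled with
#' a foam of carved air spheres ("alveolar" airspaces) connected by thin ducts
#' and by a vertical "trachea" reaching the top face, and a few high-\eqn{\mu}
#' vertical "bone" rods between the lung boundary and the body surface.
#'
#' Airspaces are carved from a jittered body-centred cubic lattice whose
#' pitch is chosen from the requested wall thickness and target air fraction;
#' one calibration pass rescales the sphere diameter so the realized air
#' fraction (counted over the lung region) lands within 5\% (relative) of the
#' target.  Neighbouring airspaces are connected by ducts so the airspace
#' forms a single 3-D connected component with the trachea.
#'
#' @param shapeVox integer (nx, ny, nz) voxel dimensions.
#' @param voxelSizeUm isotropic voxel size, micrometres.
#' @param targetAirFraction desired air fraction of the lung region, in
#'   [0, 1); 0 yields a solid block.
#' @param wallThicknessUm nominal inter-airspace wall thickness, micrometres.
#' @param seed integer seed; identical seeds give identical phantoms.
#' @param bodyRadiusFrac,lungRadiusFrac body and lung cylinder radii as
#'   fractions of min(nx, ny).
#' @param smoothSigmaVox Gaussian smoothing (voxels) applied to the
#'   attenuation map, emulating the finite detector/optics resolution; the
#'   binary ground-truth masks are kept unsmoothed.
#' @param muTissue,muBone linear attenuation of tissue and bone, 1/m.
#' @return A \linkS4class{Phantom}.
#' @examples
#' ph <- makeFoamPhantom(c(64, 64, 64), 2.75, 0.5, seed = 1)
#' airVolumeMm3(ph)
#' @export
makeFoamPhantom <- function(shapeVox, voxelSizeUm = 2.75,
                            targetAirFraction = 0.6,
                            wallThicknessUm = 2 * voxelSizeUm, seed = 1,
                            bodyRadiusFrac = 0.47, lungRadiusFrac = 0.38,
                            smoothSigmaVox = 1.5,
                            muTissue = 55, muBone = 5 * muTissue) {
  shapeVox <- as.integer(shapeVox)
  stopifnot(length(shapeVox) == 3, all(shapeVox >= 8))
  if (targetAirFraction < 0 || targetAirFraction >= 1)
    stop("targetAirFraction must be in [0, 1)")
  nx <- shapeVox[1]; ny <- shapeVox[2]; nz <- shapeVox[3]
  set.seed(as.integer(childSeed(seed, 1)) %% .Machine$integer.max)

  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r2 <- outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+")
  rBody <- bodyRadiusFrac * min(nx, ny)
  rLung <- lungRadiusFrac * min(nx, ny)
  bodyXY <- r2 <= rBody^2
  lungXY <- r2 <= rLung^2
  zLo <- 1L; zHi <- nz   # foam spans the full height (lung-only sub-volume)

  vol <- array(0, dim = shapeVox)
  body <- array(FALSE, shapeVox); body[] <- as.vector(bodyXY)
  vol[body] <- muTissue
  lung <- array(FALSE, shapeVox)
  for (z in zLo:zHi) lung[, , z] <- lungXY

  air <- array(FALSE, shapeVox)
  if (targetAirFraction > 0) {
    w <- max(1, wallThicknessUm / voxelSizeUm)
    # BCC lattice, 2 spheres per p^3 cell: fraction = (pi/3) d^3 / p^3
    cc <- (3 * targetAirFraction / pi)^(1 / 3)
    if (cc >= 0.95)
      stop("unreachable air fraction for the given wall thickness")
    d <- max(5, 2.5 * w + 2)            # airspace diameter from wall scale
    pitch <- d / cc
    if (pitch > 0.75 * min(2 * rLung, zHi - zLo))
      stop("unreachable air fraction for the given wall thickness")
    lungCount <- sum(lung)
    # jittered BCC lattice of airspace centres inside the lung region
    gx <- seq(cx - rLung, cx + rLung, by = pitch)
    gy <- seq(cy - rLung, cy + rLung, by = pitch)
    gz <- seq(zLo + 1, zHi - 1, by = pitch)
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    pts <- rbind(pts, sweep(pts, 2, rep(pitch / 2, 3), "+"))
    pts <- pts + matrix(runif(length(pts), -pitch / 6, pitch / 6), ncol = 3)
    keep <- (pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 <= (rLung - 1)^2 &
      pts[, 3] >= zLo & pts[, 3] <= zHi
    pts <- pts[keep, , drop = FALSE]
    rjit <- runif(nrow(pts), 0.85, 1.15)
    # ducts along lattice edges connect neighbouring airspaces (single
    # 26-connected airspace by construction)
    nbr <- NULL
    if (nrow(pts) > 1) {
      nbr <- do.call(rbind, lapply(seq_len(nrow(pts)), function(p) {
        dd <- sqrt(rowSums(sweep(pts, 2, pts[p, ])^2))
        q <- which(dd > 0 & dd < 1.05 * pitch & seq_along(dd) > p)
        if (length(q)) cbind(p, q, dd[q]) else NULL
      }))
    }
    carve <- function(d) {
      segs <- list(pts)
      rads <- list(d / 2 * rjit)
      if (!is.null(nbr)) {
        rd <- max(1, 0.18 * d)
        for (r in seq_len(nrow(nbr))) {
          p <- nbr[r, 1]; q <- nbr[r, 2]
          fr <- seq(0, 1, length.out = ceiling(nbr[r, 3]) + 1)
          seg <- outer(1 - fr, pts[p, ]) + outer(fr, pts[q, ])
          segs[[length(segs) + 1L]] <- seg
          rads[[length(rads) + 1L]] <- rep(rd, nrow(seg))
        }
      }
      a <- carve_balls_cpp(shapeVox, do.call(rbind, segs) - 1,
                           unlist(rads))
      a & lung
    }
    air <- carve(d)
    f2 <- sum(air) / lungCount
    for (it in 1:4) {
      if (f2 <= 0 ||
          abs(f2 - targetAirFraction) / targetAirFraction <= 0.02) break
      d <- d * (targetAirFraction / f2)^(1 / 3)
      air <- carve(d)
      f2 <- sum(air) / lungCount
    }
    if (abs(f2 - targetAirFraction) / targetAirFraction > 0.05)
      stop(sprintf(paste("unreachable air fraction for the given wall",
                         "thickness (target %.3f, realized %.3f)"),
                   targetAirFraction, f2))
    # trachea: vertical air column from the top face down into the foam
    rt <- max(2, 0.25 * d)
    trXY <- r2 <= rt^2
    for (z in seq(floor(0.5 * nz), nz)) {
      sl <- air[, , z]
      sl[trXY & as.vector(bodyXY)] <- TRUE
      air[, , z] <- sl
    }
  }

  vol[air] <- 0

  # bone rods outside the lung, inside the body
  rRod <- max(1.5, 0.02 * min(nx, ny))
  rodR <- (rLung + rBody) / 2
  bone <- array(FALSE, shapeVox)
  for (ang in c(90, 210, 330) * pi / 180) {
    bx <- cx + rodR * cos(ang); by <- cy + rodR * sin(ang)
    rodXY <- outer((seq_len(nx) - bx)^2, (seq_len(ny) - by)^2, "+") <= rRod^2
    bone[] <- bone | rep(as.vector(rodXY & bodyXY & !lungXY), nz)
  }
  bone <- bone & !air
  vol[bone] <- muBone

  if (smoothSigmaVox > 0) {
    # partial-volume smoothing: air-mask boundary voxels take intermediate
    # attenuation; the mask interior stays at mu = 0
    vol <- gaussSmooth3d(vol, smoothSigmaVox)
    vol[vol < 1e-9 * muTissue] <- 0
  }

  vox_mm3 <- (voxelSizeUm * 1e-3)^3
  new("Phantom", vol = vol, voxelSizeUm = voxelSizeUm, airMask = air,
      lungMask = lung, airVolumeMm3 = sum(air) * vox_mm3,
      muTissue = muTissue, muBone = muBone)
}


#' Ground-truth air volume of a phantom
#' @param phantom a \linkS4class{Phantom}.
#' @return air volume in mm^3.
#' @export
airVolumeMm3 <- function(phantom) phantom@airVolumeMm3

#' Realized air fraction of a phantom's lung region
#' @param phantom a \linkS4class{Phantom}.
#' @export
airFraction <- function(phantom) {
  n <- sum(phantom@lungMask)
  if (n == 0) return(0)
  sum(phantom@airMask & phantom@lungMask) / n
}

setMethod("show", "Phantom", function(object) {
  d <- dim(object@vol)
  cat(sprintf("Phantom: %d x %d x %d voxels at %.3g um\n", d[1], d[2], d[3],
              object@voxelSizeUm))
  cat(sprintf("  air volume %.4g mm^3 (lung air fraction %.3f)\n",
              object@airVolumeMm3, airFraction(object)))
})
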