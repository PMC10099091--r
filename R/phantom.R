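#' Specification of a synthetic abdomen phantom
#'
#' Defines an abdomen-like 3D grid: an elliptical body of soft tissue on an
#' air background, a spine-like posterior column with a spinous process,
#' rib-like arcs, smooth soft-tissue texture, and implanted bright fiducial
#' markers. Used to exercise every registration stage without patient data.
#'
#' @param shape Grid size (all dims >= 16); default 64x64x48.
#' @param spacing Voxel spacing in mm; default (2, 2, 2).
#' @param n_fiducials Number of implanted markers (>= 0).
#' @param seed Integer seed making generation fully reproducible.
#' @param hu_body,hu_bone,hu_air Tissue HU levels.
#' @param artifact_strength Streak/bias amplitude passed to [degrade()].
#' @param intensity_shift_hu Global HU shift passed to [degrade()].
#' @return A `dirgan_phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 48), spacing = c(2, 2, 2),
                         n_fiducials = 4, seed = 1,
                         hu_body = 40, hu_bone = 700, hu_air = -1000,
                         artifact_strength = 0, intensity_shift_hu = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop("phantom shape must be 3 dims, all >= 16")
  if (n_fiducials < 0) stop("n_fiducials must be >= 0")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 n_fiducials = as.integer(n_fiducials), seed = as.integer(seed),
                 hu_body = hu_body, hu_bone = hu_bone, hu_air = hu_air,
                 artifact_strength = artifact_strength,
                 intensity_shift_hu = intensity_shift_hu),
            class = "dirgan_phantom_spec")
}

#' Generate an abdomen-like phantom
#'
#' Builds the volume described by the spec: body ellipsoid at `hu_body`
#' (plus smooth seeded soft-tissue texture and a few organ-like blobs) on
#' `hu_air` background, one spine-like column with a posterior spinous
#' process and two rib-like arcs at `hu_bone`, and `n_fiducials` bright
#' (2500 HU) 3-voxel cross markers well inside the body. Landmarks are
#' placed at the fiducial centres, the spinous process tip and the two rib
#' tips. Fully reproducible from the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` ([volume()]), `landmarks` ([landmark_set()]),
#'   `body` ([mask()]) and the bookkeeping count `n_bone_voxels` (voxels
#'   strictly above 300 HU excluding markers).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "dirgan_phantom_spec"))
  d <- spec$shape
  with_seed(spec$seed, {
    ix <- (seq_len(d[1]) - 1)
    iy <- (seq_len(d[2]) - 1)
    iz <- (seq_len(d[3]) - 1)
    cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
    X <- array(rep(ix, times = d[2] * d[3]), d)
    Y <- array(rep(rep(iy, each = d[1]), times = d[3]), d)
    Z <- array(rep(iz, each = d[1] * d[2]), d)
    # body: superellipse cross-section, slightly tapered in z
    ax <- 0.42 * d[1]; ay <- 0.36 * d[2]
    taper <- 1 - 0.1 * abs(2 * Z / (d[3] - 1) - 1)
    body <- ((abs(X - cx) / (ax * taper))^2.5 +
               (abs(Y - cy) / (ay * taper))^2.5) <= 1
    arr <- array(spec$hu_air, d)
    # smooth soft-tissue texture so similarity losses see structure
    tex <- array(stats::rnorm(prod(d)), d)
    tex <- array(cpp_gaussian_smooth(as.numeric(tex), as.integer(d),
                                     c(4, 4, 3)), d)
    tex <- tex / max(abs(tex)) * 60
    arr[body] <- spec$hu_body + tex[body]
    # organ-like blobs
    blob <- function(ctr, semi, dhu) {
      m <- (((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
              ((Z - ctr[3]) / semi[3])^2) <= 1
      arr[m & body] <<- arr[m & body] + dhu
    }
    blob(c(cx - 0.18 * d[1], cy - 0.10 * d[2], 0.45 * d[3]),
         c(0.16 * d[1], 0.14 * d[2], 0.30 * d[3]), 45)
    blob(c(cx + 0.16 * d[1], cy - 0.05 * d[2], 0.55 * d[3]),
         c(0.10 * d[1], 0.10 * d[2], 0.20 * d[3]), -70)
    blob(c(cx, cy + 0.12 * d[2], 0.35 * d[3]),
         c(0.08 * d[1], 0.07 * d[2], 0.18 * d[3]), 35)
    # spine: posterior column, full z extent
    sy <- cy + 0.22 * d[2]
    rad_sp <- max(2.5, 0.055 * d[1])
    spine <- ((X - cx)^2 + (Y - sy)^2) <= rad_sp^2
    bone <- spine & body
    # spinous process: thin posterior ridge ending at a tip
    tip_y <- min(sy + 0.12 * d[2], cy + ay - 2)
    proc <- abs(X - cx) <= 1 & Y > sy & Y <= tip_y &
      abs(Z - (d[3] - 1) / 2) <= 0.3 * d[3]
    bone <- bone | (proc & body)
    # two rib-like arcs at fixed z bands
    rib_z <- round(c(0.30, 0.62) * (d[3] - 1))
    rib_tips <- list()
    for (s in c(-1, 1)) {
      zb <- rib_z[if (s < 0) 1 else 2]
      th <- seq(0.15 * pi, 0.75 * pi, length.out = 40)
      rx <- cx + s * 0.34 * d[1] * sin(th)
      ry <- sy - 0.30 * d[2] * (1 - cos(th))
      ribm <- array(FALSE, d)
      for (t in seq_along(th)) {
        xi <- round(rx[t]) + 1; yi <- round(ry[t]) + 1
        if (xi < 2 || xi > d[1] - 1 || yi < 2 || yi > d[2] - 1) next
        ribm[(xi - 1):(xi + 1), (yi - 1):(yi + 1),
             max(1, zb):min(d[3], zb + 2)] <- TRUE
      }
      bone <- bone | (ribm & body)
      rib_tips[[length(rib_tips) + 1]] <-
        c(round(rx[length(th)]), round(ry[length(th)]), zb + 1)
    }
    arr[bone] <- spec$hu_bone
    # partial-volume / scanner-PSF emulation: real CT edges are spread over
    # 1-2 voxels; without this the phantom's binary edges dominate every
    # intensity metric
    arr <- array(cpp_gaussian_smooth(as.numeric(arr), as.integer(d),
                                     c(0.7, 0.7, 0.7)), d)
    n_bone <- sum(arr > 300)
    # fiducial markers: 3-voxel crosses at 2500 HU, interior, non-bone
    labels <- character(); lm_idx <- NULL
    interior <- body & !bone &
      ((abs(X - cx) / (0.7 * ax))^2.5 + (abs(Y - cy) / (0.7 * ay))^2.5 <= 1) &
      Z > 0.15 * d[3] & Z < 0.85 * d[3]
    cand <- which(interior)
    placed <- matrix(numeric(0), 0, 3)
    for (f in seq_len(spec$n_fiducials)) {
      ok <- FALSE
      for (try in 1:200) {
        pick <- cand[sample.int(length(cand), 1)]
        kz <- (pick - 1) %/% (d[1] * d[2])
        ky <- ((pick - 1) %% (d[1] * d[2])) %/% d[1]
        kx <- (pick - 1) %% d[1]
        p <- c(kx, ky, kz)
        if (nrow(placed) == 0 ||
            min(sqrt(rowSums(sweep(placed, 2, p)^2))) > 6) {
          placed <- rbind(placed, p)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place ", spec$n_fiducials,
                    " fiducials without overlap")
      xi <- p[1] + 1; yi <- p[2] + 1; zi <- p[3] + 1
      arr[xi, yi, zi] <- 2500
      arr[max(1, xi - 1):min(d[1], xi + 1), yi, zi] <- 2500
      arr[xi, max(1, yi - 1):min(d[2], yi + 1), zi] <- 2500
      labels <- c(labels, sprintf("fid%d", f))
      lm_idx <- rbind(lm_idx, p)
    }
    # bone-tip landmarks
    labels <- c(labels, "spine_tip", "rib_tip_L", "rib_tip_R")
    lm_idx <- rbind(lm_idx,
                    c(cx, tip_y, (d[3] - 1) / 2),
                    rib_tips[[1]] - c(1, 1, 1) + c(1, 1, 0),
                    rib_tips[[2]] - c(1, 1, 1) + c(1, 1, 0))
    v <- volume(arr, spacing = spec$spacing)
    list(volume = v,
         landmarks = landmark_set(labels, voxel_to_mm(lm_idx, v)),
         body = body_mask(v),
         n_bone_voxels = n_bone)
  })
}

#' Smooth random ground-truth displacement field
#'
#' Each component is Gaussian white noise smoothed with an isotropic
#' Gaussian of width `smoothness_sigma_vox` and the whole field rescaled so
#' the maximum displacement magnitude equals `max_displacement_vox`. When
#' `max_displacement_vox < smoothness_sigma_vox / 2` the generated field is
#' checked to have strictly positive Jacobian determinant everywhere and is
#' regenerated with a derived sub-seed otherwise.
#'
#' @param shape Grid dims.
#' @param max_displacement_vox Peak displacement magnitude, voxels (>= 0).
#' @param smoothness_sigma_vox Gaussian smoothing width, voxels.
#' @param seed Integer seed.
#' @param spacing Grid spacing in mm.
#' @return A [dvf()].
#' @export
make_smooth_dvf <- function(shape, max_displacement_vox = 3,
                            smoothness_sigma_vox = 8, seed = 1,
                            spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (max_displacement_vox < 0) stop("max_displacement_vox must be >= 0")
  if (max_displacement_vox == 0) return(zero_dvf(shape, spacing))
  must_be_diffeo <- max_displacement_vox < smoothness_sigma_vox / 2
  for (attempt in 0:9) {
    u <- with_seed(seed + 10000L * attempt, {
      u <- array(stats::rnorm(prod(shape) * 3), c(shape, 3))
      for (comp in 1:3)
        u[, , , comp] <- array(
          cpp_gaussian_smooth(as.numeric(u[, , , comp]), shape,
                              rep(smoothness_sigma_vox, 3)), shape)
      mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
      u * (max_displacement_vox / max(mag))
    })
    out <- dvf(u, spacing)
    if (!must_be_diffeo || all(jacobian_determinant(out) > 0)) return(out)
  }
  stop("failed to generate a fold-free smooth field after 10 attempts")
}

#' Apply CBCT-like inter-fraction degradation
#'
#' Adds (i) a global HU shift, (ii) a smooth multiplicative bias field of
#' relative amplitude proportional to `artifact_strength` acting on the
#' attenuation above air, and (iii) radial streak-like high-frequency
#' stripes in the axial plane with HU amplitude `artifact_strength`.
#' Deterministic per seed; with `artifact_strength = 0` and zero shift the
#' volume is returned unchanged.
#'
#' @param v A [volume()].
#' @param artifact_strength Streak amplitude in HU (>= 0); also scales the
#'   bias field (2% relative per 10 HU of streak amplitude).
#' @param intensity_shift_hu Global additive HU shift.
#' @param seed Integer seed.
#' @return The degraded [volume()].
#' @export
degrade <- function(v, artifact_strength = 0, intensity_shift_hu = 0,
                    seed = 1) {
  stopifnot(inherits(v, "dirgan_volume"))
  if (artifact_strength == 0 && intensity_shift_hu == 0) return(v)
  d <- dim(v$data)
  arr <- v$data
  if (artifact_strength > 0) {
    arr <- with_seed(seed, {
      bias <- array(stats::rnorm(prod(d)), d)
      bias <- array(cpp_gaussian_smooth(as.numeric(bias), as.integer(d),
                                        0.25 * d), d)
      bias <- 1 + (0.002 * artifact_strength) * bias / max(abs(bias))
      out <- (arr + 1000) * bias - 1000
      # streaks: incoherent angular noise about a random axial centre —
      # a superposition of many random angular modes, so two independent
      # realizations stay uncorrelated under any rotation and cannot be
      # matched by a deformation (unlike a single coherent sinusoid)
      cx <- (d[1] - 1) / 2 + stats::runif(1, -2, 2)
      cy <- (d[2] - 1) / 2 + stats::runif(1, -2, 2)
      X <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d)
      Y <- array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), d)
      Z <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d)
      theta <- atan2(Y - cy, X - cx)
      r <- sqrt((X - cx)^2 + (Y - cy)^2)
      rmax <- sqrt(cx^2 + cy^2)
      modes <- 8:24
      amp <- stats::rnorm(length(modes))
      phs <- stats::runif(length(modes), 0, 2 * pi)
      zph <- stats::runif(length(modes), -0.2, 0.2)
      pat <- array(0, d)
      for (m in seq_along(modes))
        pat <- pat + amp[m] * sin(modes[m] * theta + phs[m] + zph[m] * Z)
      pat <- pat / max(abs(pat))
      streak <- artifact_strength * pat * exp(-((r / rmax - 0.45) / 0.35)^2)
      out + streak
    })
  }
  arr <- arr + intensity_shift_hu
  volume(arr, spacing = v$spacing, origin = v$origin)
}

#' Build a registration test pair with known ground truth
#'
#' The target is the phantom carrying its own fraction-specific artifacts;
#' the moving image is the phantom warped by a smooth ground-truth field
#' and then degraded with an independent artifact realization plus the
#' inter-fraction HU shift. Both fractions carry artifacts because both are
#' cone-beam acquisitions: against an artifact-free target, a deformation
#' can lower descriptor dissimilarity simply by squeezing the moving
#' image's artifact structure into uniformity, a shortcut that does not
#' exist in real longitudinal data. Moving-frame landmark positions are
#' obtained by numerically inverting the backward-mapping ground-truth
#' field at each target landmark, so the pre-registration TRE is exact.
#'
#' @param spec A [phantom_spec()] (its `artifact_strength`,
#'   `intensity_shift_hu` and `seed` drive the degradation).
#' @param max_displacement_vox,smoothness_sigma_vox Ground-truth field
#'   parameters, see [make_smooth_dvf()].
#' @return List with `target`, `moving` ([volume()]s), `gt_dvf` ([dvf()]),
#'   `landmarks_target`, `landmarks_moving` ([landmark_set()]s) and `body`
#'   ([mask()] of the target).
#' @export
make_registration_pair <- function(spec = phantom_spec(),
                                   max_displacement_vox = 3,
                                   smoothness_sigma_vox = 8) {
  ph <- make_phantom(spec)
  gt <- make_smooth_dvf(spec$shape, max_displacement_vox,
                        smoothness_sigma_vox, seed = spec$seed + 555L,
                        spacing = spec$spacing)
  target <- degrade(ph$volume, spec$artifact_strength, 0,
                    seed = spec$seed + 888L)
  moving <- warp(ph$volume, gt)
  moving <- degrade(moving, spec$artifact_strength, spec$intensity_shift_hu,
                    seed = spec$seed + 777L)
  # a target landmark at voxel p sits in the moving frame at x with
  # x + u(x) = p (backward mapping): fixed-point inversion
  vox_t <- mm_to_voxel(ph$landmarks$coords, ph$volume)
  vox_m <- t(apply(vox_t, 1, function(p) invert_dvf_at(gt, p)))
  list(target = target, moving = moving, gt_dvf = gt,
       landmarks_target = ph$landmarks,
       landmarks_moving = landmark_set(ph$landmarks$labels,
                                       voxel_to_mm(vox_m, moving)),
       body = ph$body)
}

# Fixed-point inversion of a backward-mapping DVF at a single 0-based voxel
# coordinate p: find x with x + u(x) = p.
invert_dvf_at <- function(d, p, tol = 1e-3, max_iter = 50) {
  dims <- dvf_dims(d)
  x <- p
  for (it in seq_len(max_iter)) {
    u_at <- cpp_sample_trilinear(as.numeric(d$u), as.integer(dims), 3L,
                                 matrix(x, 1, 3))
    x_new <- p - as.numeric(u_at)
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  attr(x, "converged") <- FALSE
  x
}
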