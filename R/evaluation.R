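#' Target registration error (TRE)
#'
#' Each moving-frame landmark is propagated into the deformed frame by
#' numerically inverting the backward-mapping displacement field
#' (fixed-point iteration, tolerance 1e-3 voxel, at most 50 iterations) and
#' the TRE is the Euclidean distance in mm to the matching target landmark.
#' With a zero field this reduces to the plain inter-set distance.
#'
#' @param moving_landmarks,target_landmarks [landmark_set()]s with matching
#'   labels.
#' @param d A [dvf()] on the image grid.
#' @param spacing Voxel spacing (mm) of the image grid.
#' @param origin Grid origin in mm.
#' @return Named numeric vector of per-landmark TREs in mm. Landmarks whose
#'   inversion did not converge are flagged in the `nonconverged` attribute.
#' @export
tre <- function(moving_landmarks, target_landmarks, d,
                spacing = d$spacing, origin = c(0, 0, 0)) {
  stopifnot(inherits(moving_landmarks, "dirgan_landmarks"),
            inherits(target_landmarks, "dirgan_landmarks"),
            inherits(d, "dirgan_dvf"))
  if (!setequal(moving_landmarks$labels, target_landmarks$labels))
    stop("landmark labels do not match between the two sets")
  labs <- moving_landmarks$labels
  ref <- list(spacing = spacing, origin = origin)
  out <- numeric(length(labs))
  names(out) <- labs
  bad <- character()
  for (i in seq_along(labs)) {
    p_mm <- moving_landmarks$coords[labs[i], ]
    q_mm <- target_landmarks$coords[labs[i], ]
    p_vox <- as.numeric(mm_to_voxel(p_mm, ref))
    # the moving landmark appears in the deformed frame at x with
    # x + u(x) = p  (backward mapping)
    x_vox <- invert_dvf_at(d, p_vox)
    if (isFALSE(attr(x_vox, "converged"))) bad <- c(bad, labs[i])
    x_mm <- as.numeric(voxel_to_mm(matrix(as.numeric(x_vox), 1, 3), ref))
    out[i] <- sqrt(sum((x_mm - q_mm)^2))
  }
  if (length(bad)) attr(out, "nonconverged") <- bad
  out
}

#' Masked mean absolute error in HU
#'
#' Mean over mask voxels of `|Id - It|`; the mask is conventionally the
#' body region (HU > -300), see [body_mask()].
#'
#' @param Id,It [volume()]s (or arrays) of identical shape.
#' @param m A non-empty [mask()].
#' @return MAE in HU.
#' @export
mae <- function(Id, It, m) {
  a <- as_field(Id); b <- as_field(It)
  stopifnot(inherits(m, "dirgan_mask"))
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(m$data)))
    stop("volumes and mask must have identical shape")
  if (!any(m$data)) stop("empty mask: MAE is undefined")
  mean(abs(a[m$data] - b[m$data]))
}

#' Masked normalized cross-correlation
#'
#' Zero-mean NCC restricted to the mask voxels (means and sums over the
#' mask only); the mask is conventionally the body region.
#'
#' @inheritParams mae
#' @return A number in \[-1, 1\].
#' @export
ncc_metric <- function(Id, It, m) {
  a <- as_field(Id); b <- as_field(It)
  stopifnot(inherits(m, "dirgan_mask"))
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(m$data)))
    stop("volumes and mask must have identical shape")
  if (!any(m$data)) stop("empty mask: NCC is undefined")
  ncc_with_grad(a[m$data], b[m$data], want_grad = FALSE)$value
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A & B| / (|A| + |B|)`; used on the bony-structure masks
#' ([bone_mask()], HU > 300) of the deformed and target volumes.
#'
#' @param mask_d,mask_t [mask()]s of identical shape, not both empty.
#' @return A number in \[0, 1\].
#' @export
dsc <- function(mask_d, mask_t) {
  stopifnot(inherits(mask_d, "dirgan_mask"), inherits(mask_t, "dirgan_mask"))
  if (!all(dim(mask_d$data) == dim(mask_t$data)))
    stop("masks must have identical shape")
  na <- sum(mask_d$data); nb <- sum(mask_t$data)
  if (na + nb == 0) stop("both masks empty: DSC is undefined")
  2 * sum(mask_d$data & mask_t$data) / (na + nb)
}

#' Displacement-field regularity report
#'
#' Summarizes the Jacobian determinant of the deformation over the body
#' mask: `pct_nonpositive` is the fraction of body voxels with det <= 0
#' (folding), and `jacobian_index` is a configurable scalar summary of the
#' determinant field, by default its standard deviation within the mask
#' (0 for any uniform — including identity — deformation). The summary
#' choice is recorded in the returned metadata.
#'
#' @param d A [dvf()].
#' @param body A non-empty [mask()] on the same grid.
#' @param index_fun Summary function applied to the in-mask determinant
#'   values (default [stats::sd()] with a degenerate-case value of 0).
#' @return List with `jacobian_index`, `pct_nonpositive` and `index_type`.
#' @export
regularity_report <- function(d, body, index_fun = NULL) {
  stopifnot(inherits(d, "dirgan_dvf"), inherits(body, "dirgan_mask"))
  if (!all(dim(body$data) == dvf_dims(d)))
    stop("mask dims must match the DVF grid")
  if (!any(body$data)) stop("empty mask: regularity report is undefined")
  jd <- jacobian_determinant(d)
  vals <- jd[body$data]
  if (is.null(index_fun)) {
    idx <- if (length(vals) > 1) stats::sd(vals) else 0
    itype <- "sd_detJ_in_mask"
  } else {
    idx <- index_fun(vals)
    itype <- "custom"
  }
  list(jacobian_index = idx,
       pct_nonpositive = sum(vals <= 0) / length(vals),
       index_type = itype)
}

#' Absolute intensity difference along a grid line
#'
#' Samples `|Id - It|` along one grid line, e.g. in the anterior-posterior
#' direction, for profile plots of residual misalignment.
#'
#' @param Id,It [volume()]s (or arrays) of identical shape.
#' @param line_axis Axis to walk along (1, 2 or 3).
#' @param line_position 1-based indices of the two fixed axes, in
#'   increasing axis order.
#' @return Numeric vector of |differences| in HU along the line.
#' @export
difference_profile <- function(Id, It, line_axis, line_position) {
  a <- as_field(Id); b <- as_field(It)
  if (!all(dim(a) == dim(b))) stop("volumes must have identical shape")
  dims <- dim(a)
  line_axis <- as.integer(line_axis)
  if (!line_axis %in% 1:3) stop("line_axis must be 1, 2 or 3")
  pos <- as.integer(line_position)
  if (length(pos) != 2) stop("line_position must give the two fixed indices")
  other <- setdiff(1:3, line_axis)
  if (any(pos < 1) || any(pos > dims[other]))
    stop("line position out of bounds")
  idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  idx[[other[1]]] <- pos[1]
  idx[[other[2]]] <- pos[2]
  abs(a[idx[[1]], idx[[2]], idx[[3]]] - b[idx[[1]], idx[[2]], idx[[3]]])
}

#' Full registration evaluation
#'
#' Computes the quantitative suite for a registration result: per-landmark
#' TRE, body-masked MAE and NCC, bony Dice, and the Jacobian regularity
#' report, using the standard HU thresholds (body > -300, bone > 300).
#'
#' @param deformed,target [volume()]s.
#' @param final_dvf The predicted [dvf()].
#' @param landmarks_moving,landmarks_target Optional [landmark_set()]s.
#' @return Nested list of metrics.
#' @export
evaluate_registration <- function(deformed, target, final_dvf,
                                  landmarks_moving = NULL,
                                  landmarks_target = NULL) {
  body <- body_mask(target)
  out <- list(
    mae_hu = mae(deformed, target, body),
    ncc = ncc_metric(deformed, target, body),
    dsc_bone = dsc(bone_mask(deformed), bone_mask(target)),
    regularity = regularity_report(final_dvf, body))
  if (!is.null(landmarks_moving) && !is.null(landmarks_target)) {
    t <- tre(landmarks_moving, landmarks_target, final_dvf,
             spacing = target$spacing)
    out$tre_mm <- t
    out$tre_mean_mm <- mean(t)
  }
  out
}
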