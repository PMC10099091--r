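#' Loss weights of the registration objective
#'
#' The total generator objective is
#' `alpha * SIM + beta * ADV + gamma * R(DVF)` with
#' `SIM = [1 - NCC(MIND(Id), MIND(It))] + delta * GD(MIND(Id), MIND(It))`
#' and `R(DVF) = mu1 * mean|grad u|^2 + mu2 * mean|lap u|^2`. Defaults are
#' the empirically set values alpha = 200, beta = 1, gamma = 10, delta = 5,
#' mu1 = 1, mu2 = 0.5.
#'
#' @param alpha Similarity weight.
#' @param beta Adversarial weight.
#' @param gamma Regularization weight.
#' @param delta Gradient-difference weight inside the similarity loss.
#' @param mu1,mu2 First/second derivative weights of the regularizer.
#' @return A `dirgan_loss_weights` list.
#' @export
loss_weights <- function(alpha = 200, beta = 1, gamma = 10, delta = 5,
                         mu1 = 1, mu2 = 0.5) {
  w <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
            mu1 = mu1, mu2 = mu2)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "dirgan_loss_weights")
}

as_field <- function(x) {
  if (inherits(x, "dirgan_volume")) return(x$data)
  if (inherits(x, "dirgan_mind")) return(x$values)
  x
}

#' Global normalized cross-correlation
#'
#' Zero-mean NCC pooled over all elements (all channels jointly for
#' multi-channel descriptor fields):
#' `sum((a - mean a)(b - mean b)) / sqrt(sum((a - mean a)^2) sum((b - mean b)^2))`.
#'
#' @param a,b Arrays (or volumes / MIND fields) of identical shape,
#'   non-constant.
#' @return A number in \[-1, 1\].
#' @export
ncc_score <- function(a, b) {
  ncc_with_grad(as_field(a), as_field(b), want_grad = FALSE)$value
}

ncc_with_grad <- function(a, b, want_grad = TRUE) {
  if (!all(dim(a) == dim(b))) stop("NCC inputs must have identical shape")
  ac <- a - mean(a)
  bc <- b - mean(b)
  sa <- sum(ac * ac)
  sb <- sum(bc * bc)
  if (sa == 0 || sb == 0)
    stop("NCC is undefined for a constant (zero-variance) input")
  den <- sqrt(sa * sb)
  r <- sum(ac * bc) / den
  ga <- NULL
  if (want_grad) ga <- bc / den - r * ac / sa
  list(value = r, ga = ga)
}

#' Gradient-difference loss
#'
#' Mean over the three axes of the mean squared difference of the spatial
#' derivatives of `a` and `b` (central differences, one-sided at borders;
#' multi-channel fields pool over channels).
#'
#' @param a,b Arrays (or volumes / MIND fields) of identical shape.
#' @return Non-negative number; 0 iff the derivatives agree.
#' @export
gradient_difference <- function(a, b) {
  gd_with_grad(as_field(a), as_field(b), want_grad = FALSE)$value
}

gd_with_grad <- function(a, b, want_grad = TRUE) {
  if (!all(dim(a) == dim(b))) stop("GD inputs must have identical shape")
  d <- dim(a)
  n <- length(a)
  val <- 0
  ga <- if (want_grad) array(0, d) else NULL
  for (ax in 1:3) {
    diffd <- axis_diff(a, ax) - axis_diff(b, ax)
    val <- val + mean(diffd^2)
    if (want_grad) ga <- ga + axis_diff(diffd, ax, adjoint = TRUE) * (2 / n)
  }
  if (want_grad) ga <- ga / 3
  list(value = val / 3, ga = ga)
}

#' MIND-based image similarity loss
#'
#' `SIM(Id, It) = [1 - NCC(MIND(Id), MIND(It))] + delta * GD(MIND(Id), MIND(It))`.
#' Because both terms act on the descriptor, the loss is invariant to
#' affine HU rescaling between fractions and is 0 when the two volumes have
#' identical descriptors.
#'
#' @param Id,It Deformed and target [volume()]s (or arrays) of equal shape.
#' @param delta GD weight inside the loss (default 5).
#' @param patch_radius,offsets,epsilon_rel MIND parameters, see [mind()].
#' @return Non-negative number.
#' @export
similarity_loss <- function(Id, It, delta = 5, patch_radius = 1L,
                            offsets = mind_offsets_6(), epsilon_rel = 1e-6) {
  Id <- as_field(Id); It <- as_field(It)
  if (!all(dim(Id) == dim(It))) stop("volumes must have identical shape")
  md <- mind_forward(Id, patch_radius, offsets, epsilon_rel)$N
  mt <- mind_forward(It, patch_radius, offsets, epsilon_rel)$N
  (1 - ncc_with_grad(md, mt, want_grad = FALSE)$value) +
    delta * gd_with_grad(md, mt, want_grad = FALSE)$value
}

# Similarity loss plus its gradient with respect to the deformed image.
# mind_t is the precomputed mind_forward(...)$N of the target.
similarity_with_grad <- function(Id_arr, mind_t, delta, patch_radius = 1L,
                                 offsets = mind_offsets_6(),
                                 epsilon_rel = 1e-6) {
  fwd <- mind_forward(Id_arr, patch_radius, offsets, epsilon_rel)
  nccr <- ncc_with_grad(fwd$N, mind_t)
  gdr <- gd_with_grad(fwd$N, mind_t)
  value <- (1 - nccr$value) + delta * gdr$value
  gN <- -nccr$ga + delta * gdr$ga
  list(value = value, gId = mind_backward(fwd, gN))
}

#' Displacement-field regularization
#'
#' `mu1 * mean(|grad u|^2) + mu2 * mean(|lap u|^2)`: the squared first
#' derivatives (central differences, one-sided at borders) and the squared
#' discrete Laplacian per component (zero at border planes, where the second
#' derivative is undefined), both summed over components and averaged over
#' voxels. Enforces general smoothness of the predicted field.
#'
#' @param d A [dvf()] (or raw 4D displacement array) with dims >= 3.
#' @param mu1,mu2 Term weights (defaults 1 and 0.5).
#' @return Non-negative number.
#' @export
dvf_regularization <- function(d, mu1 = 1, mu2 = 0.5) {
  reg_with_grad(if (inherits(d, "dirgan_dvf")) d$u else d, mu1, mu2,
                want_grad = FALSE)$value
}

reg_with_grad <- function(u, mu1, mu2, want_grad = TRUE) {
  d <- dim(u)
  dims <- d[1:3]
  if (any(dims < 3)) stop("regularizer needs >= 3 voxels along every axis")
  nvox <- prod(dims)
  val <- 0
  gu <- if (want_grad) array(0, d) else NULL
  lap <- array(0, d)
  for (ax in 1:3) {
    g1 <- axis_diff(u, ax)
    val <- val + mu1 * sum(g1^2) / nvox
    if (want_grad)
      gu <- gu + mu1 * 2 / nvox * axis_diff(g1, ax, adjoint = TRUE)
    lap <- lap + axis_diff(u, ax, order = 2)
  }
  val <- val + mu2 * sum(lap^2) / nvox
  if (want_grad) {
    glap <- mu2 * 2 / nvox * lap
    for (ax in 1:3)
      gu <- gu + axis_diff(glap, ax, order = 2, adjoint = TRUE)
  }
  list(value = val, gu = gu)
}

#' Adversarial losses of the GAN pair
#'
#' Binary cross entropy over patch-level discriminator score maps:
#' the discriminator is pushed to score real images towards 1 and deformed
#' images towards 0 (the two BCE terms averaged), while the generator's
#' adversarial term pushes the deformed image's scores towards 1.
#'
#' @param disc_score_real,disc_score_fake Arrays of scores strictly inside
#'   (0, 1).
#' @return List with `gen_loss` and `disc_loss`.
#' @export
adversarial_losses <- function(disc_score_real, disc_score_fake) {
  r <- as.numeric(disc_score_real)
  f <- as.numeric(disc_score_fake)
  if (any(r <= 0 | r >= 1) || any(f <= 0 | f >= 1))
    stop("discriminator scores must lie strictly inside (0, 1)")
  list(gen_loss = mean(-log(f)),
       disc_loss = 0.5 * (mean(-log(r)) + mean(-log(1 - f))))
}

#' Total generator objective
#'
#' `alpha * SIM(Id, It) + beta * ADV + gamma * R(dvf)` with the components
#' as in [similarity_loss()], [adversarial_losses()] and
#' [dvf_regularization()].
#'
#' @param Id,It Deformed and target [volume()]s.
#' @param d The predicted [dvf()].
#' @param w A [loss_weights()].
#' @param disc_score_fake Discriminator scores of the deformed image.
#' @return The scalar total, with a `components` attribute listing the
#'   unweighted similarity, adversarial and regularization terms.
#' @export
total_generator_loss <- function(Id, It, d, w = loss_weights(),
                                 disc_score_fake) {
  sim <- similarity_loss(Id, It, delta = w$delta)
  adv <- if (w$beta > 0) {
    mean(-log(pmin(pmax(as.numeric(disc_score_fake), 1e-12), 1 - 1e-12)))
  } else 0
  reg <- dvf_regularization(d, w$mu1, w$mu2)
  total <- w$alpha * sim + w$beta * adv + w$gamma * reg
  attr(total, "components") <- list(similarity = sim, adversarial = adv,
                                    regularization = reg)
  total
}
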