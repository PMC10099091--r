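# Hand-written 3D conv networks: explicit forward/backward chains over the
# Rcpp kernels. Parameters are nested lists of plain numeric vectors, so the
# optimizer and checkpoint IO stay trivial and fully deterministic.

HU_SCALE <- 1000  # input normalization: HU / 1000

norm_hu <- function(x) x / HU_SCALE

conv_init <- function(cin, cout, k, gain = 1, zero = FALSE) {
  nw <- cout * cin * k^3
  w <- if (zero) numeric(nw)
  else stats::rnorm(nw, sd = gain * sqrt(2 / (cin * k^3)))
  list(w = w, b = numeric(cout), cin = cin, cout = cout, k = k)
}

conv_fwd <- function(x, par) {
  d <- dim(x)
  y <- cpp_conv3d_fwd(x, as.integer(d[1:3]), as.integer(d[4]),
                      par$w, par$b, as.integer(par$cout), as.integer(par$k))
  dim(y) <- c(d[1:3], par$cout)
  y
}

conv_bwd <- function(x, gy, par) {
  d <- dim(x)
  r <- cpp_conv3d_bwd(x, gy, as.integer(d[1:3]),
                      as.integer(d[4]), as.integer(par$cout), par$w,
                      as.integer(par$k))
  gx <- r$gx
  dim(gx) <- d
  list(gx = gx, gw = r$gw, gb = r$gb)
}

lrelu_fwd <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
lrelu_bwd <- function(x, gy, slope) gy * ((x > 0) + slope * (x <= 0))

sigmoid <- function(x) 1 / (1 + exp(-x))

pool_fwd <- function(x) {
  d <- dim(x)
  r <- cpp_maxpool3d_fwd(x, as.integer(d[1:3]), as.integer(d[4]))
  y <- r$y
  dim(y) <- c(d[1:3] %/% 2L, d[4])
  list(y = y, argmax = r$argmax, dims = d)
}

pool_bwd <- function(p, gy) {
  gx <- cpp_maxpool3d_bwd(gy, p$argmax,
                          as.integer(p$dims[1:3]), as.integer(p$dims[4]))
  dim(gx) <- p$dims
  gx
}

resize_fwd <- function(x, odims) {
  d <- dim(x)
  y <- cpp_resize3d(x, as.integer(d[1:3]), as.integer(d[4]),
                    as.integer(odims))
  dim(y) <- c(odims, d[4])
  y
}

resize_bwd <- function(gy, idims) {
  d <- dim(gy)
  gx <- cpp_resize3d_adjoint(gy, as.integer(d[1:3]),
                             as.integer(d[4]), as.integer(idims))
  dim(gx) <- c(idims, d[4])
  gx
}

#' Generator configuration
#'
#' The generator is an encoder with two max-pooling downsamples and a
#' quarter-resolution decoding stage: both skip connections are pooled to
#' the coarse grid, gated by additive attention against the bottleneck
#' features, concatenated and convolved, and a zero-initialized 1x1x1
#' linear head emits the 3-component displacement field at 1/4 resolution,
#' which is trilinearly upsampled (with displacement rescaling) to the
#' input grid. Producing the field on the coarse grid and upsampling is
#' what keeps the prediction structurally smooth; an untrained network
#' performs the identity registration exactly. Input grids must be
#' divisible by 4 along every axis.
#'
#' @param base_filters Channel width of the first encoder level.
#' @param lrelu_slope LeakyReLU negative slope.
#' @param dvf_scale Fixed multiplier applied to the linear head's output.
#'   The head is zero-initialized, and Adam moves each weight by at most
#'   roughly one learning rate per step, so the attainable displacement
#'   after n steps scales with `dvf_scale * lr * n`; the multiplier makes
#'   multi-voxel displacements reachable in short runs without touching
#'   the identity-at-initialization property.
#' @return A `dirgan_gen_config` list.
#' @export
generator_config <- function(base_filters = 8, lrelu_slope = 0.2,
                             dvf_scale = 8) {
  stopifnot(base_filters >= 1, dvf_scale > 0)
  structure(list(base_filters = as.integer(base_filters),
                 lrelu_slope = lrelu_slope, dvf_scale = dvf_scale),
            class = "dirgan_gen_config")
}

#' Initialize generator parameters
#'
#' He-initialized convolution stacks; the DVF head is zero-initialized so
#' the initial prediction is exactly the zero field.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed for the weight draw.
#' @return Nested parameter list.
#' @export
generator_init <- function(cfg = generator_config(), seed = 1) {
  f <- cfg$base_filters
  with_seed(seed, list(
    enc1a = conv_init(2, f, 3), enc1b = conv_init(f, f, 3),
    enc2a = conv_init(f, 2 * f, 3), enc2b = conv_init(2 * f, 2 * f, 3),
    bota = conv_init(2 * f, 4 * f, 3), botb = conv_init(4 * f, 4 * f, 3),
    ag2 = list(wx = conv_init(2 * f, f, 1), wg = conv_init(4 * f, f, 1),
               psi = conv_init(f, 1, 1)),
    ag1 = list(wx = conv_init(f, f, 1), wg = conv_init(4 * f, f, 1),
               psi = conv_init(f, 1, 1)),
    deca = conv_init(7 * f, 2 * f, 3), decb = conv_init(2 * f, 2 * f, 3),
    head = conv_init(2 * f, 3, 1, zero = TRUE)))
}

# Additive attention gate: skip features multiplied by a sigmoid map derived
# from skip + gating features (both already on the same grid).
attention_fwd <- function(skip, gate, par) {
  q <- conv_fwd(skip, par$wx) + conv_fwd(gate, par$wg)
  qr <- pmax(q, 0)
  s <- sigmoid(conv_fwd(qr, par$psi))   # dims x 1
  smap <- s[, , , 1]
  gated <- skip
  for (ch in seq_len(dim(skip)[4])) gated[, , , ch] <- skip[, , , ch] * smap
  list(gated = gated, q = q, qr = qr, s = s, skip = skip, gate = gate)
}

attention_bwd <- function(cache, g_gated, par) {
  smap <- cache$s[, , , 1]
  g_skip <- g_gated
  g_s <- array(0, dim(cache$s))
  acc <- 0
  for (ch in seq_len(dim(cache$skip)[4])) {
    g_skip[, , , ch] <- g_gated[, , , ch] * smap
    acc <- acc + g_gated[, , , ch] * cache$skip[, , , ch]
  }
  g_s[, , , 1] <- acc * cache$s[, , , 1] * (1 - cache$s[, , , 1])
  bp <- conv_bwd(cache$qr, g_s, par$psi)
  g_q <- bp$gx * (cache$q > 0)
  bx <- conv_bwd(cache$skip, g_q, par$wx)
  bg <- conv_bwd(cache$gate, g_q, par$wg)
  list(g_skip = g_skip + bx$gx, g_gate = bg$gx,
       grads = list(wx = list(gw = bx$gw, gb = bx$gb),
                    wg = list(gw = bg$gw, gb = bg$gb),
                    psi = list(gw = bp$gw, gb = bp$gb)))
}

#' Generator forward pass
#'
#' Takes the 2-channel concatenation of the (normalized) moving and target
#' grids and predicts a 3-component displacement field in voxel units on
#' the input grid (generated at 1/4 resolution and upsampled).
#' Deterministic for fixed parameters.
#'
#' @param moving,target 3D arrays (already intensity-normalized) of equal
#'   shape, dims divisible by 4.
#' @param params Parameters from [generator_init()].
#' @param cfg The matching [generator_config()].
#' @param keep_cache Keep all intermediates for [generator_backward()].
#' @return List with `u` (dims x 3 displacement array) and (optionally)
#'   `cache`.
#' @export
generator_forward <- function(moving, target, params,
                              cfg = generator_config(), keep_cache = FALSE) {
  if (!all(dim(moving) == dim(target)))
    stop("moving and target must have identical shape")
  dims <- dim(moving)
  if (any(dims %% 4 != 0))
    stop("generator input dims must be divisible by 4, got ",
         paste(dims, collapse = "x"))
  sl <- cfg$lrelu_slope
  cc <- list(dims = dims)
  x0 <- array(c(moving, target), c(dims, 2))
  cc$x0 <- x0
  cc$e1a_pre <- conv_fwd(x0, params$enc1a); e1a <- lrelu_fwd(cc$e1a_pre, sl)
  cc$e1a <- e1a
  cc$e1b_pre <- conv_fwd(e1a, params$enc1b); e1b <- lrelu_fwd(cc$e1b_pre, sl)
  cc$e1b <- e1b
  cc$p1 <- pool_fwd(e1b)
  cc$e2a_pre <- conv_fwd(cc$p1$y, params$enc2a); e2a <- lrelu_fwd(cc$e2a_pre, sl)
  cc$e2a <- e2a
  cc$e2b_pre <- conv_fwd(e2a, params$enc2b); e2b <- lrelu_fwd(cc$e2b_pre, sl)
  cc$e2b <- e2b
  cc$p2 <- pool_fwd(e2b)
  cc$ba_pre <- conv_fwd(cc$p2$y, params$bota); ba <- lrelu_fwd(cc$ba_pre, sl)
  cc$ba <- ba
  cc$bb_pre <- conv_fwd(ba, params$botb); bb <- lrelu_fwd(cc$bb_pre, sl)
  cc$bb <- bb
  # both skips pooled onto the coarse grid and attention-gated by the
  # bottleneck context
  cc$s1p <- pool_fwd(cc$p1$y)            # f channels at 1/4
  cc$ag2 <- attention_fwd(cc$p2$y, bb, params$ag2)
  cc$ag1 <- attention_fwd(cc$s1p$y, bb, params$ag1)
  f4 <- dim(bb)[4]
  qdims <- dim(bb)[1:3]
  cat0 <- array(c(bb, cc$ag2$gated, cc$ag1$gated),
                c(qdims, f4 + dim(cc$ag2$gated)[4] + dim(cc$ag1$gated)[4]))
  cc$cat0 <- cat0
  cc$da_pre <- conv_fwd(cat0, params$deca); da <- lrelu_fwd(cc$da_pre, sl)
  cc$da <- da
  cc$db_pre <- conv_fwd(da, params$decb); db <- lrelu_fwd(cc$db_pre, sl)
  cc$db <- db
  uq <- conv_fwd(db, params$head) * cfg$dvf_scale
  cc$qdims <- qdims
  u <- resize_fwd(uq, dims)
  scale <- dims / qdims
  for (ax in 1:3) u[, , , ax] <- u[, , , ax] * scale[ax]
  list(u = u, cache = if (keep_cache) cc else NULL)
}

#' Generator backward pass
#'
#' Backpropagates a gradient with respect to the predicted (full-grid)
#' displacement field through the whole network, returning parameter
#' gradients in the same nested shape as the parameters.
#'
#' @param cache Cache from [generator_forward()] with `keep_cache = TRUE`.
#' @param gu Gradient array (dims x 3) with respect to the output field.
#' @param params,cfg As in [generator_forward()].
#' @return Nested gradient list.
#' @export
generator_backward <- function(cache, gu, params, cfg = generator_config()) {
  sl <- cfg$lrelu_slope
  g <- list()
  dims <- cache$dims
  qdims <- cache$qdims
  scale <- dims / qdims
  gs <- gu
  for (ax in 1:3) gs[, , , ax] <- gs[, , , ax] * scale[ax]
  g_uq <- resize_bwd(gs, qdims) * cfg$dvf_scale
  bh <- conv_bwd(cache$db, g_uq, params$head)
  g$head <- list(gw = bh$gw, gb = bh$gb)
  gdb <- lrelu_bwd(cache$db_pre, bh$gx, sl)
  bdb <- conv_bwd(cache$da, gdb, params$decb)
  g$decb <- list(gw = bdb$gw, gb = bdb$gb)
  gda <- lrelu_bwd(cache$da_pre, bdb$gx, sl)
  bda <- conv_bwd(cache$cat0, gda, params$deca)
  g$deca <- list(gw = bda$gw, gb = bda$gb)
  f4 <- dim(cache$bb)[4]
  c2 <- dim(cache$ag2$gated)[4]
  g_bb <- bda$gx[, , , seq_len(f4), drop = FALSE]
  g_gated2 <- bda$gx[, , , f4 + seq_len(c2), drop = FALSE]
  g_gated1 <- bda$gx[, , , -(seq_len(f4 + c2)), drop = FALSE]
  ab2 <- attention_bwd(cache$ag2, g_gated2, params$ag2)
  g$ag2 <- ab2$grads
  ab1 <- attention_bwd(cache$ag1, g_gated1, params$ag1)
  g$ag1 <- ab1$grads
  g_bb <- g_bb + ab2$g_gate + ab1$g_gate
  g_s1p <- ab1$g_skip
  g_p2 <- ab2$g_skip
  gbb <- lrelu_bwd(cache$bb_pre, g_bb, sl)
  bbb <- conv_bwd(cache$ba, gbb, params$botb)
  g$botb <- list(gw = bbb$gw, gb = bbb$gb)
  gba <- lrelu_bwd(cache$ba_pre, bbb$gx, sl)
  bba <- conv_bwd(cache$p2$y, gba, params$bota)
  g$bota <- list(gw = bba$gw, gb = bba$gb)
  g_e2b <- pool_bwd(cache$p2, bba$gx + g_p2)
  g_e2b <- lrelu_bwd(cache$e2b_pre, g_e2b, sl)
  b2bE <- conv_bwd(cache$e2a, g_e2b, params$enc2b)
  g$enc2b <- list(gw = b2bE$gw, gb = b2bE$gb)
  g_e2a <- lrelu_bwd(cache$e2a_pre, b2bE$gx, sl)
  b2aE <- conv_bwd(cache$p1$y, g_e2a, params$enc2a)
  g$enc2a <- list(gw = b2aE$gw, gb = b2aE$gb)
  g_p1 <- b2aE$gx + pool_bwd(cache$s1p, g_s1p)
  g_e1b <- pool_bwd(cache$p1, g_p1)
  g_e1b <- lrelu_bwd(cache$e1b_pre, g_e1b, sl)
  b1bE <- conv_bwd(cache$e1a, g_e1b, params$enc1b)
  g$enc1b <- list(gw = b1bE$gw, gb = b1bE$gb)
  g_e1a <- lrelu_bwd(cache$e1a_pre, b1bE$gx, sl)
  b1aE <- conv_bwd(cache$x0, g_e1a, params$enc1a)
  g$enc1a <- list(gw = b1aE$gw, gb = b1aE$gb)
  g
}

#' Discriminator configuration
#' @param base_filters Channel width of the first convolution.
#' @param lrelu_slope LeakyReLU negative slope.
#' @return A `dirgan_disc_config` list.
#' @export
discriminator_config <- function(base_filters = 8, lrelu_slope = 0.2) {
  structure(list(base_filters = as.integer(base_filters),
                 lrelu_slope = lrelu_slope),
            class = "dirgan_disc_config")
}

#' Initialize discriminator parameters
#' @param cfg A [discriminator_config()].
#' @param seed Integer seed.
#' @return Nested parameter list.
#' @export
discriminator_init <- function(cfg = discriminator_config(), seed = 1) {
  f <- cfg$base_filters
  with_seed(seed, list(
    c1 = conv_init(1, f, 3), c2 = conv_init(f, 2 * f, 3),
    c3 = conv_init(2 * f, 2 * f, 3), head = conv_init(2 * f, 1, 1)))
}

#' Discriminator forward pass
#'
#' Fully convolutional: three 3x3x3 convolutions with two max-poolings and
#' a sigmoid 1x1x1 head, yielding a patch-level score map strictly inside
#' (0, 1) at 1/4 resolution.
#'
#' @param image 3D array (normalized intensities).
#' @param params Parameters from [discriminator_init()].
#' @param cfg The matching [discriminator_config()].
#' @param keep_cache Keep intermediates for the backward pass.
#' @return List with `scores` (4D array, one channel) and optional `cache`.
#' @export
discriminator_forward <- function(image, params,
                                  cfg = discriminator_config(),
                                  keep_cache = FALSE) {
  dims <- dim(image)
  if (length(dims) != 3) stop("discriminator expects a single-channel 3D grid")
  if (any(dims %% 4 != 0))
    stop("discriminator input dims must be divisible by 4")
  sl <- cfg$lrelu_slope
  cc <- list()
  x0 <- array(image, c(dims, 1))
  cc$x0 <- x0
  cc$c1_pre <- conv_fwd(x0, params$c1); h1 <- lrelu_fwd(cc$c1_pre, sl)
  cc$h1 <- h1
  cc$p1 <- pool_fwd(h1)
  cc$c2_pre <- conv_fwd(cc$p1$y, params$c2); h2 <- lrelu_fwd(cc$c2_pre, sl)
  cc$h2 <- h2
  cc$p2 <- pool_fwd(h2)
  cc$c3_pre <- conv_fwd(cc$p2$y, params$c3); h3 <- lrelu_fwd(cc$c3_pre, sl)
  cc$h3 <- h3
  logits <- conv_fwd(h3, params$head)
  cc$scores <- sigmoid(logits)
  list(scores = cc$scores, cache = if (keep_cache) cc else NULL)
}

# Backward pass; g_scores is the gradient wrt the sigmoid scores. Returns
# parameter gradients and the gradient wrt the input image (needed for the
# generator's adversarial term).
discriminator_backward <- function(cache, g_scores, params,
                                   cfg = discriminator_config()) {
  sl <- cfg$lrelu_slope
  g <- list()
  g_logit <- g_scores * cache$scores * (1 - cache$scores)
  bh <- conv_bwd(cache$h3, g_logit, params$head)
  g$head <- list(gw = bh$gw, gb = bh$gb)
  g3 <- lrelu_bwd(cache$c3_pre, bh$gx, sl)
  b3 <- conv_bwd(cache$p2$y, g3, params$c3)
  g$c3 <- list(gw = b3$gw, gb = b3$gb)
  g2 <- pool_bwd(cache$p2, b3$gx)
  g2 <- lrelu_bwd(cache$c2_pre, g2, sl)
  b2 <- conv_bwd(cache$p1$y, g2, params$c2)
  g$c2 <- list(gw = b2$gw, gb = b2$gb)
  g1 <- pool_bwd(cache$p1, b2$gx)
  g1 <- lrelu_bwd(cache$c1_pre, g1, sl)
  b1 <- conv_bwd(cache$x0, g1, params$c1)
  g$c1 <- list(gw = b1$gw, gb = b1$gb)
  list(grads = g, g_input = b1$gx[, , , 1])
}

#' Predict a displacement field for a volume pair
#'
#' Normalizes the pair, runs the generator and wraps the result as a
#' [dvf()] on the volume grid.
#'
#' @param moving,target [volume()]s of equal shape.
#' @param params,cfg Generator parameters and config.
#' @return A [dvf()].
#' @export
predict_dvf <- function(moving, target, params, cfg = generator_config()) {
  stopifnot(inherits(moving, "dirgan_volume"), inherits(target, "dirgan_volume"))
  out <- generator_forward(norm_hu(moving$data), norm_hu(target$data),
                           params, cfg)
  dvf(out$u, spacing = moving$spacing)
}

#' Count of learnable parameters
#' @param params Nested parameter list.
#' @return Integer parameter count.
#' @export
n_params <- function(params) {
  if (is.list(params)) {
    if (!is.null(params$w)) return(length(params$w) + length(params$b))
    return(sum(vapply(params, n_params, 0)))
  }
  0
}

# Run a seeded computation without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
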