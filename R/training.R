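#' Training configuration
#'
#' @param weights A [loss_weights()].
#' @param learning_rate Adam learning rate (default 2e-4).
#' @param learning_rate_local Optional separate Adam rate for the local
#'   (patch) stage; defaults to `learning_rate`. The local stage corrects
#'   sub-voxel residuals and benefits from a gentler rate than the global
#'   stage.
#' @param adam_betas Adam (beta1, beta2); (0.5, 0.999) is the usual GAN
#'   setting.
#' @param iterations_global,iterations_local Generator update counts for
#'   the global and local stages.
#' @param global_downsample_shape Grid the global stage trains on (whole
#'   volumes resampled here; dims divisible by 4).
#' @param patch_shape,overlap Patch tiling of the local stage; defaults are
#'   the 64^3 / (32, 32, 48) production values.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param disc_steps_per_gen_step Discriminator updates per generator
#'   update.
#' @param gen_filters,disc_filters Base channel widths of the two networks.
#' @return A `dirgan_train_config` list.
#' @export
train_config <- function(weights = loss_weights(), learning_rate = 2e-4,
                         learning_rate_local = NULL,
                         adam_betas = c(0.5, 0.999),
                         iterations_global = 200, iterations_local = 200,
                         global_downsample_shape = c(64, 64, 48),
                         patch_shape = c(64, 64, 64),
                         overlap = c(32, 32, 48),
                         seed = 1, disc_steps_per_gen_step = 1,
                         gen_filters = 8, disc_filters = 8) {
  stopifnot(iterations_global >= 1, iterations_local >= 1)
  if (any(as.integer(global_downsample_shape) %% 4 != 0))
    stop("global_downsample_shape dims must be divisible by 4")
  if (is.null(learning_rate_local)) learning_rate_local <- learning_rate
  structure(list(weights = weights, learning_rate = learning_rate,
                 learning_rate_local = learning_rate_local,
                 adam_betas = adam_betas,
                 iterations_global = as.integer(iterations_global),
                 iterations_local = as.integer(iterations_local),
                 global_downsample_shape = as.integer(global_downsample_shape),
                 patch_shape = as.integer(patch_shape),
                 overlap = as.integer(overlap),
                 seed = as.integer(seed),
                 disc_steps_per_gen_step = as.integer(disc_steps_per_gen_step),
                 gen_filters = as.integer(gen_filters),
                 disc_filters = as.integer(disc_filters)),
            class = "dirgan_train_config")
}

# ----------------------------------------------------------------- Adam ----

adam_new <- function(params) {
  if (is.list(params)) {
    if (!is.null(params$w))
      return(list(mw = numeric(length(params$w)), vw = numeric(length(params$w)),
                  mb = numeric(length(params$b)), vb = numeric(length(params$b))))
    return(lapply(params, adam_new))
  }
  NULL
}

# params: nested conv nodes ($w, $b); grads mirror with ($gw, $gb).
adam_step <- function(params, grads, state, lr, betas, t, eps = 1e-8) {
  if (!is.null(params$w)) {
    b1 <- betas[1]; b2 <- betas[2]
    corr <- lr * sqrt(1 - b2^t) / (1 - b1^t)
    state$mw <- b1 * state$mw + (1 - b1) * grads$gw
    state$vw <- b2 * state$vw + (1 - b2) * grads$gw^2
    params$w <- params$w - corr * state$mw / (sqrt(state$vw) + eps)
    state$mb <- b1 * state$mb + (1 - b1) * grads$gb
    state$vb <- b2 * state$vb + (1 - b2) * grads$gb^2
    params$b <- params$b - corr * state$mb / (sqrt(state$vb) + eps)
    return(list(params = params, state = state))
  }
  for (nm in names(grads)) {
    r <- adam_step(params[[nm]], grads[[nm]], state[[nm]], lr, betas, t, eps)
    params[[nm]] <- r$params
    state[[nm]] <- r$state
  }
  list(params = params, state = state)
}

clamp01 <- function(s, eps = 1e-7) pmin(pmax(s, eps), 1 - eps)

# One generator update on an (HU-valued) moving/target array pair.
# mind_t is the precomputed target descriptor. Returns updated params/state
# and the loss components.
gen_step <- function(mov_hu, tgt_hu, mind_t, gen, gstate, gcfg,
                     disc, dcfg, w, lr, betas, t) {
  gf <- generator_forward(norm_hu(mov_hu), norm_hu(tgt_hu), gen, gcfg,
                          keep_cache = TRUE)
  u <- gf$u
  dims <- dim(mov_hu)
  Id <- cpp_warp(mov_hu, as.integer(dims), u, 0L)
  dim(Id) <- dims
  sim <- similarity_with_grad(Id, mind_t, delta = w$delta)
  gId <- w$alpha * sim$gId
  adv_val <- 0
  if (w$beta > 0) {
    df <- discriminator_forward(norm_hu(Id), disc, dcfg, keep_cache = TRUE)
    s <- clamp01(df$scores)
    adv_val <- mean(-log(s))
    g_s <- -1 / (s * length(s))
    db <- discriminator_backward(df$cache, g_s, disc, dcfg)
    gId <- gId + (w$beta / HU_SCALE) * db$g_input
  }
  gu <- cpp_warp_bwd_u(mov_hu, as.integer(dims), u, gId)
  dim(gu) <- c(dims, 3)
  reg <- reg_with_grad(u, w$mu1, w$mu2)
  gu <- gu + w$gamma * reg$gu
  ggrads <- generator_backward(gf$cache, gu, gen, gcfg)
  total <- w$alpha * sim$value + w$beta * adv_val + w$gamma * reg$value
  if (!is.finite(total)) return(list(diverged = TRUE, total = total))
  up <- adam_step(gen, ggrads, gstate, lr, betas, t)
  list(diverged = FALSE, params = up$params, state = up$state,
       total = total, similarity = sim$value, adversarial = adv_val,
       regularization = reg$value, u = u, Id = Id)
}

# One discriminator update on (real = target, fake = current deformed).
disc_step <- function(Id_hu, tgt_hu, disc, dstate, dcfg, lr, betas, t) {
  fr <- discriminator_forward(norm_hu(tgt_hu), disc, dcfg, keep_cache = TRUE)
  sr <- clamp01(fr$scores)
  ff <- discriminator_forward(norm_hu(Id_hu), disc, dcfg, keep_cache = TRUE)
  sf <- clamp01(ff$scores)
  dloss <- 0.5 * (mean(-log(sr)) + mean(-log(1 - sf)))
  g_sr <- -0.5 / (sr * length(sr))
  g_sf <- 0.5 / ((1 - sf) * length(sf))
  br <- discriminator_backward(fr$cache, g_sr, disc, dcfg)
  bf <- discriminator_backward(ff$cache, g_sf, disc, dcfg)
  grads <- add_grads(br$grads, bf$grads)
  up <- adam_step(disc, grads, dstate, lr, betas, t)
  list(params = up$params, state = up$state, disc_loss = dloss)
}

add_grads <- function(a, b) {
  if (!is.null(a$gw)) return(list(gw = a$gw + b$gw, gb = a$gb + b$gb))
  out <- a
  for (nm in names(a)) out[[nm]] <- add_grads(a[[nm]], b[[nm]])
  out
}

as_pair_list <- function(pairs) {
  if (!is.null(pairs$moving)) pairs <- list(pairs)
  for (p in pairs)
    stopifnot(inherits(p$moving, "dirgan_volume"),
              inherits(p$target, "dirgan_volume"))
  pairs
}

#' Train the global registration GAN
#'
#' Trains the coarse-stage generator/discriminator pair on whole volumes
#' resampled to `cfg$global_downsample_shape`, alternating discriminator
#' and generator updates on the total objective (whole-image losses). No
#' ground-truth displacement fields are consumed: training sees image
#' pairs only. Fully reproducible from `cfg$seed`.
#'
#' @param pairs A list of `list(moving =, target =)` [volume()] pairs (or a
#'   single such pair).
#' @param cfg A [train_config()].
#' @return List with `checkpoint` (parameters + configs) and `history`
#'   (per-iteration loss data frame).
#' @export
train_global <- function(pairs, cfg = train_config()) {
  pairs <- as_pair_list(pairs)
  shape <- cfg$global_downsample_shape
  w <- cfg$weights
  small <- lapply(pairs, function(p) {
    mov <- resample_volume(p$moving, shape)
    tgt <- resample_volume(p$target, shape)
    list(mov = mov$data, tgt = tgt$data,
         mind_t = mind_forward(tgt$data)$N)
  })
  gcfg <- generator_config(cfg$gen_filters)
  dcfg <- discriminator_config(cfg$disc_filters)
  gen <- generator_init(gcfg, seed = cfg$seed)
  disc <- discriminator_init(dcfg, seed = cfg$seed + 1L)
  gstate <- adam_new(gen)
  dstate <- adam_new(disc)
  hist <- vector("list", cfg$iterations_global)
  with_seed(cfg$seed + 2L, {
    for (it in seq_len(cfg$iterations_global)) {
      p <- small[[(it - 1L) %% length(small) + 1L]]
      gs <- gen_step(p$mov, p$tgt, p$mind_t, gen, gstate, gcfg,
                     disc, dcfg, w, cfg$learning_rate, cfg$adam_betas, it)
      if (gs$diverged)
        stop("global training diverged (non-finite loss) at iteration ", it)
      gen <- gs$params; gstate <- gs$state
      dloss <- NA_real_
      if (w$beta > 0) {
        for (k in seq_len(cfg$disc_steps_per_gen_step)) {
          ds <- disc_step(gs$Id, p$tgt, disc, dstate, dcfg,
                          cfg$learning_rate, cfg$adam_betas,
                          (it - 1L) * cfg$disc_steps_per_gen_step + k)
          disc <- ds$params; dstate <- ds$state; dloss <- ds$disc_loss
        }
      }
      hist[[it]] <- data.frame(iteration = it, total = gs$total,
                               similarity = gs$similarity,
                               adversarial = gs$adversarial,
                               regularization = gs$regularization,
                               disc_loss = dloss)
    }
  })
  list(checkpoint = list(kind = "global", gen = gen, gen_cfg = gcfg,
                         disc = disc, disc_cfg = dcfg,
                         train_shape = shape, weights = w, seed = cfg$seed),
       history = do.call(rbind, hist))
}

# Global-stage displacement field for a full-resolution pair: predict on
# the training grid and upsample (with displacement rescaling) to the
# volume grid.
global_dvf_for <- function(moving, target, ckpt) {
  shape <- ckpt$train_shape
  mov_s <- resample_volume(moving, shape)
  tgt_s <- resample_volume(target, shape)
  out <- generator_forward(norm_hu(mov_s$data), norm_hu(tgt_s$data),
                           ckpt$gen, ckpt$gen_cfg)
  upsample_dvf(dvf(out$u, mov_s$spacing), dim(moving$data),
               target_spacing = moving$spacing)
}

#' Train the local (patch) registration GAN
#'
#' Applies the trained global stage to every pair, then trains a second
#' generator/discriminator pair on co-located patches extracted from the
#' globally deformed and target volumes on the [plan_patches()] grid
#' (patch-level losses). Each epoch visits the full patch grid in order.
#'
#' @param pairs As in [train_global()].
#' @param global_ckpt Checkpoint from [train_global()].
#' @param cfg A [train_config()]; `patch_shape`/`overlap` define the grid.
#' @return List with `checkpoint` and `history` as in [train_global()].
#' @export
train_local <- function(pairs, global_ckpt, cfg = train_config()) {
  pairs <- as_pair_list(pairs)
  if (!identical(global_ckpt$kind, "global"))
    stop("global_ckpt must be a checkpoint from train_global()")
  w <- cfg$weights
  prepared <- lapply(pairs, function(p) {
    gdvf <- global_dvf_for(p$moving, p$target, global_ckpt)
    inter <- warp(p$moving, gdvf)
    grid <- plan_patches(dim(p$moving$data), cfg$patch_shape, cfg$overlap)
    list(inter = inter$data, tgt = p$target$data, grid = grid)
  })
  schedule <- do.call(rbind, lapply(seq_along(prepared), function(i)
    cbind(i, seq_len(nrow(prepared[[i]]$grid$starts)))))
  gcfg <- generator_config(cfg$gen_filters)
  dcfg <- discriminator_config(cfg$disc_filters)
  gen <- generator_init(gcfg, seed = cfg$seed + 10L)
  disc <- discriminator_init(dcfg, seed = cfg$seed + 11L)
  gstate <- adam_new(gen)
  dstate <- adam_new(disc)
  hist <- vector("list", cfg$iterations_local)
  ps <- cfg$patch_shape
  with_seed(cfg$seed + 12L, {
    for (it in seq_len(cfg$iterations_local)) {
      row <- schedule[(it - 1L) %% nrow(schedule) + 1L, ]
      pr <- prepared[[row[1]]]
      s <- pr$grid$starts[row[2], ]
      ix <- (s[1] + 1):(s[1] + ps[1])
      iy <- (s[2] + 1):(s[2] + ps[2])
      iz <- (s[3] + 1):(s[3] + ps[3])
      mov_p <- pr$inter[ix, iy, iz]
      tgt_p <- pr$tgt[ix, iy, iz]
      gs <- gen_step(mov_p, tgt_p, mind_forward(tgt_p)$N, gen, gstate, gcfg,
                     disc, dcfg, w, cfg$learning_rate_local, cfg$adam_betas, it)
      if (gs$diverged)
        stop("local training diverged (non-finite loss) at iteration ", it)
      gen <- gs$params; gstate <- gs$state
      dloss <- NA_real_
      if (w$beta > 0) {
        for (k in seq_len(cfg$disc_steps_per_gen_step)) {
          ds <- disc_step(gs$Id, tgt_p, disc, dstate, dcfg,
                          cfg$learning_rate_local, cfg$adam_betas,
                          (it - 1L) * cfg$disc_steps_per_gen_step + k)
          disc <- ds$params; dstate <- ds$state; dloss <- ds$disc_loss
        }
      }
      hist[[it]] <- data.frame(iteration = it, total = gs$total,
                               similarity = gs$similarity,
                               adversarial = gs$adversarial,
                               regularization = gs$regularization,
                               disc_loss = dloss)
    }
  })
  list(checkpoint = list(kind = "local", gen = gen, gen_cfg = gcfg,
                         disc = disc, disc_cfg = dcfg,
                         patch_shape = ps, overlap = cfg$overlap,
                         weights = w, seed = cfg$seed),
       history = do.call(rbind, hist))
}

#' Save / load a network checkpoint
#'
#' One archive per network pair, with the configuration embedded.
#'
#' @param ckpt Checkpoint list from [train_global()] / [train_local()].
#' @param path Destination file.
#' @return [load_checkpoint()]: the checkpoint list.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  readRDS(path)
}

#' Scaled recovery-study training configuration
#'
#' The configuration used by the package's phantom deformation-recovery
#' experiment: global stage on the whole 64x64x48 grid, local stage on
#' 32^3 patches with (16, 16, 12) overlap, reduced filter widths, a few
#' hundred Adam iterations per stage with momentum-style betas, a faster
#' rate for the coarse global stage and a gentler one for the sub-voxel
#' local refinement. All loss weights are the production defaults.
#'
#' @param seed Integer seed controlling the whole run.
#' @return A [train_config()].
#' @export
recovery_train_config <- function(seed = 1) {
  train_config(
    weights = loss_weights(),
    learning_rate = 5e-3,
    learning_rate_local = 5e-4,
    adam_betas = c(0.9, 0.999),
    iterations_global = 500,
    iterations_local = 450,
    global_downsample_shape = c(64, 64, 48),
    patch_shape = c(32, 32, 32),
    overlap = c(16, 16, 12),
    seed = seed,
    gen_filters = 4,
    disc_filters = 2)
}
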