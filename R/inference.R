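#' Identity checkpoint (zero-displacement generator)
#'
#' A freshly initialized generator has a zero head and therefore predicts
#' the zero field; this helper packages one as a checkpoint, useful as the
#' identity-registration baseline.
#'
#' @param kind `"global"` or `"local"`.
#' @param train_shape Global-stage training grid (global checkpoints).
#' @param patch_shape,overlap Patch grid (local checkpoints).
#' @param base_filters Generator width.
#' @param seed Seed for the (non-head) weight draw.
#' @return A checkpoint list compatible with [register_pair()].
#' @export
identity_checkpoint <- function(kind = c("global", "local"),
                                train_shape = c(64, 64, 48),
                                patch_shape = c(64, 64, 64),
                                overlap = c(32, 32, 48),
                                base_filters = 4, seed = 1) {
  kind <- match.arg(kind)
  gcfg <- generator_config(base_filters)
  ck <- list(kind = kind, gen = generator_init(gcfg, seed), gen_cfg = gcfg,
             disc = NULL, disc_cfg = NULL, weights = loss_weights(),
             seed = seed)
  if (kind == "global") ck$train_shape <- as.integer(train_shape)
  else { ck$patch_shape <- as.integer(patch_shape); ck$overlap <- as.integer(overlap) }
  ck
}

#' Register a moving volume onto a target volume
#'
#' The deployed two-stage path: the global generator predicts a coarse
#' field on its (down-sampled) training grid, which is upsampled to the
#' full grid and applied to the moving volume; the local generator then
#' predicts patch fields on the [plan_patches()] tiling of the globally
#' deformed/target pair, which are tiled and averaged into a whole-volume
#' local field. The final field is the composition of the two and is
#' applied to the original moving volume with a single interpolation.
#'
#' @param moving,target [volume()]s of identical shape.
#' @param global_ckpt Checkpoint from [train_global()] (or
#'   [identity_checkpoint()]).
#' @param local_ckpt Checkpoint from [train_local()], or `NULL` for the
#'   global-only arm.
#' @return List with `final_dvf`, `deformed`, `global_dvf`, `local_dvf`
#'   and the globally-deformed `intermediate` volume. `deformed` equals
#'   `warp(moving, final_dvf)` exactly.
#' @export
register_pair <- function(moving, target, global_ckpt, local_ckpt = NULL) {
  stopifnot(inherits(moving, "dirgan_volume"),
            inherits(target, "dirgan_volume"))
  if (!all(dim(moving$data) == dim(target$data)))
    stop("moving and target must have identical shape")
  if (!identical(global_ckpt$kind, "global"))
    stop("global_ckpt is not a global checkpoint")
  dims <- dim(moving$data)
  global_dvf <- global_dvf_for(moving, target, global_ckpt)
  intermediate <- warp(moving, global_dvf)
  if (is.null(local_ckpt)) {
    local_dvf <- zero_dvf(dims, moving$spacing)
  } else {
    if (!identical(local_ckpt$kind, "local"))
      stop("local_ckpt is not a local checkpoint")
    grid <- plan_patches(dims, local_ckpt$patch_shape, local_ckpt$overlap)
    mov_n <- norm_hu(intermediate$data)
    tgt_n <- norm_hu(target$data)
    ps <- local_ckpt$patch_shape
    patch_dvfs <- lapply(seq_len(nrow(grid$starts)), function(p) {
      s <- grid$starts[p, ]
      ix <- (s[1] + 1):(s[1] + ps[1])
      iy <- (s[2] + 1):(s[2] + ps[2])
      iz <- (s[3] + 1):(s[3] + ps[3])
      generator_forward(mov_n[ix, iy, iz], tgt_n[ix, iy, iz],
                        local_ckpt$gen, local_ckpt$gen_cfg)$u
    })
    local_dvf <- fuse_patches(patch_dvfs, grid, dims,
                              spacing = moving$spacing)
  }
  final_dvf <- compose_dvf(global_dvf, local_dvf)
  deformed <- warp(moving, final_dvf)
  list(final_dvf = final_dvf, deformed = deformed,
       global_dvf = global_dvf, local_dvf = local_dvf,
       intermediate = intermediate)
}
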