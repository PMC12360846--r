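# Adversarial training loop with gradient accumulation, per-epoch
# validation losses, and checkpointing.

#' Train the GAN on paired tiles
#'
#' Per batch the discriminator is updated first on (real = experimental
#' tile, fake = G(sim tile)) with the standard GAN loss, then the generator
#' on the composite SmoothL1 + alpha * adversarial objective; both use
#' NAdam. Gradients are accumulated over `config$batch_size` tiles per
#' step. With `alpha = 0` generator updates never evaluate the
#' discriminator (ablation isolation); the discriminator is still trained
#' so its validation loss remains defined. All stochastic choices
#' (initialization, shuffling) derive from `config$seed`, so two runs with
#' the same seed produce identical loss histories.
#'
#' @param train_pairs list of pairs, each `list(sim = 32^3 array, exp =
#'   32^3 array)` (see [build_toy_dataset]).
#' @param val_pairs held-out pairs for the per-epoch validation losses.
#' @param config a [gan_config].
#' @param verbose print one structured line per epoch.
#' @return an object of class `gan_checkpoint`: `generator`,
#'   `discriminator`, optimizer states, `epoch`, `history` (data.frame with
#'   per-epoch mean validation generator and discriminator losses) and the
#'   config snapshot.
#' @export
train_gan <- function(train_pairs, val_pairs = NULL, config = gan_config(),
                      verbose = FALSE) {
  if (!length(train_pairs)) stop("empty training dataset")
  if (is.null(val_pairs) || !length(val_pairs)) val_pairs <- train_pairs
  gen <- build_generator(config)
  disc <- build_discriminator(config)
  opt_g <- nadam_new(gen$params, lr = config$learning_rate)
  opt_d <- nadam_new(disc$params, lr = config$learning_rate)
  old <- local_rng(config$seed + 2L)
  on.exit(restore_rng(old))

  hist_g <- numeric(config$epochs)
  hist_d <- numeric(config$epochs)
  hist_l1 <- numeric(config$epochs)
  nb <- max(1L, config$batch_size)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(train_pairs))
    batches <- split(ord, ceiling(seq_along(ord) / nb))
    for (batch in batches) {
      # -- discriminator step (fakes from the current generator, no G grads)
      zero_grads(disc$params)
      for (idx in batch) {
        pr <- train_pairs[[idx]]
        fake <- generator_forward(gen, pr$sim, tape = NULL)
        tp <- tape_new()
        d_real <- discriminator_forward(disc, pr$exp, tape = tp)
        d_fake <- discriminator_forward(disc, fake, tape = tp)
        loss_d <- ag_add(tp, ag_neg_log(tp, d_real), ag_neg_log1m(tp, d_fake))
        if (!is.finite(loss_d$value))
          stop("discriminator loss diverged (non-finite) at epoch ", epoch)
        ag_backward(tp, loss_d)
      }
      scale_grads(disc$params, 1 / length(batch))
      nadam_step(opt_d)

      # -- generator step against the just-updated discriminator
      zero_grads(gen$params)
      for (idx in batch) {
        pr <- train_pairs[[idx]]
        tp <- tape_new()
        fake <- generator_forward(gen, pr$sim, tape = tp)
        terms <- list()
        if (config$use_smooth_l1) {
          target <- array(pr$exp, dim = dim(fake$value))
          terms$l1 <- ag_smooth_l1(tp, fake, target)
        }
        if (config$alpha > 0) {
          d_fake <- discriminator_forward(disc, fake, tape = tp)
          terms$adv <- ag_scale(tp, ag_neg_log(tp, d_fake), config$alpha)
        }
        if (!length(terms))
          stop("generator objective is empty (alpha = 0 and use_smooth_l1 = FALSE)")
        loss_g <- if (length(terms) == 2L) ag_add(tp, terms$l1, terms$adv)
          else terms[[1]]
        if (!is.finite(loss_g$value))
          stop("generator loss diverged (non-finite) at epoch ", epoch)
        ag_backward(tp, loss_g)
        if (config$alpha > 0) zero_grads(disc$params)  # G step must not move D
      }
      scale_grads(gen$params, 1 / length(batch))
      nadam_step(opt_g)
    }

    vl <- validate_gan(gen, disc, val_pairs, config)
    hist_g[epoch] <- vl$g
    hist_d[epoch] <- vl$d
    hist_l1[epoch] <- vl$l1
    if (verbose)
      message(sprintf("epoch %d lossG_val %.6f lossD_val %.6f lossL1_val %.6f",
                      epoch, vl$g, vl$d, vl$l1))
  }

  structure(list(generator = gen, discriminator = disc,
                 opt_g = nadam_state(opt_g), opt_d = nadam_state(opt_d),
                 epoch = config$epochs,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      loss_g_val = hist_g,
                                      loss_d_val = hist_d,
                                      loss_l1_val = hist_l1),
                 config = config),
            class = "gan_checkpoint")
}

scale_grads <- function(params, s) {
  for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * s
  invisible(NULL)
}

# mean per-tile validation losses (no gradients)
validate_gan <- function(gen, disc, pairs, config) {
  lg <- ld <- l1 <- 0
  for (pr in pairs) {
    fake <- generator_forward(gen, pr$sim, tape = NULL)
    df <- discriminator_forward(disc, fake, tape = NULL)
    dr <- discriminator_forward(disc, pr$exp, tape = NULL)
    target <- array(pr$exp, dim = dim(fake))
    lg <- lg + generator_loss(fake, target, df, alpha = config$alpha,
                              use_smooth_l1 = config$use_smooth_l1)
    l1 <- l1 + smooth_l1(fake, target)
    ld <- ld + discriminator_loss(dr, df)
  }
  list(g = lg / length(pairs), d = ld / length(pairs), l1 = l1 / length(pairs))
}

#' Save / load a training checkpoint
#'
#' Parameter values, optimizer moments and the config snapshot are written
#' with `saveRDS`; reloading and re-running [generate_map] on the same
#' input reproduces outputs bit-for-bit on the same platform.
#'
#' @param checkpoint a `gan_checkpoint` from [train_gan].
#' @param path destination `.rds` file.
#' @return `path` (save) / the restored `gan_checkpoint` (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  if (!inherits(checkpoint, "gan_checkpoint")) stop("expected a `gan_checkpoint`")
  payload <- list(
    gen_values = lapply(checkpoint$generator$params, function(p) p$value),
    disc_values = lapply(checkpoint$discriminator$params, function(p) p$value),
    opt_g = checkpoint$opt_g, opt_d = checkpoint$opt_d,
    epoch = checkpoint$epoch, history = checkpoint$history,
    config = checkpoint$config)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path path of a checkpoint written by [save_checkpoint].
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  gen <- build_generator(payload$config)
  disc <- build_discriminator(payload$config)
  if (!identical(sort(names(gen$params)), sort(names(payload$gen_values))))
    stop("incompatible checkpoint: generator parameter sets differ")
  for (nm in names(payload$gen_values))
    gen$params[[nm]]$value <- payload$gen_values[[nm]]
  for (nm in names(payload$disc_values))
    disc$params[[nm]]$value <- payload$disc_values[[nm]]
  structure(list(generator = gen, discriminator = disc,
                 opt_g = payload$opt_g, opt_d = payload$opt_d,
                 epoch = payload$epoch, history = payload$history,
                 config = payload$config),
            class = "gan_checkpoint")
}

#' Apply the trained generator tile-wise to a full map
#'
#' @param map a normalized [density_map] (values in [0, 1]).
#' @param gen a `gan_generator` (or a `gan_checkpoint`).
#' @return a [density_map] on the same grid, negatives clamped to 0.
#' @export
refine_map <- function(map, gen) {
  if (inherits(gen, "gan_checkpoint")) gen <- gen$generator
  if (!inherits(gen, "gan_generator")) stop("expected a `gan_generator`")
  pack <- pad_and_tile(map)
  out_tiles <- lapply(pack$tiles, function(t)
    generator_forward(gen, t, tape = NULL))
  out <- reassemble(pack, out_tiles)
  out$data <- pmax(out$data, 0)
  out
}

#' Generate an experimental-like map from an atomic model
#'
#' The full inference path: simulate a map from the model (2 Angstrom
#' default on a 1 Angstrom grid), min-max normalize, split into 32^3 tiles,
#' run the generator on each tile, reassemble from the tile cores, and
#' clamp negatives to zero. Deterministic given (model, checkpoint).
#'
#' @param model an [atomic_model].
#' @param checkpoint a `gan_checkpoint` (or `gan_generator`).
#' @param params a [sim_params] for the input simulation.
#' @param voxel,margin grid spec passed to [grid_from_model].
#' @param reference optional [density_map]; when given, simulation uses its
#'   exact grid instead of a model-derived one.
#' @return a [density_map] on the simulated map's grid.
#' @export
generate_map <- function(model, checkpoint, params = sim_params(),
                         voxel = 1, margin = 5, reference = NULL) {
  grid <- if (is.null(reference)) grid_from_model(model, voxel, margin)
    else reference
  sim <- simulate_on_reference(model, grid, params)
  refine_map(sim, checkpoint)
}
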