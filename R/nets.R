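#' Specify a dense prediction network
#'
#' A compact U-Net: per resolution level two same-padded convolutions with
#' ReLU, max-pool downsampling, nearest-neighbor upsampling with skip
#' concatenation, and one sigmoid-activated 1x1 head per output. 2D models
#' use `(1, 3, 3)` kernels and act on single sections; 3D models use
#' `(3, 3, 3)` kernels and may downsample anisotropically.
#'
#' @param dimensionality 2 or 3.
#' @param in_channels input channel count (1 for raw images, 6 for stacked
#'   2D descriptors).
#' @param out_heads named integer vector of output heads, e.g. `c(lsd = 6)`,
#'   `c(affs = 3)` or `c(affs = 3, lsd = 10)`.
#' @param depth number of down-sampling levels.
#' @param base_features feature maps at full resolution; doubled per level.
#' @param downsample_factors list of `depth` integer triples `(z, y, x)`;
#'   defaults to `(1, 2, 2)` for 2D and `(2, 2, 2)` for 3D models
#'   (anisotropy-aware factors can be supplied).
#' @export
model_spec <- function(dimensionality, in_channels, out_heads,
                       depth = if (dimensionality == 2) 3 else 2,
                       base_features = 12,
                       downsample_factors = NULL) {
  stopifnot(dimensionality %in% c(2, 3), in_channels >= 1, depth >= 0,
            length(out_heads) >= 1, !is.null(names(out_heads)))
  if (is.null(downsample_factors))
    downsample_factors <- rep(list(
      if (dimensionality == 2) c(1L, 2L, 2L) else c(2L, 2L, 2L)), depth)
  stopifnot(length(downsample_factors) == depth)
  kernel <- if (dimensionality == 2) c(1L, 3L, 3L) else c(3L, 3L, 3L)
  if (dimensionality == 2 &&
      any(vapply(downsample_factors, `[`, integer(1), 1) != 1L))
    stop("2D models must not downsample along z")
  structure(list(
    dimensionality = dimensionality,
    in_channels = as.integer(in_channels),
    out_heads = vapply(out_heads, as.integer, integer(1)),
    depth = as.integer(depth),
    base_features = as.integer(base_features),
    downsample_factors = lapply(downsample_factors, as.integer),
    kernel = kernel), class = "model_spec")
}

# architecture description consumed by the C++ engine
cpp_spec <- function(spec) {
  features <- spec$base_features * 2L^(0:spec$depth)
  factors <- if (spec$depth > 0)
    do.call(rbind, spec$downsample_factors) else matrix(integer(), 0, 3)
  list(in_channels = spec$in_channels,
       features = as.integer(features),
       factors = matrix(as.integer(factors), ncol = 3),
       kernel = spec$kernel,
       heads = as.integer(unname(spec$out_heads)),
       head_names = names(spec$out_heads))
}

# parameter array dims in the fixed layout order shared with the C++ engine
param_shapes <- function(spec) {
  cs <- cpp_spec(spec)
  f <- cs$features
  L <- length(f) - 1
  k <- cs$kernel
  shapes <- list()
  add <- function(co, ci, kk) {
    shapes[[length(shapes) + 1]] <<- c(co, ci, kk)
    shapes[[length(shapes) + 1]] <<- co
  }
  for (l in 0:L) {
    ci <- if (l == 0) cs$in_channels else f[l]
    add(f[l + 1], ci, k)
    add(f[l + 1], f[l + 1], k)
  }
  if (L > 0) for (l in (L - 1):0) {
    add(f[l + 1], f[l + 1] + f[l + 2], k)
    add(f[l + 1], f[l + 1], k)
  }
  for (h in cs$heads) add(h, f[1], c(1L, 1L, 1L))
  shapes
}

#' Initialize an untrained model
#'
#' He-normal weight initialization, zero biases; fully determined by `seed`.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return a `bootseg_model` (untrained checkpoint).
#' @export
init_model <- function(spec, seed = 1) {
  shapes <- param_shapes(spec)
  params <- withr::with_seed(seed, lapply(shapes, function(s) {
    if (length(s) == 1) return(array(0, s))
    fan_in <- prod(s[-1])
    array(rnorm(prod(s), 0, sqrt(2 / fan_in)), dim = s)
  }))
  structure(list(spec = spec, params = params,
                 opt = list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
                            v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
                            t = 0),
                 iteration = 0L, loss_trace = numeric(), sigma = NULL),
            class = "bootseg_model")
}

#' @export
print.bootseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<bootseg_model> %dD, heads [%s], %d parameters, %d iterations trained\n",
              x$spec$dimensionality,
              paste(sprintf("%s:%d", names(x$spec$out_heads), x$spec$out_heads),
                    collapse = ", "),
              np, x$iteration))
  invisible(x)
}

#' Save or load a model checkpoint
#' @param model a `bootseg_model`.
#' @param path file path (RDS serialization).
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

adam_update <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0) {
  model$opt$t <- model$opt$t + 1
  t <- model$opt$t
  for (i in seq_along(model$params)) {
    g <- grads[[i]]
    model$opt$m[[i]] <- beta1 * model$opt$m[[i]] + (1 - beta1) * g
    model$opt$v[[i]] <- beta2 * model$opt$v[[i]] + (1 - beta2) * g^2
    mhat <- model$opt$m[[i]] / (1 - beta1^t)
    vhat <- model$opt$v[[i]] / (1 - beta2^t)
    model$params[[i]] <- model$params[[i]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && !is.null(dim(model$params[[i]])))
      model$params[[i]] <- model$params[[i]] * (1 - lr * weight_decay)
  }
  model
}

#' Training configuration
#'
#' @param iterations gradient steps to run (0 returns the initialized model).
#' @param patch_shape training patch in voxels: `(y, x)` for 2D models,
#'   `(z, y, x)` for 3D; must be divisible by the product of the model's
#'   downsample factors per axis.
#' @param learning_rate Adam step size.
#' @param augmentations subset of `"flips"`, `"transpose"`, `"intensity"`
#'   (multiplicative/additive jitter, raw inputs only) and `"noise"`
#'   (additive Gaussian noise, raw inputs only).
#' @param weight_decay decoupled weight decay applied to convolution
#'   weights after each Adam step (0 disables).
#' @param min_labeled_fraction minimum fraction of annotated voxels a sparse
#'   training patch must contain (rejection sampling).
#' @param checkpoint_every optionally save the model every this many
#'   iterations (requires `checkpoint_path`).
#' @param checkpoint_path file stem for periodic checkpoints.
#' @param master_seed seed from which all per-iteration sub-seeds derive.
#' @export
train_config <- function(iterations, patch_shape, learning_rate = 5e-5,
                         augmentations = c("flips", "transpose"),
                         weight_decay = 0,
                         min_labeled_fraction = 0.05,
                         checkpoint_every = Inf, checkpoint_path = NULL,
                         master_seed = 1) {
  stopifnot(iterations >= 0, all(patch_shape >= 1), weight_decay >= 0)
  structure(list(iterations = as.integer(iterations),
                 patch_shape = as.integer(patch_shape),
                 learning_rate = learning_rate,
                 augmentations = augmentations,
                 weight_decay = weight_decay,
                 min_labeled_fraction = min_labeled_fraction,
                 checkpoint_every = checkpoint_every,
                 checkpoint_path = checkpoint_path,
                 master_seed = as.integer(master_seed)),
            class = "train_config")
}

train_report <- function(model, checkpoint = NULL) {
  structure(list(loss_trace = model$loss_trace, model = model,
                 checkpoint = checkpoint), class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  n <- length(x$loss_trace)
  cat(sprintf("<train_report> %d iterations; first loss %.4g, final loss %.4g\n",
              n, if (n) x$loss_trace[1] else NA, if (n) x$loss_trace[n] else NA))
  invisible(x)
}

check_patch_divisible <- function(spec, patch3) {
  f <- c(1L, 1L, 1L)
  for (df in spec$downsample_factors) f <- f * df
  if (any(patch3 %% f != 0))
    stop("patch_shape must be divisible by the total downsample factor (",
         paste(f, collapse = ","), ")")
}

# one gradient step; returns updated model and the loss
train_step <- function(model, input, targets, weights, lr,
                       weight_decay = 0) {
  res <- cpp_unet_train_step(cpp_spec(model$spec), model$params, input,
                             targets, weights)
  model <- adam_update(model, res$grads, lr, weight_decay = weight_decay)
  model$iteration <- model$iteration + 1L
  model$loss_trace <- c(model$loss_trace, res$loss)
  model
}

maybe_checkpoint <- function(model, cfg) {
  if (is.finite(cfg$checkpoint_every) && !is.null(cfg$checkpoint_path) &&
      model$iteration %% cfg$checkpoint_every == 0)
    save_checkpoint(model, sprintf("%s_iter%06d.rds", cfg$checkpoint_path,
                                   model$iteration))
  model
}

# training progress as CSV (iteration, loss) next to the checkpoint stem
finish_training <- function(model, cfg) {
  if (!is.null(cfg$checkpoint_path)) {
    dir.create(dirname(cfg$checkpoint_path), recursive = TRUE,
               showWarnings = FALSE)
    utils::write.csv(
      data.frame(iteration = seq_along(model$loss_trace),
                 loss = model$loss_trace),
      paste0(cfg$checkpoint_path, "_loss.csv"), row.names = FALSE)
  }
  train_report(model)
}

# Extract a training window: the core patch at lo..hi padded by the margin M
# on every side, zero-filled where the window leaves the volume (matching the
# zero-padded canvas used by tiled inference), with flips/transpose/intensity
# jitter applied to the whole window.  The core stays centered, so its index
# range is invariant under the transforms; targets computed on the window and
# supervised only on the core are exactly consistent with the augmented input
# while giving every core voxel a full receptive field of real context.
sample_context_patch <- function(raw_arr, lab_arr, msk_arr, lo, hi, M,
                                 augmentations) {
  d <- dim(lab_arr)
  wlo <- lo - M
  whi <- hi + M
  n <- whi - wlo + 1
  clo <- pmax(wlo, 1); chi <- pmin(whi, d)
  src <- lapply(1:3, function(a) clo[a]:chi[a])
  dst <- lapply(1:3, function(a) (clo[a] - wlo[a] + 1):(chi[a] - wlo[a] + 1))
  fill <- function(x, zero) {
    if (is.null(x)) return(NULL)
    w <- array(zero, n)
    w[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    w
  }
  raw <- fill(raw_arr, 0); lab <- fill(lab_arr, 0)
  msk <- fill(msk_arr, FALSE)
  core <- lapply(1:3, function(a) (M[a] + 1):(M[a] + (hi[a] - lo[a] + 1)))
  if ("flips" %in% augmentations) for (a in 2:3) if (runif(1) < 0.5) {
    idx <- lapply(n, seq_len); idx[[a]] <- rev(idx[[a]])
    flipit <- function(x) if (is.null(x)) NULL else
      array(x[idx[[1]], idx[[2]], idx[[3]]], n)
    raw <- flipit(raw); lab <- flipit(lab); msk <- flipit(msk)
  }
  if ("zflip" %in% augmentations && runif(1) < 0.5) {
    idx <- lapply(n, seq_len); idx[[1]] <- rev(idx[[1]])
    flipit <- function(x) if (is.null(x)) NULL else
      array(x[idx[[1]], idx[[2]], idx[[3]]], n)
    raw <- flipit(raw); lab <- flipit(lab); msk <- flipit(msk)
  }
  if ("transpose" %in% augmentations && n[2] == n[3] && runif(1) < 0.5) {
    tp <- function(x) if (is.null(x)) NULL else aperm(x, c(1, 3, 2))
    raw <- tp(raw); lab <- tp(lab); msk <- tp(msk)
  }
  if ("intensity" %in% augmentations && !is.null(raw))
    raw <- clip01(raw * runif(1, 0.9, 1.1) + runif(1, -0.05, 0.05))
  if ("noise" %in% augmentations && !is.null(raw))
    raw <- clip01(raw + array(rnorm(length(raw), 0, runif(1, 0, 0.05)),
                              dim(raw)))
  list(raw = raw, lab = lab, msk = msk, core = core)
}

# full-window targets with supervision restricted to the core (and, for
# sparse training, to the annotation mask)
context_targets <- function(lab, msk, core, voxel_size, sigma, heads,
                            dimensionality) {
  sub_lab <- label_volume(lab, voxel_size)
  n <- dim(lab)
  core_ind <- array(FALSE, n)
  core_ind[core[[1]], core[[2]], core[[3]]] <- TRUE
  sup <- if (is.null(msk)) core_ind else (core_ind & msk)
  out_t <- list(); out_w <- list()
  for (h in names(heads)) {
    if (h == "lsd") {
      lsd <- compute_lsd(sub_lab, sigma, dimensionality = dimensionality)
      tgt <- lsd$data
      C <- dim(tgt)[1]
      w <- aperm(array(sup, c(n, C)), c(4, 1, 2, 3)) * 1
    } else if (h == "affs") {
      nb <- if (dimensionality == 2)
        matrix(c(0L, -1L, 0L, 0L, 0L, -1L), nrow = 2, byrow = TRUE)
      else default_neighborhood()
      aff <- compute_affinities(sub_lab, neighborhood = nb)
      tgt <- aff$data
      w <- (aperm(array(sup, c(n, dim(tgt)[1])), c(4, 1, 2, 3)) & aff$mask) * 1
    } else stop("unknown head: ", h)
    out_t[[h]] <- array(tgt, dim(tgt))
    out_w[[h]] <- array(w, dim(tgt))
  }
  list(targets = out_t, weights = out_w)
}

#' Train the sparse-to-dense 2D network
#'
#' Each iteration samples a random section patch whose annotated fraction is
#' at least `cfg$min_labeled_fraction` (rejection sampling, at most 100
#' draws), applies augmentations (targets are recomputed from the
#' transformed labels, so they stay exactly consistent), computes the
#' per-head targets and loss weights from the sparse annotation, and takes
#' one Adam step on the masked weighted MSE. Supervision never leaks outside
#' `labeled_mask`: the loss gradient is exactly zero there.
#'
#' @param images a raw [volume_grid()] with values in `[0, 1]`.
#' @param annotation a [sparse_annotation()] on the same grid.
#' @param spec a 2D [model_spec()] (e.g. `out_heads = c(lsd = 6)`).
#' @param cfg a [train_config()]; `patch_shape` is `(y, x)`.
#' @param sigma descriptor scale in nm for `lsd` heads.
#' @return a `train_report` (loss trace + trained model).
#' @export
train_sparse_2d <- function(images, annotation, spec, cfg, sigma = 40) {
  stopifnot(inherits(images, "volume_grid"), spec$dimensionality == 2,
            inherits(annotation, "sparse_annotation"))
  d <- dim(images$data)
  patch <- cfg$patch_shape
  stopifnot(length(patch) == 2)
  check_patch_divisible(spec, c(1L, patch))
  sec_any <- which(apply(annotation$labeled_mask, 1, any))
  if (!length(sec_any)) stop("labeled_mask is empty on every section")
  model <- init_model(spec, seed = derive_subseed(cfg$master_seed, 0))
  model$sigma <- sigma
  if (cfg$iterations == 0) return(train_report(model))
  py <- min(patch[1], d[2]); px <- min(patch[2], d[3])
  for (it in seq_len(cfg$iterations)) {
    step <- withr::with_seed(derive_subseed(cfg$master_seed, it), {
      found <- NULL
      for (try_i in 1:100) {
        z <- sec_any[sample.int(length(sec_any), 1)]
        oy <- sample.int(d[2] - py + 1, 1)
        ox <- sample.int(d[3] - px + 1, 1)
        frac <- mean(annotation$labeled_mask[z, oy:(oy + py - 1),
                                             ox:(ox + px - 1)])
        if (frac >= cfg$min_labeled_fraction) {
          found <- c(z, oy, ox)
          break
        }
      }
      if (is.null(found))
        stop("no patch with labeled fraction >= ", cfg$min_labeled_fraction,
             " found in 100 draws; lower min_labeled_fraction or enlarge ",
             "the annotation")
      z <- found[1]; oy <- found[2]; ox <- found[3]
      lo <- c(z, oy, ox); hi <- c(z, oy + py - 1, ox + px - 1)
      vs <- images$voxel_size
      K <- c(0L, as.integer(floor(3 * sigma / vs[2])),
             as.integer(floor(3 * sigma / vs[3])))
      M <- pmax(K, c(0L, receptive_field(spec)[2:3]))
      Fax <- c(1L, 1L, 1L)
      for (df in spec$downsample_factors) Fax <- Fax * df
      M <- as.integer(ceiling(M / Fax) * Fax)
      M[1] <- 0L
      ctx <- sample_context_patch(images$data, annotation$labels$data,
                                  annotation$labeled_mask, lo, hi, M,
                                  cfg$augmentations)
      tw <- context_targets(ctx$lab, ctx$msk, ctx$core, vs, sigma,
                            spec$out_heads, dimensionality = 2)
      input <- array(ctx$raw, c(1, dim(ctx$raw)))
      list(input = input, targets = tw$targets, weights = tw$weights)
    })
    model <- train_step(model, step$input, step$targets, step$weights,
                        cfg$learning_rate, cfg$weight_decay %||% 0)
    model <- maybe_checkpoint(model, cfg)
  }
  finish_training(model, cfg)
}

#' Train the stacked-2D-to-3D network on synthetic data
#'
#' Each iteration draws a fresh synthetic training pair (labels, degraded
#' stacked per-section descriptors, 3D affinities) with a sub-seed derived
#' from `cfg$master_seed`, and optimizes the masked MSE on affinities. The
#' model never sees raw images, so it is dataset-agnostic.
#'
#' @param spec a 3D [model_spec()] with `in_channels = 6`,
#'   `out_heads = c(affs = 3)`.
#' @param cfg a [train_config()]; `patch_shape` is `(z, y, x)` and is used
#'   as the synthetic volume shape.
#' @param synth a [synth_params()] template (its `shape`/`seed` are
#'   overridden per iteration).
#' @param degrade a [degrade_params()] template (seed overridden).
#' @param sigma descriptor scale in nm of the simulated 2D predictions.
#' @param balance class-balance the affinity loss? Space-filling labels
#'   make affinity targets heavily one-dominated; balancing keeps the
#'   boundary class from being ignored.
#' @export
train_3d_from_synthetic <- function(spec, cfg, synth, degrade, sigma = 40,
                                    balance = TRUE) {
  stopifnot(spec$dimensionality == 3, spec$in_channels == 6)
  check_patch_divisible(spec, cfg$patch_shape)
  model <- init_model(spec, seed = derive_subseed(cfg$master_seed, 0))
  model$sigma <- sigma
  if (cfg$iterations == 0) return(train_report(model))
  # synthetic volumes carry a receptive-field margin around the supervised
  # core so trained voxels see real context, as they will under tiled
  # inference
  Fax <- c(1L, 1L, 1L)
  for (df in spec$downsample_factors) Fax <- Fax * df
  M <- as.integer(ceiling(receptive_field(spec) / Fax) * Fax)
  win <- cfg$patch_shape + 2L * M
  core <- lapply(1:3, function(a) (M[a] + 1):(M[a] + cfg$patch_shape[a]))
  for (it in seq_len(cfg$iterations)) {
    sp <- synth; sp$shape <- win
    sp$seed <- derive_subseed(cfg$master_seed, 2 * it)
    dg <- degrade; dg$seed <- derive_subseed(cfg$master_seed, 2 * it + 1)
    pair <- make_training_pair(sp, sigma, dg)
    core_ind <- array(FALSE, win)
    core_ind[core[[1]], core[[2]], core[[3]]] <- TRUE
    D <- dim(pair$target$data)[1]
    w <- (aperm(array(core_ind, c(win, D)), c(4, 1, 2, 3)) &
            pair$target$mask) * 1
    if (balance) w <- balance_weights(pair$target$data, w)
    model <- train_step(model, pair$input$data,
                        list(affs = pair$target$data),
                        list(affs = w),
                        cfg$learning_rate, cfg$weight_decay %||% 0)
    model <- maybe_checkpoint(model, cfg)
  }
  finish_training(model, cfg)
}

#' Train the 3D multi-task model on (pseudo) ground truth
#'
#' Two heads (affinities, 3 channels; descriptors, 10 channels); targets are
#' computed per patch from the provided labels; loss =
#' `masked_mse(affs) + masked_mse(lsd)` with unit head weights; no sparsity
#' masking (weights are 1 except on out-of-bounds affinity entries).
#'
#' @param raw a raw [volume_grid()] in `[0, 1]`.
#' @param pseudo_gt a [label_volume()] aligned with `raw` (typically an
#'   unproofread bootstrapped segmentation).
#' @param spec a 3D [model_spec()], e.g. `out_heads = c(affs = 3, lsd = 10)`.
#' @param cfg a [train_config()]; `patch_shape` is `(z, y, x)`.
#' @param sigma descriptor scale in nm for the `lsd` head.
#' @param balance class-balance the affinity head's loss (see
#'   [train_3d_from_synthetic()])?
#' @export
train_3d_mtlsd <- function(raw, pseudo_gt, spec, cfg, sigma = 40,
                           balance = TRUE) {
  stopifnot(inherits(raw, "volume_grid"), inherits(pseudo_gt, "label_volume"),
            identical(dim(raw$data), dim(pseudo_gt$data)),
            spec$dimensionality == 3)
  check_patch_divisible(spec, cfg$patch_shape)
  d <- dim(raw$data)
  p <- pmin(cfg$patch_shape, d)
  model <- init_model(spec, seed = derive_subseed(cfg$master_seed, 0))
  model$sigma <- sigma
  if (cfg$iterations == 0) return(train_report(model))
  for (it in seq_len(cfg$iterations)) {
    step <- withr::with_seed(derive_subseed(cfg$master_seed, it), {
      lo <- vapply(1:3, function(a) sample.int(d[a] - p[a] + 1, 1), integer(1))
      hi <- lo + p - 1
      # window margin: descriptor context and the net's receptive field,
      # capped to keep per-iteration cost bounded
      K <- pmin(as.integer(floor(3 * sigma / raw$voxel_size)), 10L)
      M <- pmax(K, receptive_field(spec))
      Fax <- c(1L, 1L, 1L)
      for (df in spec$downsample_factors) Fax <- Fax * df
      M <- as.integer(ceiling(M / Fax) * Fax)
      aug <- union(cfg$augmentations,
                   if ("flips" %in% cfg$augmentations) "zflip")
      ctx <- sample_context_patch(raw$data, pseudo_gt$data, NULL, lo, hi, M,
                                  aug)
      tw <- context_targets(ctx$lab, NULL, ctx$core, raw$voxel_size, sigma,
                            spec$out_heads, dimensionality = 3)
      if (balance && "affs" %in% names(tw$targets))
        tw$weights$affs <- balance_weights(tw$targets$affs, tw$weights$affs)
      input <- array(ctx$raw, c(1, dim(ctx$raw)))
      list(input = input, targets = tw$targets, weights = tw$weights)
    })
    model <- train_step(model, step$input, step$targets, step$weights,
                        cfg$learning_rate, cfg$weight_decay %||% 0)
    model <- maybe_checkpoint(model, cfg)
  }
  finish_training(model, cfg)
}

# class-balanced reweighting of a binary affinity target inside the
# supervised region (inverse class frequency, mean in-mask weight 1)
balance_weights <- function(target, w) {
  inm <- which(w > 0)
  if (!length(inm)) return(w)
  pos <- target[inm] > 0.5
  fpos <- mean(pos)
  if (fpos > 0 && fpos < 1) {
    wv <- ifelse(pos, 1 / fpos, 1 / (1 - fpos))
    w[inm] <- wv / mean(wv)
  }
  w
}

# per-axis receptive-field radius of the U-Net, in voxels at full resolution
receptive_field <- function(spec) {
  cs <- cpp_spec(spec)
  kr <- (cs$kernel - 1) %/% 2
  L <- length(cs$features) - 1
  f <- c(1, 1, 1)
  r <- c(0, 0, 0)
  for (l in 0:L) {
    r <- r + 2 * kr * f
    if (l < L) f <- f * cs$factors[l + 1, ]
  }
  if (L > 0) for (l in (L - 1):0) {
    f <- f / cs$factors[l + 1, ]
    r <- r + 2 * kr * f
  }
  # pooling/upsampling grid alignment extends the reach by up to the total
  # downsampling factor per axis
  Fax <- c(1, 1, 1)
  if (L > 0) for (l in 1:L) Fax <- Fax * cs$factors[l, ]
  as.integer(ceiling(r + Fax))
}

# overlap-tiled inference on a (c, z, y, x) array; exact agreement with
# single-tile inference because every core voxel only sees true data (or the
# shared zero padding) within the receptive field
tile_predict <- function(model, input, tile = NULL) {
  cs <- cpp_spec(model$spec)
  d <- dim(input)
  sp <- d[2:4]
  Fax <- c(1L, 1L, 1L)
  for (df in model$spec$downsample_factors) Fax <- Fax * df
  rf <- receptive_field(model$spec)
  m <- as.integer(ceiling(rf / Fax) * Fax)
  if (is.null(tile)) tile <- sp
  tile <- as.integer(pmin(ceiling(tile / Fax) * Fax,
                          ceiling(sp / Fax) * Fax))
  ntile <- ceiling(sp / tile)
  canvas_sp <- ntile * tile + 2L * m
  canvas <- array(0, c(d[1], canvas_sp))
  canvas[, m[1] + seq_len(sp[1]), m[2] + seq_len(sp[2]),
         m[3] + seq_len(sp[3])] <- input
  heads <- model$spec$out_heads
  outs <- lapply(heads, function(ch) array(0, c(ch, sp)))
  for (tz in seq_len(ntile[1])) for (ty in seq_len(ntile[2]))
    for (tx in seq_len(ntile[3])) {
      o <- (c(tz, ty, tx) - 1L) * tile # core origin, 0-based
      win <- lapply(1:3, function(a) o[a] + seq_len(tile[a] + 2L * m[a]))
      sub <- canvas[, win[[1]], win[[2]], win[[3]], drop = FALSE]
      pred <- cpp_unet_forward(cs, model$params, sub)
      for (h in names(heads)) {
        core <- lapply(1:3, function(a) {
          keep <- m[a] + seq_len(tile[a])
          keep[o[a] + seq_len(tile[a]) <= sp[a]]
        })
        dstz <- o[1] + seq_along(core[[1]])
        dsty <- o[2] + seq_along(core[[2]])
        dstx <- o[3] + seq_along(core[[3]])
        outs[[h]][, dstz, dsty, dstx] <-
          pred[[h]][, core[[1]], core[[2]], core[[3]], drop = FALSE]
      }
    }
  outs
}

#' Predict dense 2D descriptors for every section of a volume
#'
#' Runs the trained 2D network on each z-section independently with
#' overlap-tiled inference and stacks the outputs along z.
#'
#' @param model a trained 2D `bootseg_model` (or a checkpoint path).
#' @param volume a raw [volume_grid()].
#' @param tile optional `(y, x)` tile core size.
#' @return a [descriptor_grid()] (for an `lsd` head model).
#' @export
predict_2d_stack <- function(model, volume, tile = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(model$spec$dimensionality == 2,
            inherits(volume, "volume_grid"))
  d <- dim(volume$data)
  C <- sum(model$spec$out_heads)
  out <- array(0, c(model$spec$out_heads[[1]], d))
  for (z in seq_len(d[1])) {
    sec <- array(volume$data[z, , ], c(1, 1, d[2], d[3]))
    pr <- tile_predict(model, sec,
                       tile = if (is.null(tile)) NULL else c(1L, tile))
    out[, z, , ] <- pr[[1]][, 1, , ]
  }
  out <- clip01(out)
  if (names(model$spec$out_heads)[1] == "lsd")
    descriptor_grid(out, model$sigma %||% 40, volume$voxel_size,
                    volume$offset)
  else volume_grid(out, volume$voxel_size, volume$offset,
                   semantic = "descriptor")
}

#' 3D inference of all model heads
#'
#' Overlap-tiled 3D inference; outputs are clipped to `[0, 1]` (sigmoid
#' heads) and returned for every head (`affs`, plus `lsd` for multi-task
#' models).
#'
#' @param model a trained 3D `bootseg_model` (or a checkpoint path).
#' @param input a [descriptor_grid()], raw [volume_grid()], or a
#'   `(c, z, y, x)` array with channels matching `spec$in_channels`.
#' @param tile optional `(z, y, x)` tile core size.
#' @return named list of grids, one per head (`affs` as [affinity_grid()],
#'   `lsd` as [descriptor_grid()]).
#' @export
predict_3d <- function(model, input, tile = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(model$spec$dimensionality == 3)
  vs <- c(1, 1, 1); off <- c(0, 0, 0)
  if (inherits(input, "volume_grid")) {
    vs <- input$voxel_size; off <- input$offset
    arr <- input$data
    if (length(dim(arr)) == 3) arr <- array(arr, c(1, dim(arr)))
  } else arr <- input
  if (dim(arr)[1] != model$spec$in_channels)
    stop("input has ", dim(arr)[1], " channels; model expects ",
         model$spec$in_channels)
  outs <- tile_predict(model, arr, tile)
  res <- list()
  for (h in names(outs)) {
    o <- clip01(outs[[h]])
    res[[h]] <- if (h == "affs")
      affinity_grid(o, voxel_size = vs, offset = off)
    else if (h == "lsd")
      descriptor_grid(o, model$sigma %||% 40, vs, off)
    else volume_grid(o, vs, off, semantic = "descriptor")
  }
  res
}
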