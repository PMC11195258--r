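#' Simulate sparse annotation from dense labels
#'
#' Instance-level ablations of a dense labeling, mimicking what a human
#' annotator produces:
#' * `single_section_fraction`: one z-section, a random subset of its
#'   instances covering approximately the requested fraction of the
#'   section's labeled area (2D annotation on a single image);
#' * `n_random_objects`: `amount` uniformly chosen instances kept in 3D;
#' * `n_adjacent_objects`: one random instance plus its `amount - 1`
#'   nearest contact-graph neighbors.
#'
#' The labeled mask contains the kept-label voxels plus a thin annotated
#' background collar around them (`collar`-voxel dilation band), since
#' sparse instance labels alone carry no boundary supervision. Repeated
#' draws with `exclude_ids` support mutually exclusive selections.
#'
#' @param dense a dense [label_volume()].
#' @param mode annotation mode (see above).
#' @param amount fraction in `(0, 1]` for `single_section_fraction`, else a
#'   number of objects.
#' @param seed integer seed.
#' @param collar width (voxels) of the annotated-background band; 0 disables.
#' @param section optional fixed z-section (1-based) for the fraction mode.
#' @param exclude_ids ids that must not be selected.
#' @return a [sparse_annotation()]; attribute `"ids"` lists the kept ids.
#' @export
simulate_sparse_annotation <- function(dense,
                                       mode = c("single_section_fraction",
                                                "n_random_objects",
                                                "n_adjacent_objects"),
                                       amount, seed = 1, collar = 2,
                                       section = NULL, exclude_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dense, "label_volume"))
  d <- dim(dense$data)
  withr::with_seed(seed, {
    if (mode == "single_section_fraction") {
      z <- section %||% sample.int(d[1], 1)
      sec <- dense$data[z, , ]
      ids <- setdiff(unique(as.vector(sec)), c(0, exclude_ids))
      if (!length(ids)) stop("no instances on the chosen section")
      ids <- ids[sample.int(length(ids))]
      areas <- vapply(ids, function(i) sum(sec == i), numeric(1))
      target <- amount * sum(sec > 0)
      keep <- ids[seq_len(max(1, which(cumsum(areas) >= target)[1]))]
      if (anyNA(keep)) keep <- ids
      lab <- array(0, d)
      kept_sec <- array(0, dim(sec))
      kept_sec[sec %in% keep] <- sec[sec %in% keep]
      lab[z, , ] <- kept_sec
      mask <- array(FALSE, d)
      m2 <- kept_sec > 0
      if (collar > 0) {
        for (i in seq_len(collar)) {
          m2 <- m2 |
            rbind(m2[-1, , drop = FALSE], m2[nrow(m2), , drop = FALSE]) |
            rbind(m2[1, , drop = FALSE], m2[-nrow(m2), , drop = FALSE]) |
            cbind(m2[, -1, drop = FALSE], m2[, ncol(m2), drop = FALSE]) |
            cbind(m2[, 1, drop = FALSE], m2[, -ncol(m2), drop = FALSE])
        }
      }
      mask[z, , ] <- m2
    } else {
      all_ids <- setdiff(sort(unique(as.vector(dense$data))),
                         c(0, exclude_ids))
      n <- as.integer(amount)
      if (n > length(all_ids))
        stop("requested ", n, " objects but only ", length(all_ids),
             " are available")
      keep <- if (mode == "n_random_objects")
        all_ids[sample.int(length(all_ids), n)]
      else {
        first <- all_ids[sample.int(length(all_ids), 1)]
        adj <- contact_neighbors(dense$data)
        sel <- first
        frontier <- first
        while (length(sel) < n) {
          cand <- setdiff(intersect(unlist(adj[as.character(frontier)]),
                                    all_ids), sel)
          if (!length(cand)) {
            cand <- setdiff(all_ids, sel)
            if (!length(cand)) break
          }
          nxt <- sort(cand)[seq_len(min(n - length(sel), length(cand)))]
          sel <- c(sel, nxt)
          frontier <- nxt
        }
        sel
      }
      lab <- array(0, d)
      lab[dense$data %in% keep] <- dense$data[dense$data %in% keep]
      mask <- lab > 0
      if (collar > 0) {
        nb <- face_neighbors()
        for (i in seq_len(collar)) {
          grown <- mask
          for (k in seq_len(nrow(nb)))
            grown <- grown | shift_edge_replicate(mask, nb[k, 1], nb[k, 2],
                                                  nb[k, 3])
          mask <- grown
        }
      }
    }
    ann <- sparse_annotation(label_volume(lab, dense$voxel_size,
                                          dense$offset), mask)
    attr(ann, "ids") <- sort(unique(lab[lab > 0]))
    if (mode == "single_section_fraction") attr(ann, "section") <- z
    ann
  })
}

# contact graph of a dense labeling: id -> adjacent ids
contact_neighbors <- function(lab) {
  d <- dim(lab)
  pairs <- NULL
  for (a in 1:3) {
    src <- lapply(1:3, function(ax) seq_len(d[ax] - (ax == a)))
    dst <- lapply(1:3, function(ax) seq_len(d[ax]) [seq_len(d[ax]) > (ax == a)])
    lp <- lab[src[[1]], src[[2]], src[[3]]]
    lq <- lab[dst[[1]], dst[[2]], dst[[3]]]
    sel <- lp > 0 & lq > 0 & lp != lq
    if (any(sel))
      pairs <- rbind(pairs, unique(cbind(pmin(lp[sel], lq[sel]),
                                         pmax(lp[sel], lq[sel]))))
  }
  if (is.null(pairs)) return(list())
  pairs <- unique(pairs)
  adj <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
  lapply(adj, unique)
}

#' Render a synthetic raw image from instance labels
#'
#' Per-object constant intensity, darkened object boundaries, and additive
#' Gaussian noise: a minimal learnable image->descriptor task for the 2D
#' network in fully synthetic demonstrations.
#'
#' @param labels a [label_volume()].
#' @param seed integer seed.
#' @param boundary_intensity intensity of boundary voxels.
#' @param noise_sd additive noise s.d.
#' @return a raw [volume_grid()] in `[0, 1]`.
#' @export
render_raw <- function(labels, seed = 1, boundary_intensity = 0.05,
                       noise_sd = 0.03) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$data
  d <- dim(lab)
  ids <- sort(unique(as.vector(lab)))
  withr::with_seed(seed, {
    shades <- setNames(runif(length(ids), 0.55, 0.85), as.character(ids))
    if ("0" %in% names(shades)) shades[["0"]] <- 0.2
    img <- array(shades[as.character(lab)], d)
    boundary <- array(FALSE, d)
    nb <- face_neighbors()
    for (k in seq_len(nrow(nb))) {
      nl <- shift_edge_replicate(lab, nb[k, 1], nb[k, 2], nb[k, 3])
      boundary <- boundary | (nl != lab)
    }
    img[boundary] <- boundary_intensity
    img <- img + array(rnorm(prod(d), 0, noise_sd), d)
  })
  volume_grid(clip01(img), labels$voxel_size, labels$offset, semantic = "raw")
}

#' 2D->3D segmentation of a volume
#'
#' Runs the trained 2D network on every section ([predict_2d_stack()]),
#' infers 3D affinities from the stacked descriptors ([predict_3d()]), and
#' post-processes into a segmentation ([segment()]). Intermediates are
#' persisted to `store` when given.
#'
#' @param volume a raw [volume_grid()].
#' @param model2d,model3d trained `bootseg_model`s, checkpoint paths, or
#'   plain functions (`volume -> descriptor grid`, `descriptors -> named
#'   list of head grids`) for stub injection in tests and experiments.
#' @param boundary_threshold,merge_threshold post-processing thresholds.
#' @param store optional directory for intermediates (Zarr).
#' @param tag name prefix for persisted datasets.
#' @return list: `segmentation`, `affs`, `stacked_lsds`, `fragments`,
#'   `rag`.
#' @export
run_2d3d <- function(volume, model2d, model3d, boundary_threshold = 0.5,
                     merge_threshold = 0.5, store = NULL, tag = "vol") {
  stacked <- if (is.function(model2d)) model2d(volume)
  else predict_2d_stack(model2d, volume)
  preds <- if (is.function(model3d)) model3d(stacked)
  else predict_3d(model3d, stacked)
  affs <- preds$affs
  parts <- segment(affs, boundary_threshold, merge_threshold,
                   return_parts = TRUE)
  if (!any(parts$segmentation$data > 0))
    bs_log("empty segmentation produced (no foreground affinities)")
  if (!is.null(store)) {
    dir.create(store, recursive = TRUE, showWarnings = FALSE)
    write_volume(stacked, file.path(store, paste0(tag, "_lsd2d.zarr")),
                 overwrite = TRUE)
    write_volume(affs, file.path(store, paste0(tag, "_affs.zarr")),
                 overwrite = TRUE)
    write_volume(parts$fragments, file.path(store, paste0(tag, "_frags.zarr")),
                 overwrite = TRUE)
    write_volume(parts$segmentation, file.path(store, paste0(tag, "_seg.zarr")),
                 overwrite = TRUE)
  }
  list(segmentation = parts$segmentation, affs = affs,
       stacked_lsds = stacked, fragments = parts$fragments, rag = parts$rag)
}

#' Configuration for the full bootstrap pipeline
#'
#' Collects the two volumes, annotation, model and training blocks,
#' post-processing grids, and evaluation settings. `master_seed` fixes
#' every stochastic stage through derived sub-seeds.
#'
#' @param vol1_raw,vol2_raw raw [volume_grid()]s (volume 1 carries the
#'   sparse annotations; volume 2 is segmented for pseudo ground truth).
#' @param annotation a [sparse_annotation()] on volume 1.
#' @param vol1_gt optional dense [label_volume()] for evaluation.
#' @param sigma descriptor scale in nm.
#' @param spec2d,cfg2d 2D model and training configuration.
#' @param spec3d,cfg3d stacked-2D->3D model and training configuration.
#' @param synth,degrade synthetic-data parameters for the 3D pre-training.
#' @param spec_mtlsd,cfg_mtlsd 3D multi-task model and training
#'   configuration.
#' @param boundary_thresholds,merge_thresholds post-processing grids for
#'   the final volume-1 grid search.
#' @param pgt_boundary_threshold,pgt_merge_threshold thresholds for the
#'   volume-2 pseudo-ground-truth segmentation.
#' @param evaluate run evaluation (requires `vol1_gt`)?
#' @param min_size,prune_length,error_threshold,opening_radius evaluation
#'   parameters.
#' @param store optional output directory.
#' @param master_seed master seed.
#' @export
bootstrap_config <- function(vol1_raw, vol2_raw, annotation, vol1_gt = NULL,
                             sigma = 40,
                             spec2d, cfg2d, spec3d, cfg3d, synth, degrade,
                             spec_mtlsd, cfg_mtlsd,
                             boundary_thresholds = c(0.25, 0.5),
                             merge_thresholds = c(0.3, 0.5, 0.7),
                             pgt_boundary_threshold = 0.5,
                             pgt_merge_threshold = 0.5,
                             evaluate = !is.null(vol1_gt),
                             min_size = 500, prune_length = NULL,
                             error_threshold = 0.25, opening_radius = 1,
                             store = NULL, master_seed = 1) {
  structure(list(vol1_raw = vol1_raw, vol2_raw = vol2_raw,
                 annotation = annotation, vol1_gt = vol1_gt, sigma = sigma,
                 spec2d = spec2d, cfg2d = cfg2d, spec3d = spec3d,
                 cfg3d = cfg3d, synth = synth, degrade = degrade,
                 spec_mtlsd = spec_mtlsd, cfg_mtlsd = cfg_mtlsd,
                 boundary_thresholds = boundary_thresholds,
                 merge_thresholds = merge_thresholds,
                 pgt_boundary_threshold = pgt_boundary_threshold,
                 pgt_merge_threshold = pgt_merge_threshold,
                 evaluate = evaluate, min_size = min_size,
                 prune_length = prune_length,
                 error_threshold = error_threshold,
                 opening_radius = opening_radius,
                 store = store, master_seed = as.integer(master_seed)),
            class = "bootstrap_config")
}

content_ref <- function(x) {
  # light content address: dimensions plus two order-sensitive checksums
  v <- as.numeric(x)
  sprintf("%s#%.10e#%.10e", paste(dim(x) %||% length(x), collapse = "x"),
          sum(v), sum(v * seq_along(v) %% 97))
}

#' Run the full bootstrap (sparse 2D annotations to a dedicated 3D model)
#'
#' Stages: (a) train the sparse-to-dense 2D network on volume 1's
#' annotations; (b) segment volume 2 with the 2D->3D networks (the 3D
#' network is pre-trained on synthetic data) to obtain pseudo ground truth;
#' (c) train the 3D multi-task model on volume 2's raw data and pseudo
#' ground truth, unproofread; (d) infer and grid-search post-processing on
#' volume 1; (e) evaluate against volume 1's ground truth (filtered labels,
#' skeleton edit counts, variation of information) and compute the
#' descriptor error map. The two-volume discipline avoids propagating
#' volume-specific biases. Stage outputs can be cached: pass cached results
#' via `resume` to rerun only later stages.
#'
#' @param config a [bootstrap_config()].
#' @param resume optional named list of cached stage outputs (`model2d`,
#'   `model3d`, `pseudo_gt`, `mtlsd`) to skip recomputation.
#' @return a report list (class `bootstrap_report`): stage summaries,
#'   content references, chosen thresholds, and evaluation metrics.
#' @export
run_bootstrap <- function(config, resume = list()) {
  stopifnot(inherits(config, "bootstrap_config"))
  report <- list(master_seed = config$master_seed, stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage_time <- function() round(proc.time()[["elapsed"]] - t0, 2)

  # (a) sparse 2D training on volume 1
  model2d <- resume$model2d
  if (is.null(model2d)) {
    cfg <- config$cfg2d
    cfg$master_seed <- derive_subseed(config$master_seed, 1)
    rep2d <- train_sparse_2d(config$vol1_raw, config$annotation,
                             config$spec2d, cfg, sigma = config$sigma)
    model2d <- rep2d$model
    report$stages$train2d <- list(
      iterations = model2d$iteration,
      final_loss = unname(tail(model2d$loss_trace, 1)),
      elapsed_s = stage_time())
  } else report$stages$train2d <- list(cached = TRUE)

  # (b) synthetic pre-training of the 3D net + pseudo-GT on volume 2
  model3d <- resume$model3d
  if (is.null(model3d)) {
    cfg <- config$cfg3d
    cfg$master_seed <- derive_subseed(config$master_seed, 2)
    rep3d <- train_3d_from_synthetic(config$spec3d, cfg, config$synth,
                                     config$degrade, sigma = config$sigma)
    model3d <- rep3d$model
    report$stages$train3d_synth <- list(
      iterations = model3d$iteration,
      final_loss = unname(tail(model3d$loss_trace, 1)),
      elapsed_s = stage_time())
  } else report$stages$train3d_synth <- list(cached = TRUE)

  pseudo_gt <- resume$pseudo_gt
  if (is.null(pseudo_gt)) {
    res2 <- run_2d3d(config$vol2_raw, model2d, model3d,
                     config$pgt_boundary_threshold,
                     config$pgt_merge_threshold,
                     store = config$store, tag = "vol2")
    pseudo_gt <- res2$segmentation
    report$stages$pseudo_gt <- list(
      n_segments = length(unique(pseudo_gt$data[pseudo_gt$data > 0])),
      content = content_ref(pseudo_gt$data),
      elapsed_s = stage_time())
  } else report$stages$pseudo_gt <- list(cached = TRUE,
                                         content = content_ref(pseudo_gt$data))

  # (c) 3D multi-task training on volume 2 pseudo ground truth
  mtlsd <- resume$mtlsd
  if (is.null(mtlsd)) {
    cfg <- config$cfg_mtlsd
    cfg$master_seed <- derive_subseed(config$master_seed, 3)
    repm <- train_3d_mtlsd(config$vol2_raw, pseudo_gt, config$spec_mtlsd,
                           cfg, sigma = config$sigma)
    mtlsd <- repm$model
    report$stages$train_mtlsd <- list(
      iterations = mtlsd$iteration,
      final_loss = unname(tail(mtlsd$loss_trace, 1)),
      elapsed_s = stage_time())
  } else report$stages$train_mtlsd <- list(cached = TRUE)

  # (d) inference + post-processing grid search on volume 1
  preds1 <- predict_3d(mtlsd, config$vol1_raw)
  affs1 <- preds1$affs
  if (config$evaluate && !is.null(config$vol1_gt)) {
    gs <- grid_search(affs1, config$vol1_gt, config$boundary_thresholds,
                      config$merge_thresholds, metric = "voi_sum")
    bt <- gs$best$boundary_threshold
    mt <- gs$best$merge_threshold
    report$stages$grid_search <- list(
      table = gs$table, boundary_threshold = bt, merge_threshold = mt,
      elapsed_s = stage_time())
  } else {
    bt <- config$boundary_thresholds[1]
    mt <- config$merge_thresholds[1]
  }
  parts1 <- segment(affs1, bt, mt, return_parts = TRUE)
  seg1 <- parts1$segmentation
  report$stages$segment_vol1 <- list(
    n_segments = length(unique(seg1$data[seg1$data > 0])),
    boundary_threshold = bt, merge_threshold = mt,
    content = content_ref(seg1$data), elapsed_s = stage_time())
  if (!is.null(config$store)) {
    write_volume(affs1, file.path(config$store, "vol1_affs.zarr"),
                 overwrite = TRUE)
    write_volume(seg1, file.path(config$store, "vol1_seg.zarr"),
                 overwrite = TRUE)
  }

  # (e) evaluation against volume 1 ground truth
  if (config$evaluate && !is.null(config$vol1_gt)) {
    gt <- filter_ground_truth(config$vol1_gt, config$min_size)
    skels <- skeletonize(gt, config$prune_length)
    mcm <- min_cut_metric(skels, seg1, parts1$rag, parts1$fragments)
    voi <- variation_of_information(seg1, gt)
    emap <- lsd_error_map(preds1$lsd, seg1, config$sigma,
                          config$error_threshold, config$opening_radius)
    report$metrics <- list(
      mcm_splits = mcm$splits, mcm_merges = mcm$merges,
      mcm_total = mcm$total, mcm_per_object = mcm$per_object,
      mcm_per_length = mcm$per_length,
      voi_split = voi$voi_split, voi_merge = voi$voi_merge,
      voi_sum = voi$sum,
      lsd_error_mean = mean(emap$error_map),
      lsd_error_mask_fraction = mean(emap$error_mask),
      n_gt_objects = length(skels))
    report$stages$evaluate <- list(elapsed_s = stage_time())
  }
  report$models <- list(model2d = model2d, model3d = model3d, mtlsd = mtlsd)
  report$outputs <- list(segmentation = seg1, affs = affs1,
                         pseudo_gt = pseudo_gt, lsd = preds1$lsd,
                         fragments = parts1$fragments, rag = parts1$rag)
  if (!is.null(config$store)) {
    js <- report
    js$models <- NULL
    js$outputs <- NULL
    jsonlite::write_json(js, file.path(config$store, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  class(report) <- "bootstrap_report"
  report
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat("<bootstrap_report>\n")
  for (s in names(x$stages))
    cat(sprintf("  %-14s %s\n", s,
                paste(names(x$stages[[s]]), "=",
                      vapply(x$stages[[s]], function(v)
                        paste(format(unlist(v))[1], collapse = ","),
                        character(1)), collapse = "  ")))
  if (!is.null(x$metrics))
    cat(sprintf("  MCM %.3f edits/object; VOI %.3f bits\n",
                x$metrics$mcm_per_object, x$metrics$voi_sum))
  invisible(x)
}

#' Self-contained synthetic bootstrap demonstration
#'
#' Builds the full two-volume study from synthetic data: two label volumes
#' drawn from the generator, raw images rendered with per-object shading,
#' a single-section sparse annotation on volume 1, desk-scale network
#' configurations, and the post-processing grids; then either returns the
#' config or also runs the bootstrap.
#'
#' @param shape volume shape, default `c(64, 96, 96)`.
#' @param master_seed master seed fixing every stage.
#' @param iterations named vector of training budgets
#'   (`train2d`, `train3d`, `mtlsd`).
#' @param annotation_fraction fraction of instances annotated on the single
#'   section of volume 1.
#' @param store optional output directory.
#' @param run run the bootstrap and return its report (otherwise return the
#'   config)?
#' @return a `bootstrap_report` (if `run`) or a [bootstrap_config()].
#' @export
demo_bootstrap <- function(shape = c(64, 96, 96), master_seed = 1,
                           iterations = c(train2d = 500, train3d = 300,
                                          mtlsd = 300),
                           annotation_fraction = 0.3, store = NULL,
                           run = TRUE) {
  sigma <- 20
  sp1 <- synth_params(shape, seed = derive_subseed(master_seed, 101))
  sp2 <- synth_params(shape, seed = derive_subseed(master_seed, 102))
  gt1 <- generate_labels(sp1)
  gt2 <- generate_labels(sp2)
  raw1 <- render_raw(gt1, seed = derive_subseed(master_seed, 103))
  raw2 <- render_raw(gt2, seed = derive_subseed(master_seed, 104))
  ann <- simulate_sparse_annotation(gt1, "single_section_fraction",
                                    annotation_fraction,
                                    seed = derive_subseed(master_seed, 105))
  # a small receptive field keeps the sparsely supervised 2D model a local
  # geometric feature extractor rather than letting it memorize the few
  # annotated instances
  spec2d <- model_spec(2, in_channels = 1, out_heads = c(lsd = 6),
                       depth = 1, base_features = 8)
  cfg2d <- train_config(iterations[["train2d"]], patch_shape = c(48, 48),
                        learning_rate = 1e-3, weight_decay = 1e-2,
                        augmentations = c("flips", "transpose", "intensity",
                                          "noise"),
                        master_seed = master_seed)
  spec3d <- model_spec(3, in_channels = 6, out_heads = c(affs = 3),
                       depth = 1, base_features = 8,
                       downsample_factors = list(c(1L, 2L, 2L)))
  cfg3d <- train_config(iterations[["train3d"]],
                        patch_shape = c(8, 16, 16), learning_rate = 3e-3,
                        augmentations = character(),
                        master_seed = master_seed)
  spec_mtlsd <- model_spec(3, in_channels = 1,
                           out_heads = c(affs = 3, lsd = 10),
                           depth = 1, base_features = 12,
                           downsample_factors = list(c(1L, 2L, 2L)))
  cfg_mtlsd <- train_config(iterations[["mtlsd"]],
                            patch_shape = c(8, 16, 16), learning_rate = 1e-3,
                            augmentations = c("flips", "intensity"),
                            master_seed = master_seed)
  synth <- synth_params(c(8, 16, 16), num_objects = c(6, 14),
                        seed = master_seed)
  degrade <- degrade_params(noise_sd = 0.1, jitter_max = 0,
                            dropout_prob = 0.02, blur_sigma = 0.5,
                            seed = master_seed)
  config <- bootstrap_config(
    vol1_raw = raw1, vol2_raw = raw2, annotation = ann, vol1_gt = gt1,
    sigma = sigma, spec2d = spec2d, cfg2d = cfg2d, spec3d = spec3d,
    cfg3d = cfg3d, synth = synth, degrade = degrade,
    spec_mtlsd = spec_mtlsd, cfg_mtlsd = cfg_mtlsd,
    boundary_thresholds = c(0.25, 0.5),
    merge_thresholds = c(0.3, 0.5, 0.7, 0.85),
    store = store, master_seed = master_seed)
  if (!run) return(config)
  run_bootstrap(config)
}
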