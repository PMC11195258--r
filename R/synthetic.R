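#' Parameters of the synthetic instance-label generator
#'
#' The generator emulates densely packed, space-filling 3D instances with
#' optionally elongated, neurite-like morphology: a Gaussian-smoothed noise
#' potential (anisotropically stretched) is partitioned by a seeded
#' watershed, then roughened by random per-object dilation/erosion rounds,
#' and optionally shrunk to leave background shells between objects.
#'
#' @param shape volume shape `(z, y, x)` in voxels, each axis >= 8.
#' @param voxel_size nm per axis `(z, y, x)`.
#' @param num_objects integer range `(lo, hi)`, lower bound >= 1.
#' @param smoothness Gaussian scale of the noise potential in nm.
#' @param elongation 3 x 2 matrix of per-axis stretch factor ranges
#'   `(z, y, x)` rows; factors > 0. Larger stretch along an axis elongates
#'   objects along it.
#' @param gap_thickness voxels of inter-object background shell (0 =
#'   space-filling).
#' @param perturb_iterations integer range of random per-object
#'   dilate/erode rounds.
#' @param seed integer seed; the draw is fully deterministic given it.
#' @export
synth_params <- function(shape,
                         voxel_size = c(10, 10, 10),
                         num_objects = c(20, 30),
                         smoothness = 100,
                         elongation = rbind(z = c(1, 3),
                                            y = c(1, 1.5),
                                            x = c(1, 1.5)),
                         gap_thickness = 0,
                         perturb_iterations = c(2, 6),
                         seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 8),
            num_objects[1] >= 1, num_objects[2] >= num_objects[1],
            all(elongation > 0), gap_thickness >= 0,
            all(perturb_iterations >= 0), smoothness > 0)
  structure(list(shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size),
                 num_objects = as.integer(num_objects),
                 smoothness = smoothness,
                 elongation = matrix(elongation, nrow = 3),
                 gap_thickness = as.integer(gap_thickness),
                 perturb_iterations = as.integer(perturb_iterations),
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Parameters of the stacked-2D prediction degradation model
#'
#' Emulates imperfections of per-section 2D descriptor predictions: additive
#' channel noise, per-section translation jitter, per-section blur, and
#' whole-section dropout.
#'
#' @param noise_sd Gaussian noise s.d. on descriptor channels (>= 0).
#' @param jitter_max maximum per-section random `(y, x)` integer shift in
#'   voxels.
#' @param dropout_prob probability in `[0, 1]` that a section's descriptors
#'   are zeroed.
#' @param blur_sigma per-section Gaussian smoothing in voxels (>= 0).
#' @param seed integer seed.
#' @export
degrade_params <- function(noise_sd = 0.05, jitter_max = 1,
                           dropout_prob = 0.05, blur_sigma = 0.5,
                           seed = 1) {
  stopifnot(noise_sd >= 0, jitter_max >= 0,
            dropout_prob >= 0, dropout_prob <= 1, blur_sigma >= 0)
  structure(list(noise_sd = noise_sd, jitter_max = as.integer(jitter_max),
                 dropout_prob = dropout_prob, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "degrade_params")
}

# neighbor shift helper: label of the 6-neighbor in direction (dz,dy,dx),
# out-of-bounds replicated (no new boundary at the volume edge)
shift_edge_replicate <- function(a, dz, dy, dx) {
  d <- dim(a)
  iz <- pmin(pmax(seq_len(d[1]) + dz, 1), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
  ix <- pmin(pmax(seq_len(d[3]) + dx, 1), d[3])
  a[iz, iy, ix, drop = FALSE]
}

face_neighbors <- function() {
  rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
        c(0, 0, -1), c(0, 0, 1))
}

#' Generate a random synthetic 3D instance labeling
#'
#' Draws seed points, floods a smoothed-noise potential with a seeded
#' watershed into a space-filling partition, applies random per-object
#' morphological perturbation rounds (erosion hands voxels to the adjacent
#' object with the smallest id; components disconnected by perturbation are
#' reassigned to keep every object face-connected), and optionally erodes
#' each object by `gap_thickness` voxels to introduce background shells.
#' Deterministic given `params$seed`. Degenerate draws (an object erased
#' entirely) are retried with a fresh sub-seed up to 5 times.
#'
#' @param params a [synth_params()].
#' @return a [label_volume()] with between 1 and `num_objects[2]` objects.
#' @export
generate_labels <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  for (attempt in 0:4) {
    seed <- derive_subseed(params$seed, attempt)
    out <- try(withr::with_seed(seed, generate_labels_once(params)),
               silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  stop("synthetic label generation failed after 5 attempts: ",
       attr(out, "condition")$message)
}

generate_labels_once <- function(params) {
  d <- params$shape
  n <- if (params$num_objects[1] == params$num_objects[2]) params$num_objects[1]
  else sample(params$num_objects[1]:params$num_objects[2], 1)
  stretch <- vapply(1:3, function(a)
    runif(1, params$elongation[a, 1], params$elongation[a, 2]), numeric(1))
  sigma_vox <- params$smoothness * stretch / params$voxel_size
  pot <- array(runif(prod(d)), dim = d)
  pot <- cpp_gaussian_blur(pot, sigma_vox)
  pot <- (pot - min(pot)) / max(max(pot) - min(pot), 1e-12) + 0.05
  idx <- sample(prod(d), n)
  seeds <- array(0L, dim = d)
  seeds[idx] <- seq_len(n)
  allow <- array(TRUE, dim = d)
  faces <- array(TRUE, c(3, d))
  # regions grow competitively from the seeds by accumulated noise cost;
  # cheaper steps along stretched axes elongate the objects
  step_cost <- params$voxel_size / stretch
  step_cost <- step_cost / min(step_cost)
  lab <- cpp_watershed(pot, allow, seeds, faces, accumulate = TRUE,
                       step_cost = step_cost)
  lab <- array(as.numeric(lab), dim = d)

  n_pert <- if (params$perturb_iterations[1] == params$perturb_iterations[2])
    params$perturb_iterations[1]
  else sample(params$perturb_iterations[1]:params$perturb_iterations[2], 1)
  nb <- face_neighbors()
  for (i in seq_len(n_pert)) {
    id <- sample(seq_len(n), 1)
    op <- sample(c("dilate", "erode"), 1)
    obj <- lab == id
    if (!any(obj)) next
    if (op == "dilate") {
      grow <- array(FALSE, dim = d)
      for (k in seq_len(nrow(nb)))
        grow <- grow | shift_edge_replicate(obj, nb[k, 1], nb[k, 2], nb[k, 3])
      lab[grow & !obj] <- id
    } else {
      # boundary voxels of the object go to the smallest adjacent other id
      nbr_min <- array(Inf, dim = d)
      is_boundary <- array(FALSE, dim = d)
      for (k in seq_len(nrow(nb))) {
        nl <- shift_edge_replicate(lab, nb[k, 1], nb[k, 2], nb[k, 3])
        other <- obj & nl != id
        is_boundary <- is_boundary | other
        nbr_min[other] <- pmin(nbr_min[other], nl[other])
      }
      if (all(is_boundary == obj)) next # would erase the object
      lab[is_boundary] <- ifelse(is.finite(nbr_min[is_boundary]),
                                 nbr_min[is_boundary], 0)
    }
  }
  lab <- reconnect_objects(lab)
  if (params$gap_thickness > 0) {
    for (i in seq_len(params$gap_thickness)) {
      shell <- array(FALSE, dim = d)
      for (k in seq_len(nrow(nb))) {
        nl <- shift_edge_replicate(lab, nb[k, 1], nb[k, 2], nb[k, 3])
        shell <- shell | (lab > 0 & nl != lab)
      }
      lab[shell] <- 0
    }
  }
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  if (!length(ids)) stop("all objects eroded away")
  lab <- array(match(lab, c(0, ids)) - 1, dim = d)
  label_volume(lab, params$voxel_size, c(0, 0, 0))
}

# keep the largest face-connected component of each id; smaller components
# are merged into the adjacent object with the smallest id
reconnect_objects <- function(lab) {
  d <- dim(lab)
  nb <- face_neighbors()
  passes <- 0
  repeat {
    passes <- passes + 1
    if (passes > 50) stop("could not reconnect perturbed objects")
    comp <- cpp_label_components(lab, 6L, logical(0))
    tab <- table(factor(lab[comp > 0], levels = sort(unique(lab[lab > 0]))),
                 comp[comp > 0])
    # components per id
    moved <- FALSE
    for (id in rownames(tab)) {
      comps <- which(tab[id, ] > 0)
      if (length(comps) <= 1) next
      main <- comps[which.max(tab[id, comps])]
      for (cc in setdiff(comps, main)) {
        sel <- comp == as.integer(colnames(tab)[cc])
        nbr_min <- Inf
        for (k in seq_len(nrow(nb))) {
          nl <- shift_edge_replicate(lab, nb[k, 1], nb[k, 2], nb[k, 3])
          vals <- nl[sel]
          vals <- vals[vals > 0 & vals != as.numeric(id)]
          if (length(vals)) nbr_min <- min(nbr_min, vals)
        }
        lab[sel] <- if (is.finite(nbr_min)) nbr_min else 0
        moved <- TRUE
      }
    }
    if (!moved) return(lab)
  }
}

#' Simulate degraded stacked per-section 2D descriptor predictions
#'
#' Computes clean per-section 2D descriptors of `labels`, then degrades each
#' section independently: random integer `(y, x)` translation up to
#' `jitter_max` (zero fill), per-section Gaussian blur, additive channel
#' noise, clipping to `[0, 1]`, and whole-section dropout with probability
#' `dropout_prob`. Each section consumes sub-seed
#' `derive_subseed(degrade$seed, z)` so single sections are reproducible in
#' isolation.
#'
#' @param labels a [label_volume()].
#' @param sigma descriptor scale in nm (see [compute_lsd()]).
#' @param degrade a [degrade_params()].
#' @return a 6-channel [descriptor_grid()].
#' @export
simulate_stacked_predictions <- function(labels, sigma, degrade) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(degrade, "degrade_params"))
  lsd <- compute_lsd(labels, sigma, dimensionality = 2)
  dat <- lsd$data
  d <- dim(dat)
  for (z in seq_len(d[2])) {
    sec <- dat[, z, , , drop = FALSE]
    withr::with_seed(derive_subseed(degrade$seed, z - 1), {
      if (degrade$jitter_max > 0) {
        sh <- sample(seq(-degrade$jitter_max, degrade$jitter_max), 2,
                     replace = TRUE)
        sec <- shift_section(sec, sh[1], sh[2])
      }
      if (degrade$blur_sigma > 0) {
        for (cc in seq_len(d[1])) {
          plane <- array(sec[cc, 1, , ], dim = c(1, d[3], d[4]))
          sec[cc, 1, , ] <- cpp_gaussian_blur(
            plane, c(0, degrade$blur_sigma, degrade$blur_sigma))
        }
      }
      if (degrade$noise_sd > 0)
        sec <- sec + array(rnorm(length(sec), 0, degrade$noise_sd), dim(sec))
      sec <- clip01(sec)
      if (runif(1) < degrade$dropout_prob) sec[] <- 0
    })
    dat[, z, , ] <- sec
  }
  descriptor_grid(dat, lsd$sigma, labels$voxel_size, labels$offset)
}

# integer (y,x) shift of a (C,1,y,x) section with zero fill
shift_section <- function(sec, sy, sx) {
  d <- dim(sec)
  out <- array(0, d)
  ys <- seq_len(d[3]); xs <- seq_len(d[4])
  ysrc <- ys - sy; xsrc <- xs - sx
  ky <- ysrc >= 1 & ysrc <= d[3]
  kx <- xsrc >= 1 & xsrc <= d[4]
  out[, , ys[ky], xs[kx]] <- sec[, , ysrc[ky], xsrc[kx], drop = FALSE]
  out
}

#' Generate one synthetic 2D->3D training pair
#'
#' Labels are drawn with [generate_labels()], the input is the degraded
#' stacked per-section descriptor simulation, the target is the
#' direct-neighbor 3D affinity graph of the labels, and the weights are 1
#' wherever the affinity mask is true (synthetic labels are dense; only
#' out-of-bounds entries are unsupervised).
#'
#' @inheritParams generate_labels
#' @inheritParams simulate_stacked_predictions
#' @return list with elements `input` ([descriptor_grid()]), `target`
#'   ([affinity_grid()]), `weights` (array), `labels` ([label_volume()]).
#' @export
make_training_pair <- function(params, sigma, degrade) {
  labels <- generate_labels(params)
  input <- simulate_stacked_predictions(labels, sigma, degrade)
  target <- compute_affinities(labels)
  weights <- make_loss_weights(NULL, target)
  list(input = input, target = target, weights = weights, labels = labels)
}
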