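#' Compute local shape descriptors from a label volume
#'
#' Per-voxel Gaussian-weighted local statistics of the object containing each
#' voxel. For a voxel `v` with label `L > 0`, weights
#' `w(u) = exp(-sum_a (u_a - v_a)^2 vs_a^2 / (2 sigma_a^2))` are accumulated
#' over same-label voxels `u` within the 3-sigma box; the descriptor channels
#' are the local mean offset (mapped per axis from `[-sigma, sigma]` to
#' `[0, 1]`), the coordinate variances (divided by `sigma^2`), the pairwise
#' Pearson correlations (mapped from `[-1, 1]` to `[0, 1]`), and the local
#' size (Gaussian mass relative to an unbounded same-label region), in that
#' order. Background voxels get the all-zero vector. With
#' `dimensionality = 2`, descriptors are computed independently per
#' z-section over the `(y, x)` axes (6 channels); with 3, over all axes
#' (10 channels). Anisotropy is handled in world units.
#'
#' @param labels a [label_volume()].
#' @param sigma Gaussian scale in nm, scalar or per axis `(z, y, x)`.
#' @param dimensionality 2 or 3.
#' @return a [descriptor_grid()].
#' @export
compute_lsd <- function(labels, sigma, dimensionality = 3) {
  stopifnot(inherits(labels, "label_volume"),
            dimensionality %in% c(2, 3))
  sigma <- rep(as.numeric(sigma), length.out = 3)
  if (any(sigma <= 0)) stop("sigma must be strictly positive per axis")
  data <- cpp_compute_lsd(labels$data, labels$voxel_size, sigma,
                          dimensionality == 2)
  descriptor_grid(data, sigma, labels$voxel_size, labels$offset)
}

#' Compute direct-neighbor affinities from a label volume
#'
#' Channel `d` at voxel `p` is 1 iff `labels[p] > 0` and the partner voxel
#' `p + offset_d` exists and carries the same label, else 0; background (id
#' 0) never bonds. Entries whose partner lies outside the volume are 0 and
#' mask-false; in sparse mode (an annotation supplied), entries where either
#' voxel is outside `labeled_mask` are mask-false as well.
#'
#' @param labels a [label_volume()].
#' @param neighborhood `D x 3` integer matrix of nonzero offsets `(dz,dy,dx)`.
#' @param annotation optional [sparse_annotation()] restricting supervision.
#' @return an [affinity_grid()] with `{0,1}` values and a validity mask.
#' @export
compute_affinities <- function(labels, neighborhood = default_neighborhood(),
                               annotation = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  neighborhood <- matrix(as.integer(neighborhood), ncol = 3)
  if (any(rowSums(abs(neighborhood)) == 0))
    stop("neighborhood offsets must be nonzero")
  d <- dim(labels$data)
  D <- nrow(neighborhood)
  affs <- array(0, c(D, d))
  mask <- array(FALSE, c(D, d))
  lab <- labels$data
  for (k in seq_len(D)) {
    off <- neighborhood[k, ]
    src <- lapply(1:3, function(a) {
      i <- seq_len(d[a])
      i[(i + off[a]) >= 1 & (i + off[a]) <= d[a]]
    })
    if (any(lengths(src) == 0)) next
    dst <- lapply(1:3, function(a) src[[a]] + off[a])
    lp <- lab[src[[1]], src[[2]], src[[3]], drop = FALSE]
    lq <- lab[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    a_k <- (lp > 0) & (lp == lq)
    m_k <- array(TRUE, dim(lp))
    if (!is.null(annotation)) {
      am <- annotation$labeled_mask
      m_k <- am[src[[1]], src[[2]], src[[3]], drop = FALSE] &
        am[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    }
    affs[k, src[[1]], src[[2]], src[[3]]] <- a_k
    mask[k, src[[1]], src[[2]], src[[3]]] <- m_k
  }
  affinity_grid(affs, neighborhood = neighborhood, mask = mask,
                voxel_size = labels$voxel_size, offset = labels$offset)
}

#' Loss weights from a sparse annotation
#'
#' Weights are 0 outside `labeled_mask` (and outside the affinity validity
#' mask for affinity targets), 1 inside. With `balance = TRUE` (affinity
#' targets only) the in-mask weight of each binary affinity class is made
#' inversely proportional to its within-mask frequency and normalized so the
#' mean in-mask weight is 1.
#'
#' @param annotation a [sparse_annotation()], or `NULL` for dense supervision.
#' @param target a [descriptor_grid()] or [affinity_grid()].
#' @param balance class-balance affinity weights?
#' @return a weight array shaped like `target$data` (a `volume_grid` with
#'   semantic `"weight"` is not used here; plain array keeps broadcasting
#'   explicit).
#' @export
make_loss_weights <- function(annotation, target, balance = FALSE) {
  dims <- dim(target$data)
  C <- dims[1]
  if (!is.null(annotation) &&
      !identical(dim(annotation$labeled_mask), dims[-1]))
    stop("annotation mask shape does not match target")
  vox_mask <- if (is.null(annotation)) array(TRUE, dims[-1])
  else annotation$labeled_mask
  w <- array(0, dims)
  full <- aperm(array(vox_mask, c(dims[-1], C)), c(4, 1, 2, 3))
  if (inherits(target, "affinity_grid")) full <- full & target$mask
  w[full] <- 1
  if (balance) {
    if (!inherits(target, "affinity_grid"))
      stop("class balancing applies to affinity targets only")
    inm <- which(full)
    if (length(inm)) {
      pos <- target$data[inm] > 0.5
      fpos <- mean(pos)
      if (fpos > 0 && fpos < 1) {
        wv <- ifelse(pos, 1 / fpos, 1 / (1 - fpos))
        w[inm] <- wv / mean(wv)
      }
    }
  }
  w
}

#' Masked weighted mean-squared-error loss
#'
#' `L = sum(w * (pred - target)^2) / max(sum(w), 1e-8)`. Multi-head losses
#' are summed with unit head weights by callers. The epsilon guard makes an
#' all-zero weight grid yield zero loss, and the gradient with respect to
#' any zero-weight prediction entry is exactly zero.
#'
#' @param pred,target numeric arrays of identical shape.
#' @param weights non-negative weight array of the same shape.
#' @return scalar loss.
#' @export
masked_mse <- function(pred, target, weights) {
  if (!identical(dim(pred), dim(target)) ||
      !identical(dim(pred), dim(weights)))
    stop("pred, target and weights must have identical shapes")
  sum(weights * (pred - target)^2) / max(sum(weights), 1e-8)
}
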