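#' Volumetric grid containers
#'
#' All volumes use a fixed axis convention: data arrays are indexed
#' `(z, y, x)` with `z` the sectioning axis, optionally with a leading channel
#' axis `(c, z, y, x)` for descriptor and affinity grids. Voxel indices are
#' 0-based in world-coordinate formulas: the world position of voxel
#' `(i, j, k)` is `offset + c(i, j, k) * voxel_size` (voxel-corner
#' convention), with `voxel_size` and `offset` in nanometers per axis
#' `(z, y, x)`.
#'
#' @param data numeric array, `(z, y, x)` or `(c, z, y, x)` for channelled
#'   semantics.
#' @param voxel_size positive numeric length 3, nm per axis `(z, y, x)`.
#' @param offset numeric length 3, world coordinate of voxel `(0, 0, 0)` in nm.
#' @param semantic one of `"raw"`, `"descriptor"`, `"affinity"`, `"weight"`,
#'   `"labels"`.
#' @return an object of class `volume_grid` (or `label_volume` from
#'   [label_volume()]).
#' @export
volume_grid <- function(data, voxel_size, offset = c(0, 0, 0),
                        semantic = "raw") {
  semantic <- match.arg(semantic,
                        c("raw", "descriptor", "affinity", "weight", "labels"))
  if (semantic == "labels") return(label_volume(data, voxel_size, offset))
  stopifnot(is.array(data), is.numeric(data))
  channelled <- semantic %in% c("descriptor", "affinity")
  nd <- length(dim(data))
  if (channelled && nd != 4)
    stop("semantic '", semantic, "' requires a (c, z, y, x) array")
  if (!channelled && nd != 3)
    stop("semantic '", semantic, "' requires a (z, y, x) array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive values (z, y, x)")
  if (any(!is.finite(data))) stop("grid values must be finite")
  if (semantic %in% c("descriptor", "affinity") &&
      (min(data) < 0 || max(data) > 1))
    stop(semantic, " values must lie in [0, 1]")
  structure(
    list(data = data, voxel_size = voxel_size,
         offset = as.numeric(offset), semantic = semantic),
    class = "volume_grid")
}

#' @rdname volume_grid
#' @export
label_volume <- function(data, voxel_size, offset = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "double"
  if (any(data < 0) || any(data != floor(data)))
    stop("labels must be non-negative integers (0 = background)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive values (z, y, x)")
  structure(
    list(data = data, voxel_size = voxel_size,
         offset = as.numeric(offset), semantic = "labels"),
    class = c("label_volume", "volume_grid"))
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %s  dim [%s]  voxel_size (%s) nm  offset (%s) nm\n",
              class(x)[1], x$semantic, paste(d, collapse = "x"),
              paste(x$voxel_size, collapse = ","),
              paste(x$offset, collapse = ",")))
  invisible(x)
}

#' Per-voxel local shape descriptor grid
#'
#' Channel-first `(C, z, y, x)` array of local shape descriptors in `[0, 1]`;
#' `C = 6` for per-section 2D descriptors (channels: mean offset y, x;
#' variance y, x; correlation yx; size) and `C = 10` for 3D (mean offset
#' z, y, x; variance z, y, x; correlations zy, zx, yx; size).
#'
#' @param data `(C, z, y, x)` numeric array in `[0, 1]`.
#' @param sigma Gaussian scale in nm per axis `(z, y, x)`.
#' @inheritParams volume_grid
#' @export
descriptor_grid <- function(data, sigma, voxel_size, offset = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 4,
            dim(data)[1] %in% c(6L, 10L))
  g <- volume_grid(data, voxel_size, offset, semantic = "descriptor")
  g$sigma <- as.numeric(sigma)
  class(g) <- c("descriptor_grid", class(g))
  g
}

#' Direct-neighbor affinity grid
#'
#' Channel-first `(D, z, y, x)` connectivity values in `[0, 1]`, one channel
#' per neighborhood offset; channel `d` at voxel `p` is the affinity of the
#' bond between `p` and `p + neighborhood[d, ]`. The accompanying logical
#' `mask` marks supervised (valid) entries; entries whose partner voxel lies
#' outside the volume are 0 and mask-false.
#'
#' @param data `(D, z, y, x)` numeric array in `[0, 1]`.
#' @param neighborhood `D x 3` integer matrix of nonzero voxel offsets
#'   `(dz, dy, dx)`; default the direct 3D neighborhood
#'   `(-1,0,0), (0,-1,0), (0,0,-1)`.
#' @param mask logical array of the same shape as `data`.
#' @inheritParams volume_grid
#' @export
affinity_grid <- function(data, neighborhood = default_neighborhood(),
                          mask = NULL, voxel_size = c(1, 1, 1),
                          offset = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  neighborhood <- as.matrix(neighborhood)
  if (nrow(neighborhood) != dim(data)[1])
    stop("one neighborhood offset per affinity channel required")
  if (any(rowSums(abs(neighborhood)) == 0))
    stop("neighborhood offsets must be nonzero")
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  g <- volume_grid(data, voxel_size, offset, semantic = "affinity")
  g$neighborhood <- neighborhood
  g$mask <- mask
  class(g) <- c("affinity_grid", class(g))
  g
}

#' @rdname affinity_grid
#' @export
default_neighborhood <- function() {
  matrix(c(-1L, 0L, 0L, 0L, -1L, 0L, 0L, 0L, -1L), nrow = 3, byrow = TRUE)
}

#' Sparse annotation: labels plus an annotator-decision mask
#'
#' `labeled_mask` is true exactly where the annotator made a decision,
#' including explicit background; voxels outside it contribute zero loss
#' weight during training.
#'
#' @param labels a [label_volume()].
#' @param labeled_mask logical `(z, y, x)` array; must cover every positively
#'   labeled voxel.
#' @export
sparse_annotation <- function(labels, labeled_mask) {
  stopifnot(inherits(labels, "label_volume"),
            is.logical(labeled_mask),
            identical(dim(labels$data), dim(labeled_mask)))
  if (any(labels$data > 0 & !labeled_mask))
    stop("every labeled voxel must be inside labeled_mask")
  structure(list(labels = labels, labeled_mask = labeled_mask),
            class = "sparse_annotation")
}

#' Skeleton: a center-line graph of one object
#'
#' @param object_id positive integer id of the object.
#' @param nodes data.frame with columns `node_id`, `z`, `y`, `x` (world nm).
#' @param edges 2-column matrix of unordered node-id pairs (may have 0 rows).
#' @export
skeleton <- function(object_id, nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  stopifnot(object_id > 0, all(c("node_id", "z", "y", "x") %in% names(nodes)))
  if (nrow(edges)) {
    if (any(!(edges %in% nodes$node_id))) stop("edge endpoint not among nodes")
    if (any(edges[, 1] == edges[, 2])) stop("self-loop edges are not allowed")
  }
  structure(list(object_id = as.numeric(object_id), nodes = nodes,
                 edges = edges),
            class = "skeleton")
}

#' Total path length of a skeleton in world units (nm)
#' @param skel a [skeleton()].
#' @export
skeleton_length <- function(skel) {
  if (!nrow(skel$edges)) return(0)
  a <- match(skel$edges[, 1], skel$nodes$node_id)
  b <- match(skel$edges[, 2], skel$nodes$node_id)
  sum(sqrt((skel$nodes$z[a] - skel$nodes$z[b])^2 +
             (skel$nodes$y[a] - skel$nodes$y[b])^2 +
             (skel$nodes$x[a] - skel$nodes$x[b])^2))
}
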