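#' Filter small ground-truth labels and relabel connected components
#'
#' Removes (sets to 0) every label whose voxel count is strictly below
#' `min_size`, then relabels the face-connected components of the remaining
#' foreground with fresh consecutive ids (so a label with two disconnected
#' parts becomes two objects). Idempotent.
#'
#' @param labels a [label_volume()].
#' @param min_size minimum object size in voxels (default 500).
#' @return a filtered, relabeled [label_volume()].
#' @export
filter_ground_truth <- function(labels, min_size = 500) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$data
  if (any(lab > 0)) {
    sizes <- table(lab[lab > 0])
    small <- as.numeric(names(sizes)[sizes < min_size])
    if (length(small)) lab[lab %in% small] <- 0
  }
  comp <- cpp_label_components(lab, 6L, logical(0))
  out <- labels
  out$data <- array(as.numeric(comp), dim(lab))
  out
}

#' Skeletonize a label volume to per-object center-line graphs
#'
#' Per object: distance-ordered 3D homotopic thinning (26-connected
#' foreground) reduces the mask to a center line; skeleton voxels become
#' nodes at voxel-center world coordinates, 26-adjacent skeleton voxels are
#' connected, transitive shortcuts are removed by keeping a minimum
#' spanning structure (edge weights = world lengths), and terminal branches
#' shorter than `prune_length` are pruned. Objects thinner than one voxel
#' everywhere reduce to a single node.
#'
#' @param labels a (filtered) [label_volume()].
#' @param prune_length terminal-twig pruning threshold in nm; default 10x
#'   the minimum voxel size.
#' @return a list of [skeleton()] objects (class `skeleton_set`).
#' @export
skeletonize <- function(labels, prune_length = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  vs <- labels$voxel_size
  if (is.null(prune_length)) prune_length <- 10 * min(vs)
  d <- dim(labels$data)
  ids <- sort(unique(as.vector(labels$data)))
  ids <- ids[ids > 0]
  skels <- lapply(ids, function(id) {
    idx <- which(labels$data == id, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - 1, 1)
    hi <- pmin(apply(idx, 2, max) + 1, d)
    sub <- labels$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    m <- array(sub == id, hi - lo + 1)
    dist <- cpp_edt(m, vs)
    cap <- max(dist[is.finite(dist)], 0) + 1
    dist[!is.finite(dist)] <- cap
    sk <- cpp_thin(m, dist)
    vox <- which(sk, arr.ind = TRUE)
    # world coordinates at voxel centers
    g0 <- sweep(vox - 1, 2, lo - 1, "+")
    pos <- sweep(sweep(g0, 2, vs, "*"), 2, labels$offset + 0.5 * vs, "+")
    nodes <- data.frame(node_id = seq_len(nrow(vox)),
                        z = pos[, 1], y = pos[, 2], x = pos[, 3])
    if (nrow(vox) <= 1)
      return(skeleton(id, nodes, matrix(integer(), ncol = 2)))
    # 26-adjacency edges among skeleton voxels (linear-index lookup)
    bb <- hi - lo + 1
    key <- (vox[, 1] - 1) + bb[1] * ((vox[, 2] - 1) + bb[2] * (vox[, 3] - 1))
    ea <- integer(); eb <- integer(); ew <- numeric()
    offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    offs <- offs[rowSums(abs(offs)) > 0, ]
    # each unordered pair once: keep lexicographically positive offsets
    offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                   (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
    for (r in seq_len(nrow(offs))) {
      nz2 <- vox[, 1] + offs$dz[r]; ny2 <- vox[, 2] + offs$dy[r]
      nx2 <- vox[, 3] + offs$dx[r]
      inb <- nz2 >= 1 & nz2 <= bb[1] & ny2 >= 1 & ny2 <= bb[2] &
        nx2 >= 1 & nx2 <= bb[3]
      nk <- (nz2 - 1) + bb[1] * ((ny2 - 1) + bb[2] * (nx2 - 1))
      hit <- match(nk, key)
      ok <- inb & !is.na(hit)
      if (!any(ok)) next
      ea <- c(ea, which(ok))
      eb <- c(eb, hit[ok])
      ew <- c(ew, rep(sqrt(sum((c(offs$dz[r], offs$dy[r], offs$dx[r]) * vs)^2)),
                      sum(ok)))
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = ea, to = eb, weight = ew), directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(vox))))
    g <- igraph::mst(g)
    g <- prune_twigs(g, prune_length)
    keep <- as.integer(igraph::V(g)$name)
    nodes <- nodes[nodes$node_id %in% keep, , drop = FALSE]
    el <- igraph::as_edgelist(g)
    edges <- matrix(as.integer(el), ncol = 2)
    skeleton(id, nodes, edges)
  })
  structure(skels, class = "skeleton_set")
}

# iteratively remove terminal branches (leaf up to the next junction) whose
# world length is below prune_length; never removes the last node
prune_twigs <- function(g, prune_length) {
  repeat {
    if (igraph::vcount(g) <= 1) return(g)
    deg <- igraph::degree(g)
    leaves <- which(deg == 1)
    if (!length(leaves)) return(g)
    removed_any <- FALSE
    drop <- integer()
    for (lf in leaves) {
      path <- lf
      len <- 0
      cur <- lf
      prev <- -1
      repeat {
        nbr <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nbr) != 1) break # junction or isolated
        e <- igraph::get_edge_ids(g, c(cur, nbr[1]))
        len <- len + igraph::E(g)$weight[e]
        if (igraph::degree(g, nbr[1]) > 2) { # reached a junction
          if (len < prune_length) drop <- c(drop, path)
          break
        }
        prev <- cur
        cur <- nbr[1]
        path <- c(path, cur)
        if (igraph::degree(g, cur) == 1) break # leaf-to-leaf path: keep
      }
    }
    drop <- unique(drop)
    if (!length(drop) || length(drop) >= igraph::vcount(g)) return(g)
    g <- igraph::delete_vertices(g, drop)
    removed_any <- TRUE
    if (!removed_any) return(g)
  }
}

#' Skeleton-based split/merge edit counts (adapted min-cut metric)
#'
#' Maps every skeleton node to the segment at its voxel (nodes on
#' background are dropped and logged). Split edits: per skeleton, the
#' number of connected components of the subgraph keeping only edges whose
#' endpoints share a segment, minus one. Merge edits: per segment hosting
#' k >= 2 skeletons, the number of min-cut operations (unit capacities, on
#' the fragment graph restricted to the segment) needed to separate all
#' skeleton pairs, processed in skeleton-id order; one edit per cut
#' operation. The total is also normalized per ground-truth object and per
#' skeleton path length (edits per micron).
#'
#' @param skeletons a `skeleton_set` (ground truth).
#' @param segmentation the evaluated [label_volume()].
#' @param rag,fragments the [build_rag()] graph and fragment volume of the
#'   same post-processing run (for merge-edit cuts).
#' @return list of class `edit_counts`: `splits`, `merges`, `total`,
#'   `per_object`, `per_length` (edits per micron of skeleton path).
#' @export
min_cut_metric <- function(skeletons, segmentation, rag, fragments) {
  stopifnot(inherits(segmentation, "label_volume"))
  d <- dim(segmentation$data)
  vs <- segmentation$voxel_size
  off <- segmentation$offset
  node_tables <- lapply(seq_along(skeletons), function(i) {
    sk <- skeletons[[i]]
    vox <- cbind(floor((sk$nodes$z - off[1]) / vs[1]),
                 floor((sk$nodes$y - off[2]) / vs[2]),
                 floor((sk$nodes$x - off[3]) / vs[3])) + 1
    vox <- pmin(pmax(vox, 1), matrix(d, nrow(vox), 3, byrow = TRUE))
    seg <- segmentation$data[vox]
    frag <- fragments$data[vox]
    data.frame(node_id = sk$nodes$node_id, seg = seg, frag = frag)
  })
  total_len_nm <- sum(vapply(skeletons, skeleton_length, numeric(1)))
  n_objects <- length(skeletons)
  splits <- 0
  used <- logical(length(skeletons))
  for (i in seq_along(skeletons)) {
    sk <- skeletons[[i]]
    nt <- node_tables[[i]]
    keep_nodes <- nt$node_id[nt$seg > 0]
    if (!length(keep_nodes)) {
      bs_log("skeleton ", sk$object_id, " lies entirely on background; excluded")
      next
    }
    used[i] <- TRUE
    segmap <- setNames(nt$seg, as.character(nt$node_id))
    e <- sk$edges
    if (nrow(e)) {
      ok <- segmap[as.character(e[, 1])] > 0 &
        segmap[as.character(e[, 2])] > 0 &
        segmap[as.character(e[, 1])] == segmap[as.character(e[, 2])]
      e <- e[ok, , drop = FALSE]
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e[, 1]), to = as.character(e[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(keep_nodes)))
    splits <- splits + igraph::count_components(g) - 1
  }
  # merge edits per segment hosting several skeletons
  merges <- 0
  seg_skels <- list()
  for (i in which(used)) {
    nt <- node_tables[[i]]
    for (s in unique(nt$seg[nt$seg > 0])) {
      k <- as.character(s)
      seg_skels[[k]] <- union(seg_skels[[k]], i)
    }
  }
  pos <- fragments$data > 0
  frag_to_seg <- tapply(segmentation$data[pos], fragments$data[pos],
                        function(v) v[1])
  for (s in names(seg_skels)) {
    si <- sort(seg_skels[[s]])
    if (length(si) < 2) next
    seg_id <- as.numeric(s)
    # fragment graph restricted to this segment
    frag_ids <- as.numeric(names(frag_to_seg)[frag_to_seg == seg_id])
    frag_ids <- intersect(frag_ids, rag$nodes$id)
    el <- rag$edges[rag$edges$a %in% frag_ids & rag$edges$b %in% frag_ids, ,
                    drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(el$a), to = as.character(el$b)),
      directed = FALSE, vertices = data.frame(name = as.character(frag_ids)))
    sets <- lapply(si, function(i) {
      nt <- node_tables[[i]]
      intersect(unique(nt$frag[nt$seg == seg_id & nt$frag > 0]), frag_ids)
    })
    sets <- Filter(length, sets)
    if (length(sets) < 2) next
    merges <- merges + separate_skeleton_sets(g, sets)
  }
  total <- splits + merges
  structure(list(splits = splits, merges = merges, total = total,
                 per_object = if (n_objects > 0) total / n_objects else 0,
                 per_length = if (total_len_nm > 0)
                   total / (total_len_nm / 1000) else 0),
            class = "edit_counts")
}

# Number of cut operations (one edit each, unit edge capacities) needed to
# separate all skeleton fragment sets.  For small restricted graphs the
# minimum over all pair orders and all minimum cuts is computed exactly
# (branch-and-memoize); larger graphs use the sequential greedy procedure
# (process pairs in skeleton-id order, remove one minimum cut per step).
# A pair whose fragment sets overlap cannot be separated by edge cuts and
# counts as one edit (logged).
separate_skeleton_sets <- function(g, sets) {
  sets_chr <- lapply(sets, as.character)
  shared <- 0
  npairs <- length(sets_chr)
  for (i in seq_len(npairs - 1)) for (j in (i + 1):npairs) {
    if (length(intersect(sets_chr[[i]], sets_chr[[j]]))) {
      bs_log("skeleton pair shares a fragment; one edit counted, not separable by cuts")
      shared <- shared + 1
    }
  }
  if (igraph::ecount(g) <= 12)
    return(shared + min_cut_ops_exact(g, sets_chr))
  shared + min_cut_ops_greedy(g, sets_chr)
}

# exact minimum number of cut operations over all sequences
min_cut_ops_exact <- function(g, sets) {
  el <- igraph::as_edgelist(g)
  nodes <- igraph::V(g)$name
  npairs <- length(sets)
  pair_list <- list()
  for (i in seq_len(npairs - 1)) for (j in (i + 1):npairs)
    if (!length(intersect(sets[[i]], sets[[j]])))
      pair_list[[length(pair_list) + 1]] <- c(i, j)
  connected <- function(edge_idx, a, b) {
    gs <- igraph::graph_from_data_frame(
      data.frame(from = el[edge_idx, 1], to = el[edge_idx, 2]),
      directed = FALSE, vertices = data.frame(name = nodes))
    comp <- igraph::components(gs)$membership
    any(comp[a] %in% comp[b])
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(edge_idx) {
    unsep <- Filter(function(p)
      connected(edge_idx, sets[[p[1]]], sets[[p[2]]]), pair_list)
    if (!length(unsep)) return(0)
    key <- paste(edge_idx, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- Inf
    for (p in unsep) {
      # smallest cut size for this pair among the remaining edges
      found_k <- FALSE
      for (k in seq_along(edge_idx)) {
        for (rm in utils::combn(seq_along(edge_idx), k, simplify = FALSE)) {
          rest <- edge_idx[-rm]
          if (!connected(rest, sets[[p[1]]], sets[[p[2]]])) {
            found_k <- TRUE
            best <- min(best, 1 + rec(rest))
          }
        }
        if (found_k) break
      }
    }
    memo[[key]] <- best
    best
  }
  rec(seq_len(nrow(el)))
}

min_cut_ops_greedy <- function(g, sets) {
  edits <- 0
  npairs <- length(sets)
  repeat {
    comp <- igraph::components(g)$membership
    pair <- NULL
    for (i in seq_len(npairs - 1)) {
      for (j in (i + 1):npairs) {
        a <- intersect(sets[[i]], names(comp))
        b <- intersect(sets[[j]], names(comp))
        if (!length(a) || !length(b) || length(intersect(a, b))) next
        if (any(comp[a] %in% comp[b])) { pair <- list(i = i, j = j, a = a, b = b); break }
      }
      if (!is.null(pair)) break
    }
    if (is.null(pair)) break
    gx <- igraph::add_vertices(g, 2, name = c(".s", ".t"))
    gx <- igraph::add_edges(gx, as.vector(rbind(".s", pair$a)))
    gx <- igraph::add_edges(gx, as.vector(rbind(".t", pair$b)))
    cap <- rep(1, igraph::ecount(gx))
    big <- igraph::ecount(g) + length(pair$a) + length(pair$b) + 1
    cap[as.integer(igraph::incident(gx, ".s"))] <- big
    cap[as.integer(igraph::incident(gx, ".t"))] <- big
    mc <- igraph::min_cut(gx, source = ".s", target = ".t", capacity = cap,
                          value.only = FALSE)
    g <- igraph::delete_edges(g, igraph::as_ids(mc$cut))
    edits <- edits + 1
  }
  edits
}

#' @export
print.edit_counts <- function(x, ...) {
  cat(sprintf("<edit_counts> splits %d, merges %d, total %d (%.3f per object, %.3f per um)\n",
              x$splits, x$merges, x$total, x$per_object, x$per_length))
  invisible(x)
}

#' Variation of information between two labelings
#'
#' Computed in bits over the voxels where `gt > 0`:
#' `voi_split = H(seg | gt)`, `voi_merge = H(gt | seg)` from the joint
#' label-pair histogram. Zero iff the labelings agree up to relabeling on
#' the foreground.
#'
#' @param seg,gt [label_volume()]s of identical shape.
#' @return list of class `voi_result`: `voi_split`, `voi_merge`, `sum`.
#' @export
variation_of_information <- function(seg, gt) {
  stopifnot(identical(dim(seg$data), dim(gt$data)))
  fg <- gt$data > 0
  if (!any(fg)) stop("ground truth has no foreground voxels")
  s <- seg$data[fg]
  g <- gt$data[fg]
  n <- length(s)
  joint <- table(s, g) / n
  ps <- rowSums(joint)
  pg <- colSums(joint)
  hj <- -sum(joint[joint > 0] * log2(joint[joint > 0]))
  hs <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  hg <- -sum(pg[pg > 0] * log2(pg[pg > 0]))
  voi_split <- hj - hg # H(seg | gt)
  voi_merge <- hj - hs # H(gt | seg)
  structure(list(voi_split = max(voi_split, 0), voi_merge = max(voi_merge, 0),
                 sum = max(voi_split, 0) + max(voi_merge, 0)),
            class = "voi_result")
}

#' @export
print.voi_result <- function(x, ...) {
  cat(sprintf("<voi_result> split %.4f + merge %.4f = %.4f bits\n",
              x$voi_split, x$voi_merge, x$sum))
  invisible(x)
}

#' Descriptor error map between model predictions and a segmentation
#'
#' Recomputes descriptors from the evaluated segmentation and takes the
#' per-voxel Euclidean norm of the channel-wise difference with the model's
#' predicted descriptors. The error mask thresholds the map and applies
#' binary opening with a world-unit-aware ball structuring element, which
#' removes pointlike boundary discrepancies while keeping extended error
#' blobs (typical of merged or missing objects).
#'
#' @param model_lsds predicted [descriptor_grid()] (10 channels).
#' @param segmentation the segmentation [label_volume()] to compare against.
#' @param sigma descriptor scale in nm (should match the model's).
#' @param error_threshold threshold on the error norm for the mask.
#' @param opening_radius ball radius in voxels (of the finest axis) for
#'   binary opening.
#' @return list with `error_map` (array), `error_mask` (logical array).
#' @export
lsd_error_map <- function(model_lsds, segmentation, sigma = NULL,
                          error_threshold = 0.25, opening_radius = 1) {
  stopifnot(inherits(model_lsds, "descriptor_grid"),
            inherits(segmentation, "label_volume"))
  if (is.null(sigma)) sigma <- model_lsds$sigma
  seg_lsds <- compute_lsd(segmentation, sigma, dimensionality = 3)
  if (!identical(dim(model_lsds$data), dim(seg_lsds$data)))
    stop("descriptor shapes do not match")
  diff2 <- (model_lsds$data - seg_lsds$data)^2
  err <- sqrt(apply(diff2, c(2, 3, 4), sum))
  mask <- err > error_threshold
  if (opening_radius > 0 && any(mask)) {
    se <- ball_offsets(opening_radius, segmentation$voxel_size)
    mask <- cpp_morph_binary(mask, se, 0L)     # erode
    mask <- cpp_morph_binary(mask, se, 1L)     # dilate
  }
  list(error_map = err, error_mask = array(mask, dim(err)))
}
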