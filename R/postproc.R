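#' Watershed supervoxels from predicted affinities
#'
#' The per-voxel boundary indicator is the mean of the valid affinity
#' entries touching the voxel (its own channels and the mirrored entries of
#' its successors); voxels with indicator above `boundary_threshold` form
#' the foreground mask. An anisotropy-aware Euclidean distance transform
#' (world units) is computed inside the mask, its local maxima (within a
#' configurable box footprint, plateaus merged into a single seed) seed a
#' watershed on the negative distance. Flooding and plateau connectivity
#' use only faces whose affinity exceeds the threshold, which guarantees
#' that fragments never span a 0-affinity face. Voxels outside the mask
#' (or unreachable through allowed faces) stay 0.
#'
#' @param affs an [affinity_grid()] over the direct 3D neighborhood.
#' @param boundary_threshold boundary indicator threshold in `[0, 1]`.
#' @param seed_footprint box half-widths `(z, y, x)` in voxels for maxima
#'   detection (default footprint 3x9x9).
#' @return a [label_volume()] of fragments with attribute
#'   `boundary_threshold`.
#' @export
watershed_fragments <- function(affs, boundary_threshold = 0.5,
                                seed_footprint = c(1L, 4L, 4L)) {
  stopifnot(inherits(affs, "affinity_grid"),
            boundary_threshold >= 0, boundary_threshold <= 1)
  d <- dim(affs$data)[-1]
  ind <- boundary_indicator(affs)
  mask <- ind > boundary_threshold
  frag <- label_volume(array(0, d), affs$voxel_size, affs$offset)
  attr(frag, "boundary_threshold") <- boundary_threshold
  if (!any(mask)) {
    bs_log("no foreground above boundary threshold; empty fragment volume")
    return(frag)
  }
  faces <- array(FALSE, dim(affs$data))
  faces[affs$data > boundary_threshold] <- TRUE
  dist <- cpp_edt(mask, affs$voxel_size)
  finite_cap <- max(dist[is.finite(dist)], 0) + 1
  dist[!is.finite(dist)] <- finite_cap
  maxima <- cpp_local_maxima(dist, mask, as.integer(seed_footprint))
  seeds <- cpp_seed_labels(maxima, dist, faces)
  lab <- cpp_watershed(-dist, mask, seeds, faces)
  frag$data <- array(as.numeric(lab), d)
  frag
}

# mean over the valid affinity entries touching each voxel: channel d at p
# (bond to p + offset_d) and channel d at p - offset_d (bond of the successor)
boundary_indicator <- function(affs) {
  d <- dim(affs$data)[-1]
  ssum <- array(0, d); cnt <- array(0, d)
  D <- dim(affs$data)[1]
  for (k in seq_len(D)) {
    a <- array(affs$data[k, , , ], d)
    m <- array(affs$mask[k, , , ], d)
    ssum <- ssum + a * m
    cnt <- cnt + m
    off <- affs$neighborhood[k, ]
    src <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax]); i[(i + off[ax]) >= 1 & (i + off[ax]) <= d[ax]]
    })
    if (any(lengths(src) == 0)) next
    dst <- lapply(1:3, function(ax) src[[ax]] + off[ax])
    ssum[dst[[1]], dst[[2]], dst[[3]]] <-
      ssum[dst[[1]], dst[[2]], dst[[3]]] +
      a[src[[1]], src[[2]], src[[3]]] * m[src[[1]], src[[2]], src[[3]]]
    cnt[dst[[1]], dst[[2]], dst[[3]]] <-
      cnt[dst[[1]], dst[[2]], dst[[3]]] + m[src[[1]], src[[2]], src[[3]]]
  }
  out <- array(0, d)
  out[cnt > 0] <- ssum[cnt > 0] / cnt[cnt > 0]
  out
}

# label plateau components of maxima (connected via allowed faces among
# equal-distance maxima) as individual seeds
cpp_seed_labels <- function(maxima, dist, faces) {
  plateau <- array(0, dim(maxima))
  plateau[maxima] <- dist[maxima]
  # components of equal nonzero value connected through allowed faces
  comp <- cpp_label_components(plateau, 6L, as.logical(faces))
  array(as.integer(comp), dim(maxima))
}

#' Region adjacency graph of a fragment volume
#'
#' Nodes are fragments with world-coordinate centroids; an edge joins every
#' pair of fragments sharing at least one face-adjacent voxel pair, scored
#' by the mean predicted affinity over all face pairs joining them (using
#' the channel matching each face orientation).
#'
#' @param fragments a fragment [label_volume()].
#' @param affs the [affinity_grid()] the fragments were derived from.
#' @return an object of class `bootseg_rag`: `nodes` (data.frame id, z, y,
#'   x) and `edges` (data.frame a, b, score, sum, count with a < b).
#' @export
build_rag <- function(fragments, affs) {
  stopifnot(inherits(fragments, "label_volume"),
            identical(dim(fragments$data), dim(affs$data)[-1]))
  lab <- fragments$data
  d <- dim(lab)
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  idx <- which(lab > 0, arr.ind = TRUE)
  cz <- tapply((idx[, 1] - 1) * fragments$voxel_size[1] + fragments$offset[1],
               lab[lab > 0], mean)
  cy <- tapply((idx[, 2] - 1) * fragments$voxel_size[2] + fragments$offset[2],
               lab[lab > 0], mean)
  cx <- tapply((idx[, 3] - 1) * fragments$voxel_size[3] + fragments$offset[3],
               lab[lab > 0], mean)
  nodes <- data.frame(id = as.numeric(names(cz)), z = as.numeric(cz),
                      y = as.numeric(cy), x = as.numeric(cx))
  ea <- numeric(); eb <- numeric(); ev <- numeric()
  for (k in seq_len(nrow(affs$neighborhood))) {
    off <- affs$neighborhood[k, ]
    src <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax]); i[(i + off[ax]) >= 1 & (i + off[ax]) <= d[ax]]
    })
    if (any(lengths(src) == 0)) next
    dst <- lapply(1:3, function(ax) src[[ax]] + off[ax])
    lp <- lab[src[[1]], src[[2]], src[[3]], drop = FALSE]
    lq <- lab[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    av <- array(affs$data[k, , , ], d)[src[[1]], src[[2]], src[[3]],
                                       drop = FALSE]
    sel <- lp > 0 & lq > 0 & lp != lq
    if (!any(sel)) next
    ea <- c(ea, pmin(lp[sel], lq[sel]))
    eb <- c(eb, pmax(lp[sel], lq[sel]))
    ev <- c(ev, av[sel])
  }
  if (length(ea)) {
    key <- paste(ea, eb)
    s <- rowsum(ev, key)
    n <- rowsum(rep(1, length(ev)), key)
    parts <- do.call(rbind, strsplit(rownames(s), " "))
    edges <- data.frame(a = as.numeric(parts[, 1]),
                        b = as.numeric(parts[, 2]),
                        sum = as.numeric(s), count = as.numeric(n))
    edges$score <- edges$sum / edges$count
    edges <- edges[order(edges$a, edges$b), c("a", "b", "score", "sum", "count")]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = numeric(), b = numeric(), score = numeric(),
                        sum = numeric(), count = numeric())
  }
  structure(list(nodes = nodes, edges = edges), class = "bootseg_rag")
}

#' @export
print.bootseg_rag <- function(x, ...) {
  cat(sprintf("<bootseg_rag> %d fragments, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Hierarchical agglomeration of a region adjacency graph
#'
#' Edges are processed in decreasing score order; the two clusters joined by
#' the current best edge merge iff its score is at least `merge_threshold`.
#' After a merge, the score between two clusters is the mean of the original
#' face-pair affinities between them (the face-count-weighted mean of the
#' constituent edge scores). Ties are broken deterministically by the
#' (smaller, then larger) representative fragment id of the pair.
#'
#' @param rag a `bootseg_rag` from [build_rag()].
#' @param merge_threshold minimum score for a merge in `[0, 1]`.
#' @return named numeric vector mapping fragment id to segment id (the
#'   smallest fragment id of its cluster).
#' @export
agglomerate <- function(rag, merge_threshold = 0.5) {
  ids <- rag$nodes$id
  parent <- setNames(ids, as.character(ids))
  find <- function(i) {
    k <- as.character(i)
    while (parent[[k]] != i) {
      i <- parent[[k]]
      k <- as.character(i)
    }
    i
  }
  ea <- rag$edges$a; eb <- rag$edges$b
  es <- rag$edges$sum; en <- rag$edges$count
  while (length(ea)) {
    sc <- es / en
    best <- which(sc == max(sc))
    if (length(best) > 1)
      best <- best[order(ea[best], eb[best])][1]
    if (sc[best] < merge_threshold) break
    ra <- ea[best]; rb <- eb[best]
    keep <- min(ra, rb); drop <- max(ra, rb)
    parent[[as.character(drop)]] <- keep
    # re-key edges touching the dropped cluster, then aggregate duplicates
    sel <- -best
    ea <- ea[sel]; eb <- eb[sel]; es <- es[sel]; en <- en[sel]
    touch <- ea == drop | eb == drop
    if (any(touch)) {
      na <- ifelse(ea[touch] == drop, keep, ea[touch])
      nb <- ifelse(eb[touch] == drop, keep, eb[touch])
      ea[touch] <- pmin(na, nb); eb[touch] <- pmax(na, nb)
      key <- paste(ea, eb)
      dup <- duplicated(key)
      if (any(dup)) {
        s <- rowsum(es, key); n <- rowsum(en, key)
        parts <- do.call(rbind, strsplit(rownames(s), " "))
        ea <- as.numeric(parts[, 1]); eb <- as.numeric(parts[, 2])
        es <- as.numeric(s); en <- as.numeric(n)
      }
    }
  }
  setNames(vapply(ids, find, numeric(1)), as.character(ids))
}

#' Segment a volume from predicted affinities
#'
#' Composition of [watershed_fragments()], [build_rag()] and
#' [agglomerate()]; segments are relabeled to consecutive positive integers
#' (ascending representative order). Voxels left unsegmented by the
#' watershed (the thin boundary band below the foreground threshold) are
#' then absorbed, layer by layer, into the adjacent segment behind their
#' strongest above-threshold bond (`fill_background`); voxels with no such
#' bond stay 0.
#'
#' @inheritParams watershed_fragments
#' @param merge_threshold agglomeration threshold.
#' @param fill_background absorb unsegmented voxels across above-threshold
#'   bonds?
#' @param return_parts also return fragments and RAG (for evaluation)?
#' @return a segmentation [label_volume()]; with `return_parts = TRUE`, a
#'   list `(segmentation, fragments, rag, assignment)`.
#' @export
segment <- function(affs, boundary_threshold = 0.5, merge_threshold = 0.5,
                    seed_footprint = c(1L, 4L, 4L), fill_background = TRUE,
                    return_parts = FALSE) {
  frag <- watershed_fragments(affs, boundary_threshold, seed_footprint)
  if (!any(frag$data > 0)) {
    out <- frag
    if (return_parts)
      return(list(segmentation = out, fragments = frag,
                  rag = structure(list(nodes = data.frame(id = numeric(),
                                                          z = numeric(),
                                                          y = numeric(),
                                                          x = numeric()),
                                       edges = data.frame()),
                                  class = "bootseg_rag"),
                  assignment = numeric()))
    return(out)
  }
  rag <- build_rag(frag, affs)
  assign <- agglomerate(rag, merge_threshold)
  segs <- sort(unique(assign))
  remap <- setNames(seq_along(segs), as.character(segs))
  seg <- frag
  pos <- frag$data > 0
  seg$data[pos] <- remap[as.character(assign[as.character(frag$data[pos])])]
  seg$data <- array(as.numeric(seg$data), dim(frag$data))
  if (fill_background)
    seg$data <- absorb_unsegmented(seg$data, affs, boundary_threshold)
  if (return_parts)
    list(segmentation = seg, fragments = frag, rag = rag,
         assignment = assign)
  else seg
}

# iteratively assign unsegmented voxels to the neighboring segment behind
# their strongest above-threshold bond (deterministic: max affinity, ties by
# fixed direction order)
absorb_unsegmented <- function(seg, affs, threshold) {
  d <- dim(seg)
  D <- nrow(affs$neighborhood)
  repeat {
    un <- seg == 0
    if (!any(un)) break
    best_aff <- array(-1, d)
    best_lab <- array(0, d)
    consider <- function(aval, nseg, sel) {
      upd <- sel & un & nseg > 0 & aval > threshold & aval > best_aff
      best_aff[upd] <<- aval[upd]
      best_lab[upd] <<- nseg[upd]
    }
    for (k in seq_len(D)) {
      off <- affs$neighborhood[k, ]
      a <- array(affs$data[k, , , ], d)
      # bond at p toward p + off (channel k at p)
      src <- lapply(1:3, function(ax) {
        i <- seq_len(d[ax]); i[(i + off[ax]) >= 1 & (i + off[ax]) <= d[ax]]
      })
      if (all(lengths(src) > 0)) {
        dst <- lapply(1:3, function(ax) src[[ax]] + off[ax])
        aval <- array(-1, d); nseg <- array(0, d); sel <- array(FALSE, d)
        aval[src[[1]], src[[2]], src[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
        nseg[src[[1]], src[[2]], src[[3]]] <- seg[dst[[1]], dst[[2]], dst[[3]]]
        sel[src[[1]], src[[2]], src[[3]]] <- TRUE
        consider(aval, nseg, sel)
        # mirrored bond: channel k at p - off links p with p - off
        aval <- array(-1, d); nseg <- array(0, d); sel <- array(FALSE, d)
        aval[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
        nseg[dst[[1]], dst[[2]], dst[[3]]] <- seg[src[[1]], src[[2]], src[[3]]]
        sel[dst[[1]], dst[[2]], dst[[3]]] <- TRUE
        consider(aval, nseg, sel)
      }
    }
    grow <- un & best_lab > 0
    if (!any(grow)) break
    seg[grow] <- best_lab[grow]
  }
  seg
}

#' Post-processing parameter grid search
#'
#' Evaluates [segment()] at every combination of boundary and merge
#' thresholds against a reference labeling and returns all scores sorted
#' ascending (lower is better), plus the argmin row. Deterministic:
#' re-running yields an identical table.
#'
#' @inheritParams segment
#' @param reference reference [label_volume()].
#' @param boundary_thresholds,merge_thresholds numeric grids.
#' @param metric `"voi_sum"` (variation of information, bits) or
#'   `"mcm_per_object"` (skeleton edits per object; reference skeletons are
#'   computed once via [filter_ground_truth()] + [skeletonize()]).
#' @return list with `table` (data.frame boundary_threshold,
#'   merge_threshold, score, sorted ascending) and `best` (its first row).
#' @export
grid_search <- function(affs, reference, boundary_thresholds,
                        merge_thresholds, metric = c("voi_sum",
                                                     "mcm_per_object")) {
  metric <- match.arg(metric)
  stopifnot(length(boundary_thresholds) >= 1, length(merge_thresholds) >= 1)
  skels <- NULL
  if (metric == "mcm_per_object") {
    gt <- filter_ground_truth(reference)
    skels <- skeletonize(gt)
  }
  rows <- list()
  for (bt in boundary_thresholds) {
    parts <- NULL
    for (mt in merge_thresholds) {
      if (is.null(parts))
        parts <- segment(affs, bt, merge_thresholds[1], return_parts = TRUE)
      res <- segment_from_parts(parts, affs, mt)
      score <- if (metric == "voi_sum") {
        v <- variation_of_information(res$segmentation, reference)
        v$sum
      } else {
        mc <- min_cut_metric(skels, res$segmentation, parts$rag,
                             parts$fragments)
        mc$per_object
      }
      rows[[length(rows) + 1]] <-
        data.frame(boundary_threshold = bt, merge_threshold = mt,
                   score = score)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$score, tab$boundary_threshold, tab$merge_threshold), ]
  rownames(tab) <- NULL
  list(table = tab, best = tab[1, ])
}

# re-agglomerate cached fragments/RAG at a new merge threshold
segment_from_parts <- function(parts, affs, merge_threshold) {
  frag <- parts$fragments
  if (!any(frag$data > 0)) return(list(segmentation = frag))
  assign <- agglomerate(parts$rag, merge_threshold)
  segs <- sort(unique(assign))
  remap <- setNames(seq_along(segs), as.character(segs))
  seg <- frag
  pos <- frag$data > 0
  seg$data[pos] <- remap[as.character(assign[as.character(frag$data[pos])])]
  seg$data <- array(as.numeric(seg$data), dim(frag$data))
  seg$data <- absorb_unsegmented(seg$data, affs,
                                 attr(frag, "boundary_threshold") %||% 0.5)
  list(segmentation = seg)
}
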