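# Independent oracles: direct per-voxel / brute-force implementations used to
# validate the package's vectorized or incremental algorithms.  These are
# deliberately naive and share no code with the implementations they check.

options(bootseg.quiet = TRUE)

# per-voxel summation over the 3-sigma box
brute_lsd <- function(labels, sigma, dimensionality = 3) {
  lab <- labels$data
  vs <- labels$voxel_size
  sigma <- rep(sigma, length.out = 3)
  d <- dim(lab)
  K <- floor(3 * sigma / vs + 1e-9)
  if (dimensionality == 2) K[1] <- 0
  C <- if (dimensionality == 2) 6 else 10
  out <- array(0, c(C, d))
  Ssum <- sapply(1:3, function(a)
    sum(exp(-((-K[a]:K[a]) * vs[a])^2 / (2 * sigma[a]^2))))
  m_iso <- if (dimensionality == 2) Ssum[2] * Ssum[3] else prod(Ssum)
  cl <- function(v) pmin(pmax(v, 0), 1)
  rho <- function(cv, va, vb) if (va * vb > 1e-24) cv / sqrt(va * vb) else 0
  for (x in 1:d[3]) for (y in 1:d[2]) for (z in 1:d[1]) {
    L <- lab[z, y, x]
    if (L == 0) next
    zs <- max(1, z - K[1]):min(d[1], z + K[1])
    ys <- max(1, y - K[2]):min(d[2], y + K[2])
    xs <- max(1, x - K[3]):min(d[3], x + K[3])
    g <- expand.grid(z = zs, y = ys, x = xs)
    g <- g[lab[cbind(g$z, g$y, g$x)] == L, ]
    w <- exp(-(((g$z - z) * vs[1])^2 / (2 * sigma[1]^2) +
                 ((g$y - y) * vs[2])^2 / (2 * sigma[2]^2) +
                 ((g$x - x) * vs[3])^2 / (2 * sigma[3]^2)))
    m <- sum(w)
    wz <- g$z * vs[1]; wy <- g$y * vs[2]; wx <- g$x * vs[3]
    mz <- sum(w * wz) / m; my <- sum(w * wy) / m; mx <- sum(w * wx) / m
    vz <- sum(w * (wz - mz)^2) / m
    vy <- sum(w * (wy - my)^2) / m
    vx <- sum(w * (wx - mx)^2) / m
    czy <- sum(w * (wz - mz) * (wy - my)) / m
    czx <- sum(w * (wz - mz) * (wx - mx)) / m
    cyx <- sum(w * (wy - my) * (wx - mx)) / m
    if (dimensionality == 3) {
      out[, z, y, x] <- c(
        cl((mz - z * vs[1]) / (2 * sigma[1]) + 0.5),
        cl((my - y * vs[2]) / (2 * sigma[2]) + 0.5),
        cl((mx - x * vs[3]) / (2 * sigma[3]) + 0.5),
        cl(vz / sigma[1]^2), cl(vy / sigma[2]^2), cl(vx / sigma[3]^2),
        cl((rho(czy, vz, vy) + 1) / 2), cl((rho(czx, vz, vx) + 1) / 2),
        cl((rho(cyx, vy, vx) + 1) / 2), cl(m / m_iso))
    } else {
      out[, z, y, x] <- c(
        cl((my - y * vs[2]) / (2 * sigma[2]) + 0.5),
        cl((mx - x * vs[3]) / (2 * sigma[3]) + 0.5),
        cl(vy / sigma[2]^2), cl(vx / sigma[3]^2),
        cl((rho(cyx, vy, vx) + 1) / 2), cl(m / m_iso))
    }
  }
  out
}

# exhaustive same-nonzero-label predicate over all voxel/offset combinations
brute_affinities <- function(labels, neighborhood) {
  lab <- labels$data
  d <- dim(lab)
  D <- nrow(neighborhood)
  affs <- array(0, c(D, d))
  mask <- array(FALSE, c(D, d))
  for (k in 1:D) for (x in 1:d[3]) for (y in 1:d[2]) for (z in 1:d[1]) {
    q <- c(z, y, x) + neighborhood[k, ]
    if (any(q < 1) || any(q > d)) next
    mask[k, z, y, x] <- TRUE
    if (lab[z, y, x] > 0 && lab[z, y, x] == lab[q[1], q[2], q[3]])
      affs[k, z, y, x] <- 1
  }
  list(affs = affs, mask = mask)
}

# random RAG generator: n nodes, random subset of edges with random scores
# and face counts
random_rag <- function(n_nodes, max_edges, seed) {
  set.seed(seed)
  ids <- sort(sample(1:20, n_nodes))
  all_pairs <- t(combn(ids, 2))
  ne <- sample.int(min(max_edges, nrow(all_pairs)), 1)
  sel <- sample(nrow(all_pairs), ne)
  cnt <- sample(1:5, ne, replace = TRUE)
  sc <- round(runif(ne), 2)
  edges <- data.frame(a = all_pairs[sel, 1], b = all_pairs[sel, 2],
                      score = sc, sum = sc * cnt, count = cnt)
  structure(list(nodes = data.frame(id = ids, z = 0, y = 0, x = ids),
                 edges = edges),
            class = "bootseg_rag")
}

# agglomeration oracle: recompute every cluster-pair score from the original
# face-pair sums at every step
brute_agglomerate <- function(rag, merge_threshold) {
  clusters <- lapply(rag$nodes$id, function(i) i)
  e0 <- rag$edges
  repeat {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        sel <- (e0$a %in% clusters[[i]] & e0$b %in% clusters[[j]]) |
          (e0$a %in% clusters[[j]] & e0$b %in% clusters[[i]])
        if (!any(sel)) next
        sc <- sum(e0$sum[sel]) / sum(e0$count[sel])
        ra <- min(min(clusters[[i]]), min(clusters[[j]]))
        rb <- max(min(clusters[[i]]), min(clusters[[j]]))
        if (is.null(best) || sc > best$sc ||
            (sc == best$sc && (ra < best$ra ||
                               (ra == best$ra && rb < best$rb))))
          best <- list(i = i, j = j, sc = sc, ra = ra, rb = rb)
      }
    }
    if (is.null(best) || best$sc < merge_threshold) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  out <- numeric()
  for (cl in clusters) for (i in cl) out[as.character(i)] <- min(cl)
  out[as.character(sort(rag$nodes$id))]
}

# ---- exhaustive merge-edit oracle ------------------------------------------

# minimum edge-cut size between two disjoint vertex sets (exhaustive over
# edge subsets; graphs have <= 8 edges)
sets_connected <- function(edges, a, b, nodes) {
  # connectivity via union-find over the given edges
  parent <- setNames(nodes, nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    ra <- find(as.character(edges$a[r])); rb <- find(as.character(edges$b[r]))
    if (ra != rb) parent[[rb]] <- ra
  }
  any(vapply(a, function(x) find(x), character(1)) %in%
        vapply(b, function(x) find(x), character(1)))
}

# exhaustive minimum number of cut operations separating all skeleton pairs;
# each operation removes a minimum-cardinality edge cut between some
# still-connected pair (all minimum cuts explored)
brute_merge_edits <- function(edges, sets, nodes) {
  sets <- lapply(sets, as.character)
  nodes <- as.character(nodes)
  npairs <- length(sets)
  pair_list <- list()
  shared <- 0
  for (i in seq_len(npairs - 1)) for (j in (i + 1):npairs) {
    if (length(intersect(sets[[i]], sets[[j]]))) shared <- shared + 1
    else pair_list[[length(pair_list) + 1]] <- c(i, j)
  }
  memo <- new.env()
  rec <- function(edge_idx) {
    unsep <- Filter(function(p) {
      sets_connected(edges[edge_idx, , drop = FALSE],
                     sets[[p[1]]], sets[[p[2]]], nodes)
    }, pair_list)
    if (!length(unsep)) return(0)
    key <- paste(edge_idx, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- Inf
    for (p in unsep) {
      # minimum cut size for this pair among remaining edges
      kmin <- NULL
      for (k in 0:length(edge_idx)) {
        subs <- if (k == 0) list(integer()) else
          utils::combn(seq_along(edge_idx), k, simplify = FALSE)
        any_cut <- FALSE
        for (rm in subs) {
          rest <- edge_idx[setdiff(seq_along(edge_idx), rm)]
          if (!sets_connected(edges[rest, , drop = FALSE],
                              sets[[p[1]]], sets[[p[2]]], nodes)) {
            any_cut <- TRUE
            cand <- 1 + rec(rest)
            if (cand < best) best <- cand
          }
        }
        if (any_cut) { kmin <- k; break }
      }
    }
    memo[[key]] <- best
    best
  }
  rec(seq_len(nrow(edges))) + shared
}

# split-edit oracle: direct component count over same-segment skeleton edges
brute_split_edits <- function(node_seg, edges) {
  keep <- names(node_seg)[node_seg > 0]
  if (!length(keep)) return(NA_integer_)
  parent <- setNames(keep, keep)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- as.character(edges[r, 1]); b <- as.character(edges[r, 2])
    if (a %in% keep && b %in% keep && node_seg[[a]] == node_seg[[b]]) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[rb]] <- ra
    }
  }
  length(unique(vapply(keep, find, character(1)))) - 1
}

# joint-histogram VOI oracle
brute_voi <- function(seg, gt) {
  fg <- which(gt > 0)
  s <- seg[fg]; g <- gt[fg]
  n <- length(fg)
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  pj <- as.vector(table(paste(s, g))) / n
  ps <- as.vector(table(s)) / n
  pg <- as.vector(table(g)) / n
  list(voi_split = h(pj) - h(pg), voi_merge = h(pj) - h(ps))
}

# small deterministic label fixtures
two_block_labels <- function() {
  lab <- array(0, c(8, 16, 8))
  lab[, 1:8, ] <- 1
  lab[, 9:16, ] <- 2
  label_volume(lab, c(10, 10, 10))
}
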