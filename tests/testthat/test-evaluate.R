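test_that("ground-truth filtering removes small labels and relabels components", {
  lab <- array(0, c(10, 20, 10))
  lab[1:5, 1:10, 1:10] <- 1                 # 5000 voxels: kept
  lab[6:10, 1:10, 1:10] <- 2                # kept
  lab[1, 11:15, 1] <- 3                     # 5 voxels: removed
  lv <- label_volume(lab, c(10, 10, 10))
  f <- filter_ground_truth(lv, 500)
  expect_false(any(f$data[lab == 3] > 0))
  expect_equal(length(unique(f$data[f$data > 0])), 2)
  # strictly-below semantics at the threshold: 499 out, 500 in
  lab <- array(0, c(8, 100, 2))
  lab[1:4, 1:25, 1:2] <- 1                  # 200... make exact counts instead
  lab[] <- 0
  lab[seq_len(499) + 8 * 100 * 2 - 499] <- 0 # noop, keep shape
  lab <- array(0, c(4, 250, 2))
  lab[1, 1:250, 1] <- 1; lab[2, 1:249, 1] <- 1  # id 1: 499 voxels
  lab[3, 1:250, 1] <- 2; lab[4, 1:250, 1] <- 2  # id 2: 500 voxels
  lv <- label_volume(lab, c(10, 10, 10))
  f <- filter_ground_truth(lv, 500)
  expect_false(any(f$data[lab == 1] > 0))
  expect_true(all(f$data[lab == 2] > 0))
  # a label with two disconnected parts becomes two objects
  lab <- array(0, c(8, 20, 10))
  lab[1:8, 1:8, ] <- 7
  lab[1:8, 13:20, ] <- 7
  f <- filter_ground_truth(label_volume(lab, c(10, 10, 10)), 500)
  expect_equal(length(unique(f$data[f$data > 0])), 2)
  # idempotence
  f2 <- filter_ground_truth(f, 500)
  expect_identical(f$data, f2$data)
  # empty volume passes through
  e <- filter_ground_truth(label_volume(array(0, c(4, 4, 4)), c(1, 1, 1)))
  expect_true(all(e$data == 0))
})

test_that("skeletons are center lines contained in their objects", {
  # 1-voxel-wide straight tube of length 20
  lab <- array(0, c(3, 3, 24))
  lab[2, 2, 3:22] <- 1
  lv <- label_volume(lab, c(10, 10, 10))
  sk <- skeletonize(lv, prune_length = 0)
  expect_length(sk, 1)
  len_vox <- skeleton_length(sk[[1]]) / 10
  expect_gte(len_vox, 17); expect_lte(len_vox, 22)
  # path topology: all degrees <= 2, connected
  deg <- table(factor(c(sk[[1]]$edges), levels = sk[[1]]$nodes$node_id))
  expect_true(all(deg <= 2))
  # single-voxel object: one node, no edges, zero length
  lab1 <- array(0, c(5, 5, 5)); lab1[3, 3, 3] <- 4
  sk1 <- skeletonize(label_volume(lab1, c(10, 10, 10)), prune_length = 0)
  expect_equal(nrow(sk1[[1]]$nodes), 1)
  expect_equal(nrow(sk1[[1]]$edges), 0)
  expect_equal(skeleton_length(sk1[[1]]), 0)
  # containment: every node's voxel carries the object's label
  sp <- synth_params(c(24, 24, 24), num_objects = c(4, 7), seed = 6)
  lab <- generate_labels(sp)
  gt <- filter_ground_truth(lab, 100)
  sks <- skeletonize(gt)
  for (s in sks) {
    vox <- cbind(floor(s$nodes$z / 10), floor(s$nodes$y / 10),
                 floor(s$nodes$x / 10)) + 1
    expect_true(all(gt$data[vox] == s$object_id))
  }
})

# helper: tiny abstract instance (fragments along x as 2x2x2 blocks)
block_world <- function(frag_of_block, seg_of_frag) {
  nb <- length(frag_of_block)
  frag <- array(0, c(2, 2, 2 * nb))
  for (i in seq_len(nb)) frag[, , (2 * i - 1):(2 * i)] <- frag_of_block[i]
  frag <- label_volume(frag, c(10, 10, 10))
  seg <- frag
  seg$data <- array(seg_of_frag[as.character(frag$data)], dim(frag$data))
  list(frag = frag, seg = seg)
}

block_skeleton <- function(id, blocks, node_offset = 0) {
  nodes <- data.frame(node_id = node_offset + seq_along(blocks),
                      z = 10, y = 10, x = (2 * blocks - 1) * 10)
  edges <- if (length(blocks) > 1)
    cbind(nodes$node_id[-length(blocks)], nodes$node_id[-1])
  else matrix(integer(), ncol = 2)
  skeleton(id, nodes, edges)
}

test_that("a perfect segmentation needs zero edits", {
  sp <- synth_params(c(24, 24, 24), num_objects = c(4, 7), seed = 2)
  lab <- generate_labels(sp)
  affs <- compute_affinities(lab)
  parts <- segment(affs, 0.5, 0.5, return_parts = TRUE)
  gt <- filter_ground_truth(lab, 100)
  sk <- skeletonize(gt)
  mc <- min_cut_metric(sk, parts$segmentation, parts$rag, parts$fragments)
  expect_equal(mc$splits, 0)
  expect_equal(mc$merges, 0)
  expect_equal(mc$per_object, 0)
  expect_equal(mc$per_length, 0)
})

test_that("a skeleton crossing segments A-B-A needs two split edits", {
  w <- block_world(1:6, setNames(c(1, 1, 2, 2, 1, 1), 1:6))
  rag <- build_rag(w$frag, compute_affinities(w$frag))
  sk <- structure(list(block_skeleton(1, 1:6)), class = "skeleton_set")
  mc <- min_cut_metric(sk, w$seg, rag, w$frag)
  expect_equal(mc$splits, 2)
  expect_equal(mc$merges, 0)
})

test_that("two skeletons joined through one fragment need one merge edit", {
  # fragment path f1 - f2 - f3 in a single segment; skeletons at the ends
  w <- block_world(1:3, setNames(c(1, 1, 1), 1:3))
  rag <- structure(list(
    nodes = data.frame(id = 1:3, z = 10, y = 10, x = c(10, 30, 50)),
    edges = data.frame(a = c(1, 2), b = c(2, 3), score = 0.9, sum = 0.9,
                       count = 1)), class = "bootseg_rag")
  sk <- structure(list(block_skeleton(1, 1), block_skeleton(2, 3)),
                  class = "skeleton_set")
  mc <- min_cut_metric(sk, w$seg, rag, w$frag)
  expect_equal(mc$splits, 0)
  expect_equal(mc$merges, 1)
  expect_equal(mc$per_object, 0.5)
})

test_that("edit counts match exhaustive search on random tiny instances", {
  set.seed(77)
  for (trial in 1:30) {
    nfrag <- sample(3:6, 1)
    nskel <- sample(2:3, 1)
    seg_of_frag <- setNames(sample(1:2, nfrag, replace = TRUE), 1:nfrag)
    w <- block_world(1:nfrag, seg_of_frag)
    # random RAG edges among the fragments (unit world, <= 8 edges)
    pairs <- t(combn(nfrag, 2))
    ne <- sample.int(min(8, nrow(pairs)), 1)
    sel <- pairs[sample(nrow(pairs), ne), , drop = FALSE]
    rag <- structure(list(
      nodes = data.frame(id = 1:nfrag, z = 10, y = 10,
                         x = (2 * (1:nfrag) - 1) * 10),
      edges = data.frame(a = sel[, 1], b = sel[, 2], score = 0.9,
                         sum = 0.9, count = 1)), class = "bootseg_rag")
    # skeletons visit random disjoint-ish block subsets
    offs <- 0
    sks <- lapply(seq_len(nskel), function(i) {
      blocks <- sort(sample(nfrag, sample(1:3, 1)))
      s <- block_skeleton(i, blocks, node_offset = offs)
      offs <<- offs + length(blocks)
      s
    })
    sks <- structure(sks, class = "skeleton_set")
    mc <- min_cut_metric(sks, w$seg, rag, w$frag)
    # oracle: splits by direct component counting, merges by exhaustive DFS
    want_splits <- 0
    for (s in sks) {
      node_seg <- setNames(w$seg$data[cbind(2, 2, ceiling(s$nodes$x / 10))],
                           s$nodes$node_id)
      want_splits <- want_splits + brute_split_edits(node_seg, s$edges)
    }
    want_merges <- 0
    for (sid in unique(seg_of_frag)) {
      frags <- as.numeric(names(seg_of_frag)[seg_of_frag == sid])
      sets <- lapply(sks, function(s) {
        blocks <- ceiling(s$nodes$x / 20)
        intersect(blocks, frags)
      })
      sets <- Filter(length, sets)
      if (length(sets) < 2) next
      el <- rag$edges[rag$edges$a %in% frags & rag$edges$b %in% frags, ,
                      drop = FALSE]
      want_merges <- want_merges + brute_merge_edits(el, sets, frags)
    }
    expect_equal(mc$splits, want_splits, label = paste("splits trial", trial))
    expect_equal(mc$merges, want_merges, label = paste("merges trial", trial))
  }
})

test_that("split-only perturbations increase splits and never merges", {
  sp <- synth_params(c(20, 20, 20), num_objects = c(3, 5), seed = 9)
  lab <- generate_labels(sp)
  affs <- compute_affinities(lab)
  parts <- segment(affs, 0.5, 0.5, return_parts = TRUE)
  gt <- filter_ground_truth(lab, 100)
  sk <- skeletonize(gt)
  # split every segment at a z-plane: purely a split perturbation
  seg2 <- parts$segmentation
  top <- seg2$data[11:20, , ]
  top[top > 0] <- top[top > 0] + max(seg2$data)
  seg2$data[11:20, , ] <- top
  frag2 <- parts$fragments
  topf <- frag2$data[11:20, , ]
  topf[topf > 0] <- topf[topf > 0] + max(frag2$data)
  frag2$data[11:20, , ] <- topf
  mc0 <- min_cut_metric(sk, parts$segmentation, parts$rag, parts$fragments)
  mc <- min_cut_metric(sk, seg2, parts$rag, frag2)
  expect_gt(mc$splits, mc0$splits)
  expect_equal(mc$merges, 0)
})

test_that("variation of information matches entropy identities and an oracle", {
  # identical labelings: exactly zero
  lab <- array(sample(1:3, 4^3, replace = TRUE), c(4, 4, 4))
  a <- label_volume(lab, c(1, 1, 1))
  v <- variation_of_information(a, a)
  expect_equal(v$sum, 0)
  # one object split into two equal halves: voi_split = 1 bit exactly
  gt <- label_volume(array(1, c(4, 4, 4)), c(1, 1, 1))
  seg <- gt
  seg$data[1:2, , ] <- 2
  v <- variation_of_information(seg, gt)
  expect_identical(v$voi_split, 1)
  expect_identical(v$voi_merge, 0)
  # random labelings agree with the brute-force joint-histogram oracle
  set.seed(3)
  for (i in 1:5) {
    s <- label_volume(array(sample(0:3, 6^3, replace = TRUE), c(6, 6, 6)),
                      c(1, 1, 1))
    g <- label_volume(array(sample(1:3, 6^3, replace = TRUE), c(6, 6, 6)),
                      c(1, 1, 1))
    v <- variation_of_information(s, g)
    o <- brute_voi(s$data, g$data)
    expect_equal(v$voi_split, o$voi_split)
    expect_equal(v$voi_merge, o$voi_merge)
  }
  # symmetry on foreground-matched volumes
  s <- label_volume(array(sample(1:4, 6^3, replace = TRUE), c(6, 6, 6)),
                    c(1, 1, 1))
  g <- label_volume(array(sample(1:4, 6^3, replace = TRUE), c(6, 6, 6)),
                    c(1, 1, 1))
  expect_equal(variation_of_information(s, g)$voi_split,
               variation_of_information(g, s)$voi_merge)
  # no foreground is an error
  expect_error(variation_of_information(
    s, label_volume(array(0, c(6, 6, 6)), c(1, 1, 1))), "foreground")
})

test_that("descriptor error maps isolate real errors and drop speckle", {
  sp <- synth_params(c(16, 24, 24), num_objects = c(4, 7), seed = 13)
  lab <- generate_labels(sp)
  lsd <- compute_lsd(lab, 20)
  # model descriptors computed from the evaluated segmentation: zero map
  em <- lsd_error_map(lsd, lab, sigma = 20)
  expect_true(all(em$error_map == 0))
  expect_false(any(em$error_mask))
  # isolated single-voxel error is removed by opening with radius 1
  lsd2 <- lsd
  lsd2$data[, 8, 12, 12] <- clip01(lsd2$data[, 8, 12, 12] + 0.9)
  em2 <- lsd_error_map(lsd2, lab, sigma = 20, error_threshold = 0.25,
                       opening_radius = 1)
  expect_gt(em2$error_map[8, 12, 12], 0.25)
  expect_false(any(em2$error_mask))
  # merging two touching objects produces a blob that survives opening
  ids <- as.numeric(names(sort(table(lab$data), decreasing = TRUE)))
  merged <- lab
  merged$data[merged$data == ids[2]] <- ids[1]
  em3 <- lsd_error_map(lsd, merged, sigma = 20, error_threshold = 0.25,
                       opening_radius = 1)
  expect_true(any(em3$error_mask))
  expect_error(lsd_error_map(compute_lsd(lab, 20, dimensionality = 2), lab),
               "descriptor|shape|channel")
})
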