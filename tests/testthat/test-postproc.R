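uniform_affs <- function(value, d = c(8, 8, 8)) {
  lab <- label_volume(array(1, d), c(10, 10, 10))
  a <- compute_affinities(lab)
  a$data[a$mask] <- value
  a
}

test_that("degenerate affinity fields give the trivial fragmentations", {
  a1 <- uniform_affs(1)
  f1 <- watershed_fragments(a1, 0.5)
  expect_true(all(f1$data == 1)) # one fragment covering the volume
  a0 <- uniform_affs(0)
  withr::with_options(
    list(bootseg.quiet = FALSE),
    expect_message(f0 <- watershed_fragments(a0, 0.5), "no foreground"))
  expect_true(all(f0$data == 0))
})

test_that("two blocks joined by 0-affinity faces give exactly two fragments", {
  tb <- two_block_labels()
  affs <- compute_affinities(tb)
  f <- watershed_fragments(affs, 0.5)
  expect_equal(length(unique(f$data[f$data > 0])), 2)
  # fragments coincide with the blocks wherever labeled
  fg <- f$data > 0
  expect_equal(length(unique(paste(f$data[fg], tb$data[fg]))), 2)
})

test_that("fragments never span a 0-affinity face on ground-truth input", {
  sp <- synth_params(c(24, 24, 24), num_objects = c(6, 10), seed = 3)
  lab <- generate_labels(sp)
  affs <- compute_affinities(lab)
  f <- watershed_fragments(affs, 0.5)
  d <- dim(lab$data)
  for (k in 1:3) {
    off <- default_neighborhood()[k, ]
    src <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax]); i[(i + off[ax]) >= 1 & (i + off[ax]) <= d[ax]]
    })
    dst <- lapply(1:3, function(ax) src[[ax]] + off[ax])
    ap <- array(affs$data[k, , , ], d)[src[[1]], src[[2]], src[[3]]]
    fp <- f$data[src[[1]], src[[2]], src[[3]]]
    fq <- f$data[dst[[1]], dst[[2]], dst[[3]]]
    expect_false(any(ap == 0 & fp > 0 & fp == fq))
  }
})

test_that("RAG nodes, edges and scores follow the face-pair definition", {
  tb <- two_block_labels()
  affs <- compute_affinities(tb)
  f <- watershed_fragments(affs, 0.5)
  # single fragment: one node, no edges
  a1 <- uniform_affs(1)
  r1 <- build_rag(watershed_fragments(a1, 0.5), a1)
  expect_equal(nrow(r1$nodes), 1)
  expect_equal(nrow(r1$edges), 0)
  # two fragments sharing four face pairs with affinities .2 .4 .6 .8
  lab <- array(0, c(1, 2, 4))
  lab[1, 1, ] <- 1; lab[1, 2, ] <- 2
  lv <- label_volume(lab, c(10, 10, 10))
  affs <- compute_affinities(lv)
  affs$data[2, 1, 2, ] <- c(0.2, 0.4, 0.6, 0.8) # the y-crossing bonds
  frag <- lv # use the labels as the fragmentation
  rag <- build_rag(frag, affs)
  expect_equal(nrow(rag$edges), 1)
  expect_equal(rag$edges$score, 0.5)
  expect_equal(rag$edges$count, 4)
  # non-touching fragments get no edge
  lab2 <- array(0, c(1, 5, 4)); lab2[1, 1, ] <- 1; lab2[1, 5, ] <- 2
  lv2 <- label_volume(lab2, c(10, 10, 10))
  rag2 <- build_rag(lv2, compute_affinities(lv2))
  expect_equal(nrow(rag2$edges), 0)
  expect_equal(nrow(rag2$nodes), 2)
})

test_that("agglomeration respects thresholds and the merge order", {
  rag <- structure(list(
    nodes = data.frame(id = 1:3, z = 0, y = 0, x = 1:3),
    edges = data.frame(a = c(1, 2), b = c(2, 3), score = c(0.9, 0.3),
                       sum = c(0.9, 0.3), count = c(1, 1))),
    class = "bootseg_rag")
  m <- agglomerate(rag, 0.5)
  expect_equal(unname(m[c("1", "2")]), c(1, 1))
  expect_equal(unname(m["3"]), 3)
  # threshold 0: everything in a RAG component merges
  m0 <- agglomerate(rag, 0)
  expect_equal(length(unique(m0)), 1)
  # threshold above 1: identity
  mid <- agglomerate(rag, 1 + 1e-9)
  expect_equal(unname(mid), c(1, 2, 3))
})

test_that("incremental agglomeration equals recompute-all linkage", {
  for (s in 1:60) {
    rag <- random_rag(n_nodes = sample(3:8, 1), max_edges = 8, seed = 1000 + s)
    th <- sample(c(0, 0.25, 0.5, 0.75), 1)
    expect_identical(agglomerate(rag, th), brute_agglomerate(rag, th),
                     label = paste("rag seed", s))
  }
})

test_that("segment count is monotone in the merge threshold", {
  sp <- synth_params(c(16, 24, 24), num_objects = c(6, 10), seed = 8)
  lab <- generate_labels(sp)
  affs <- compute_affinities(lab)
  # soften the affinities so intermediate thresholds differ
  set.seed(1)
  affs$data[affs$mask] <- pmin(pmax(
    affs$data[affs$mask] * 0.8 + 0.1 +
      rnorm(sum(affs$mask), 0, 0.05), 0), 1)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(t) {
    s <- segment(affs, 0.3, t)
    length(unique(s$data[s$data > 0]))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("ground-truth affinities are recovered into the source labels", {
  sp <- synth_params(c(40, 40, 40), num_objects = c(10, 15), seed = 2)
  lab <- generate_labels(sp)
  seg <- segment(compute_affinities(lab), 0.5, 0.5)
  v <- variation_of_information(seg, lab)
  expect_lt(v$sum, 0.1)
  ids <- sort(unique(seg$data[seg$data > 0]))
  expect_identical(ids, as.numeric(seq_along(ids))) # consecutive from 1
})

test_that("empty affinities give an empty segmentation", {
  a0 <- uniform_affs(0)
  s <- segment(a0, 0.5, 0.5)
  expect_true(all(s$data == 0))
})

test_that("grid search returns a deterministic ranked table with an argmin", {
  sp <- synth_params(c(16, 24, 24), num_objects = c(5, 8), seed = 4)
  lab <- generate_labels(sp)
  affs <- compute_affinities(lab)
  g1 <- grid_search(affs, lab, 0.5, 0.5, metric = "voi_sum")
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$best$score, g1$table$score[1])
  g <- grid_search(affs, lab, c(0.3, 0.5), c(0.3, 0.5, 0.7),
                   metric = "voi_sum")
  expect_equal(nrow(g$table), 6)
  expect_true(all(g$best$score <= g$table$score))
  expect_true(!is.unsorted(g$table$score))
  g2 <- grid_search(affs, lab, c(0.3, 0.5), c(0.3, 0.5, 0.7),
                    metric = "voi_sum")
  expect_identical(g$table, g2$table)
  # the skeleton-edit metric is also available
  gm <- grid_search(affs, lab, 0.5, c(0.5, 0.9), metric = "mcm_per_object")
  expect_equal(nrow(gm$table), 2)
  expect_true(all(gm$table$score >= 0))
})
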