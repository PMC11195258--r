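test_that("descriptors match the per-voxel brute-force oracle", {
  set.seed(5)
  for (trial in 1:3) {
    lab <- label_volume(array(sample(0:3, 14^3, replace = TRUE),
                              c(14, 14, 14)), c(10, 10, 10))
    got <- compute_lsd(lab, 40, dimensionality = 3)
    expect_lt(max(abs(got$data - brute_lsd(lab, 40, 3))), 1e-5)
    got2 <- compute_lsd(lab, 40, dimensionality = 2)
    expect_lt(max(abs(got2$data - brute_lsd(lab, 40, 2))), 1e-5)
  }
  # anisotropic voxels and sigma, in world units
  lab <- label_volume(array(sample(0:2, 6 * 12 * 12, replace = TRUE),
                            c(6, 12, 12)), c(50, 10, 10))
  got <- compute_lsd(lab, c(100, 40, 40), dimensionality = 3)
  expect_lt(max(abs(got$data - brute_lsd(lab, c(100, 40, 40), 3))), 1e-5)
})

test_that("descriptor symmetry and background contracts hold", {
  # single isolated voxel: zero offset/variance, neutral correlation
  lab <- array(0, c(7, 7, 7)); lab[4, 4, 4] <- 1
  g <- compute_lsd(label_volume(lab, c(10, 10, 10)), 40)
  expect_equal(unname(g$data[, 4, 4, 4]),
               c(0.5, 0.5, 0.5, 0, 0, 0, 0.5, 0.5, 0.5,
                 g$data[10, 4, 4, 4]))
  expect_gt(g$data[10, 4, 4, 4], 0)
  # all-zero labels: all-zero grid
  g0 <- compute_lsd(label_volume(array(0, c(6, 6, 6)), c(10, 10, 10)), 40)
  expect_true(all(g0$data == 0))
  # background voxels carry the zero vector
  lab <- array(sample(0:2, 10^3, replace = TRUE), c(10, 10, 10))
  g <- compute_lsd(label_volume(lab, c(10, 10, 10)), 30)
  bg <- which(lab == 0)
  for (cc in 1:10) expect_true(all(array(g$data[cc, , , ], dim(lab))[bg] == 0))
  expect_true(all(g$data >= 0 & g$data <= 1))
})

test_that("flipping the volume flips the matching offset channel about 0.5", {
  set.seed(8)
  lab <- array(sample(0:2, 12^3, replace = TRUE), c(12, 12, 12))
  g <- compute_lsd(label_volume(lab, c(10, 10, 10)), 40)
  flipped <- lab[, 12:1, ]
  gf <- compute_lsd(label_volume(flipped, c(10, 10, 10)), 40)
  # offset-y channel (2) of the flipped volume mirrors about 0.5
  orig <- g$data[2, , , ]
  back <- gf$data[2, , 12:1, ]
  fg <- lab > 0
  expect_lt(max(abs((1 - back[fg]) - orig[fg])), 1e-5)
})

test_that("2D descriptors depend only on their own section", {
  set.seed(9)
  lab <- array(sample(0:2, 5 * 10 * 10, replace = TRUE), c(5, 10, 10))
  g1 <- compute_lsd(label_volume(lab, c(30, 10, 10)), 40, dimensionality = 2)
  lab2 <- lab
  lab2[3, , ] <- sample(0:2, 100, replace = TRUE) # perturb one section
  g2 <- compute_lsd(label_volume(lab2, c(30, 10, 10)), 40, dimensionality = 2)
  for (z in c(1, 2, 4, 5))
    expect_equal(g1$data[, z, , ], g2$data[, z, , ])
  expect_false(isTRUE(all.equal(g1$data[, 3, , ], g2$data[, 3, , ])))
})

test_that("affinities equal the same-nonzero-label predicate exactly", {
  set.seed(11)
  nb <- default_neighborhood()
  for (trial in 1:3) {
    lab <- label_volume(array(sample(0:3, 10^3, replace = TRUE),
                              c(10, 10, 10)), c(10, 10, 10))
    got <- compute_affinities(lab)
    want <- brute_affinities(lab, nb)
    expect_identical(got$data, want$affs)
    expect_identical(got$mask, want$mask)
  }
})

test_that("affinity boundary semantics follow the offset convention", {
  # uniform single label: every in-bounds affinity is 1
  lab <- label_volume(array(1, c(6, 6, 6)), c(10, 10, 10))
  a <- compute_affinities(lab)
  expect_true(all(a$data[a$mask] == 1))
  expect_true(all(a$data[!a$mask] == 0))
  # two labels split at y = 9: channel (0,-1,0) is 0 exactly on the first
  # row of the second label
  tb <- two_block_labels()
  a <- compute_affinities(tb)
  ch_y <- array(a$data[2, , , ], dim(tb$data))
  expect_true(all(ch_y[, 9, ] == 0))
  expect_true(all(ch_y[, c(2:8, 10:16), ] == 1))
  # label against background: affinity 0 on both sides of the contact
  lab <- array(0, c(4, 6, 4)); lab[, 1:3, ] <- 5
  a <- compute_affinities(label_volume(lab, c(10, 10, 10)))
  ch_y <- array(a$data[2, , , ], dim(lab))
  expect_true(all(ch_y[, 4, ] == 0)) # background side of the contact
  expect_true(all(ch_y[, 3, ] == 1)) # interior bond of the object
})

test_that("sparse-mode affinity masks require both partners annotated", {
  tb <- two_block_labels()
  msk <- array(FALSE, dim(tb$data))
  msk[, 1:10, ] <- TRUE
  ann <- sparse_annotation(
    label_volume(tb$data * msk, tb$voxel_size), msk)
  a <- compute_affinities(tb, annotation = ann)
  ch_y <- array(a$mask[2, , , ], dim(tb$data))
  expect_true(all(ch_y[, 2:10, ]))
  expect_false(any(ch_y[, 11, ])) # partner (y=10) in, voxel (y=11) out
})

test_that("loss weights respect the annotation mask and class balance", {
  tb <- two_block_labels()
  full <- sparse_annotation(tb, array(TRUE, dim(tb$data)))
  lsd <- compute_lsd(tb, 40)
  w <- make_loss_weights(full, lsd)
  expect_true(all(w == 1))
  empty <- sparse_annotation(label_volume(array(0, dim(tb$data)),
                                          tb$voxel_size),
                             array(FALSE, dim(tb$data)))
  w0 <- make_loss_weights(empty, lsd)
  expect_true(all(w0 == 0))
  # 50 in-mask entries, 10 positive: weight ratio 40/10 = 4, mean weight 1
  lab <- array(0, c(1, 1, 100))
  lab[1, 1, 1:11] <- 1 # 10 in-bounds positive x-affinities
  lv <- label_volume(lab, c(1, 1, 1))
  aff <- compute_affinities(lv, neighborhood = rbind(c(0L, 0L, -1L)))
  msk <- array(FALSE, dim(lab)); msk[1, 1, 1:51] <- TRUE
  ann <- sparse_annotation(label_volume(lab * msk, c(1, 1, 1)), msk)
  # in-mask supervised entries: x = 2..51 (x = 1 has no partner)
  wb <- make_loss_weights(ann, aff, balance = TRUE)
  pos <- wb[aff$data == 1 & wb > 0]
  neg <- wb[aff$data == 0 & wb > 0]
  expect_equal(unique(pos) / unique(neg), 4)
  expect_equal(mean(wb[wb > 0]), 1)
})

test_that("masked MSE matches its closed form and ignores zero weights", {
  expect_equal(masked_mse(array(1, c(2, 2, 2)), array(1, c(2, 2, 2)),
                          array(1, c(2, 2, 2))), 0)
  expect_equal(masked_mse(array(5, c(2, 2, 2)), array(1, c(2, 2, 2)),
                          array(0, c(2, 2, 2))), 0)
  p <- array(c(1, 0), c(2, 1, 1)); t <- array(0, c(2, 1, 1))
  w <- array(c(1, 3), c(2, 1, 1))
  expect_equal(masked_mse(p, t, w), 0.25)
  expect_error(masked_mse(p, t, array(1, c(3, 1, 1))), "shape")
  # finite-difference: perturbing a zero-weight entry changes nothing
  set.seed(2)
  p <- array(runif(27), c(3, 3, 3)); t <- array(runif(27), c(3, 3, 3))
  w <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
  l0 <- masked_mse(p, t, w)
  for (i in which(w == 0)) {
    p2 <- p; p2[i] <- p2[i] + 0.37
    expect_identical(masked_mse(p2, t, w), l0)
  }
})
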