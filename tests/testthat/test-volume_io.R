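test_that("write-read is an identity for all container formats", {
  set.seed(41)
  raw <- volume_grid(array(runif(8 * 16 * 16), c(8, 16, 16)),
                     voxel_size = c(50, 4, 4), offset = c(100, 0, -40))
  lab <- label_volume(array(sample(c(0, 1, 2, 2^40), 8 * 16 * 16,
                                   replace = TRUE), c(8, 16, 16)),
                      voxel_size = c(40, 8, 8))
  for (ext in c("zarr", "n5")) {
    for (grid in list(raw, lab)) {
      p <- file.path(tempfile(), paste0("vol.", ext))
      dir.create(dirname(p), recursive = TRUE)
      write_volume(grid, p, dataset_key = "data")
      back <- read_volume(p, dataset_key = "data")
      expect_identical(dim(back$data), dim(grid$data))
      expect_equal(back$data, grid$data)
      expect_equal(back$voxel_size, grid$voxel_size)
      expect_equal(back$offset, grid$offset)
      expect_equal(back$semantic, grid$semantic)
    }
  }
  # TIFF: raw values are stored as 32-bit float, labels as 16-bit integers
  p <- tempfile(fileext = ".tif")
  write_volume(raw, p)
  back <- read_volume(p)
  expect_equal(back$data, raw$data, tolerance = 1e-6)
  expect_equal(back$voxel_size, raw$voxel_size)
  lab16 <- label_volume(array(sample(0:9, 5 * 32 * 32, replace = TRUE),
                              c(5, 32, 32)), c(40, 4, 4))
  p <- tempfile(fileext = ".tif")
  write_volume(lab16, p)
  back <- read_volume(p)
  expect_identical(back$data, lab16$data)
  expect_s3_class(back, "label_volume")
})

test_that("TIFF stacks map pages to z and fall back to unit voxel size", {
  p <- tempfile(fileext = ".tif")
  g <- volume_grid(array(runif(5 * 32 * 32), c(5, 32, 32)), c(1, 1, 1))
  write_volume(g, p)
  file.remove(paste0(p, ".json")) # drop the geometry sidecar
  withr::with_options(list(bootseg.quiet = FALSE),
                      expect_message(back <- read_volume(p), "voxel_size"))
  expect_identical(dim(back$data), c(5L, 32L, 32L))
  expect_equal(back$voxel_size, c(1, 1, 1))
})

test_that("geometry attributes round-trip through store metadata", {
  g <- volume_grid(array(runif(4 * 8 * 8), c(4, 8, 8)),
                   voxel_size = c(50, 4, 4))
  p <- file.path(tempfile(), "vol.zarr")
  dir.create(dirname(p), recursive = TRUE)
  write_volume(g, p)
  expect_equal(read_volume(p)$voxel_size, c(50, 4, 4))
})

test_that("channelled grids keep the channel axis first", {
  set.seed(7)
  dg <- descriptor_grid(array(runif(6 * 4 * 8 * 8), c(6, 4, 8, 8)),
                        sigma = c(40, 40, 40), voxel_size = c(10, 10, 10))
  p <- file.path(tempfile(), "lsd.zarr")
  dir.create(dirname(p), recursive = TRUE)
  write_volume(dg, p)
  back <- read_volume(p)
  expect_identical(dim(back$data), c(6L, 4L, 8L, 8L))
  expect_equal(back$data, dg$data)
  expect_s3_class(back, "descriptor_grid")
  expect_equal(back$sigma, dg$sigma)
})

test_that("existing datasets are not overwritten without consent", {
  g <- label_volume(array(1, c(4, 4, 4)), c(1, 1, 1))
  p <- file.path(tempfile(), "vol.zarr")
  dir.create(dirname(p), recursive = TRUE)
  write_volume(g, p, dataset_key = "labels")
  expect_error(write_volume(g, p, dataset_key = "labels"), "overwrite")
  expect_silent(write_volume(g, p, dataset_key = "labels", overwrite = TRUE))
})

test_that("unsupported containers give informative errors", {
  g <- label_volume(array(1, c(4, 4, 4)), c(1, 1, 1))
  expect_error(write_volume(g, tempfile(fileext = ".h5")), "HDF5")
  expect_error(read_volume(tempfile(fileext = ".zarr")), "no such file")
})

test_that("SWC skeletons round-trip topology and coordinates", {
  chain <- skeleton(5, data.frame(node_id = 1:3,
                                  z = c(0, 40.5, 81.123),
                                  y = c(8, 8, 9.5), x = c(0, 4, 8.25)),
                    rbind(c(1, 2), c(2, 3)))
  single <- skeleton(9, data.frame(node_id = 1, z = 5, y = 5, x = 5),
                     matrix(integer(), ncol = 2))
  p <- tempfile(fileext = ".swc")
  write_skeletons(list(chain, single), p)
  back <- read_skeletons(p)
  expect_length(back, 2)
  expect_equal(back[[1]]$object_id, 5)
  expect_equal(nrow(back[[1]]$edges), 2)
  expect_equal(back[[1]]$nodes[c("z", "y", "x")],
               chain$nodes[c("z", "y", "x")], tolerance = 1e-3)
  expect_equal(nrow(back[[2]]$edges), 0)
  # root node has parent -1: exactly one node without an incoming edge
  lines <- readLines(p)
  roots <- grep(" -1$", lines)
  expect_length(roots, 2)
})

test_that("dangling SWC parent references are a format error", {
  p <- tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 1.0 -1", "2 0 1 1 1 1.0 7"), p)
  expect_error(read_skeletons(p), "parent")
})

test_that("axis normalization is idempotent (read-write-read identity)", {
  set.seed(13)
  g <- label_volume(array(sample(0:4, 6 * 10 * 12, replace = TRUE),
                          c(6, 10, 12)), c(30, 10, 10), offset = c(0, 10, 20))
  p1 <- file.path(tempfile(), "a.zarr")
  dir.create(dirname(p1), recursive = TRUE)
  write_volume(g, p1)
  r1 <- read_volume(p1)
  p2 <- file.path(tempfile(), "b.n5")
  dir.create(dirname(p2), recursive = TRUE)
  write_volume(r1, p2)
  r2 <- read_volume(p2)
  expect_identical(r1$data, r2$data)
  expect_equal(r1$voxel_size, r2$voxel_size)
})
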