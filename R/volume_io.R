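#' Read and write volumetric grids
#'
#' Supported containers: Zarr v2 directories (uncompressed chunks, attribute
#' keys `voxel_size` and `offset` in `.zattrs`), N5 directories (raw
#' compression, same attribute keys in `attributes.json`), and multi-page
#' TIFF stacks (geometry carried in a JSON sidecar `<path>.json`; a stack
#' without a sidecar gets voxel size `(1, 1, 1)` with a logged warning).
#' Arrays are normalized to the package's `(z, y, x)` / `(c, z, y, x)` axis
#' order. Integer label volumes round-trip losslessly (uint64 in Zarr/N5,
#' 16-bit in TIFF). HDF5 is not a supported container in this build and
#' raises an informative error.
#'
#' @param path file or directory path; format inferred from the extension
#'   (`.zarr`, `.n5`, `.tif`/`.tiff`) or directory contents.
#' @param dataset_key optional dataset name inside a Zarr/N5 store; `NULL`
#'   addresses the store root.
#' @param voxel_size optional fallback voxel size for TIFF stacks without a
#'   sidecar.
#' @return a [volume_grid()] or [label_volume()].
#' @export
read_volume <- function(path, dataset_key = NULL, voxel_size = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  fmt <- detect_format(path)
  switch(fmt,
         zarr = zarr_read(path, dataset_key),
         n5 = n5_read(path, dataset_key),
         tiff = tiff_read(path, voxel_size),
         hdf5 = stop("HDF5 containers are not supported by this build; ",
                     "use Zarr, N5 or TIFF"),
         stop("unrecognized volume format: ", path))
}

#' @rdname read_volume
#' @param grid a [volume_grid()], [label_volume()], [descriptor_grid()] or
#'   [affinity_grid()].
#' @param overwrite replace an existing dataset? Refused (with an error) when
#'   `FALSE`.
#' @export
write_volume <- function(grid, path, dataset_key = NULL, overwrite = FALSE) {
  stopifnot(inherits(grid, "volume_grid"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return(tiff_write(grid, path, overwrite))
  if (ext %in% c("h5", "hdf5", "hdf"))
    stop("HDF5 containers are not supported by this build; use Zarr, N5 or TIFF")
  if (ext == "n5") return(n5_write(grid, path, dataset_key, overwrite))
  zarr_write(grid, path, dataset_key, overwrite)
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("h5", "hdf5", "hdf")) return("hdf5")
  if (dir.exists(path)) {
    if (ext == "n5" || file.exists(file.path(path, "n5_marker")) ||
        (file.exists(file.path(path, "attributes.json")) &&
         !file.exists(file.path(path, ".zarray")) &&
         !file.exists(file.path(path, ".zgroup"))))
      return("n5")
    return("zarr")
  }
  # single non-directory file, unknown extension: try TIFF magic
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (length(magic) == 4 &&
      (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
       identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) return("tiff")
  if (length(magic) == 4 && identical(magic, as.raw(c(0x89, 0x48, 0x44, 0x46))))
    return("hdf5")
  "unknown"
}

# ---- binary helpers ---------------------------------------------------------

write_u64 <- function(con, x, endian = "little") {
  lo <- x %% 2^32
  hi <- x %/% 2^32
  to_i32 <- function(v) as.integer(ifelse(v >= 2^31, v - 2^32, v))
  inter <- if (endian == "little") rbind(to_i32(lo), to_i32(hi)) else rbind(to_i32(hi), to_i32(lo))
  writeBin(as.vector(inter), con, size = 4L, endian = endian)
}

read_u64 <- function(con, n, endian = "little") {
  w <- readBin(con, "integer", 2L * n, size = 4L, endian = endian)
  u <- ifelse(w < 0, w + 2^32, w)
  lo_i <- if (endian == "little") seq(1, 2 * n, 2) else seq(2, 2 * n, 2)
  hi_i <- if (endian == "little") seq(2, 2 * n, 2) else seq(1, 2 * n, 2)
  u[lo_i] + u[hi_i] * 2^32
}

dtype_info <- function(dtype) {
  base <- sub("^[<>|]", "", dtype)
  switch(base,
         f8 = list(what = "double", size = 8L, signed = TRUE),
         f4 = list(what = "double", size = 4L, signed = TRUE),
         u8 = list(what = "u64", size = 8L, signed = FALSE),
         i8 = list(what = "u64", size = 8L, signed = TRUE),
         u4 = list(what = "integer", size = 4L, signed = FALSE),
         i4 = list(what = "integer", size = 4L, signed = TRUE),
         u2 = list(what = "integer", size = 2L, signed = FALSE),
         i2 = list(what = "integer", size = 2L, signed = TRUE),
         u1 = list(what = "integer", size = 1L, signed = FALSE),
         i1 = list(what = "integer", size = 1L, signed = TRUE),
         stop("unsupported dtype: ", dtype))
}

read_typed <- function(con, dtype, n, endian) {
  di <- dtype_info(dtype)
  if (di$what == "u64") return(read_u64(con, n, endian))
  v <- readBin(con, di$what, n, size = di$size, endian = endian,
               signed = if (di$size < 4) di$signed else TRUE)
  if (di$what == "integer" && !di$signed && di$size == 4L)
    v <- ifelse(v < 0, as.numeric(v) + 2^32, as.numeric(v))
  as.numeric(v)
}

write_typed <- function(con, x, dtype, endian) {
  di <- dtype_info(dtype)
  if (di$what == "u64") return(write_u64(con, x, endian))
  if (di$what == "double") writeBin(as.numeric(x), con, size = di$size, endian = endian)
  else writeBin(as.integer(x), con, size = di$size, endian = endian)
}

# reconstruct a grid object from data + stored attributes
grid_from_attrs <- function(data, attrs, dtype) {
  semantic <- attrs$semantic %||%
    (if (grepl("u8|i8", dtype)) "labels" else "raw")
  vs <- as.numeric(attrs$voxel_size %||% c(1, 1, 1))
  off <- as.numeric(attrs$offset %||% c(0, 0, 0))
  if (semantic == "labels") return(label_volume(data, vs, off))
  if (semantic == "descriptor" && !is.null(attrs$sigma))
    return(descriptor_grid(data, as.numeric(attrs$sigma), vs, off))
  if (semantic == "affinity") {
    nb <- if (!is.null(attrs$neighborhood))
      matrix(as.integer(unlist(attrs$neighborhood)), ncol = 3, byrow = TRUE)
    else default_neighborhood()
    return(affinity_grid(clip01(data), neighborhood = nb, voxel_size = vs,
                         offset = off))
  }
  volume_grid(data, vs, off, semantic = semantic)
}

grid_attrs <- function(grid) {
  attrs <- list(voxel_size = grid$voxel_size, offset = grid$offset,
                semantic = grid$semantic)
  if (inherits(grid, "descriptor_grid")) attrs$sigma <- grid$sigma
  if (inherits(grid, "affinity_grid"))
    attrs$neighborhood <- apply(grid$neighborhood, 1, as.list)
  attrs
}

grid_dtype <- function(grid) if (grid$semantic == "labels") "<u8" else "<f8"

# ---- Zarr v2 ----------------------------------------------------------------

zarr_dir <- function(path, dataset_key) {
  if (is.null(dataset_key)) path else file.path(path, dataset_key)
}

zarr_write <- function(grid, path, dataset_key = NULL, overwrite = FALSE) {
  dd <- zarr_dir(path, dataset_key)
  if (file.exists(file.path(dd, ".zarray")) && !overwrite)
    stop("dataset already exists (set overwrite = TRUE): ", dd)
  dir.create(dd, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(dataset_key))
    jsonlite::write_json(list(zarr_format = 2L),
                         file.path(path, ".zgroup"), auto_unbox = TRUE)
  shape <- dim(grid$data)
  dtype <- grid_dtype(grid)
  meta <- list(zarr_format = 2L, shape = as.list(as.integer(shape)),
               chunks = as.list(as.integer(shape)), dtype = dtype,
               compressor = NULL, fill_value = 0, order = "C",
               filters = NULL)
  jsonlite::write_json(meta, file.path(dd, ".zarray"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  jsonlite::write_json(grid_attrs(grid), file.path(dd, ".zattrs"),
                       auto_unbox = TRUE, digits = NA)
  # C order: last axis fastest; R arrays are column-major (first fastest)
  vec <- as.vector(aperm(grid$data, rev(seq_along(shape))))
  con <- file(file.path(dd, paste(rep("0", length(shape)), collapse = ".")), "wb")
  on.exit(close(con))
  write_typed(con, vec, dtype, "little")
  invisible(NULL)
}

zarr_read <- function(path, dataset_key = NULL) {
  dd <- zarr_dir(path, dataset_key)
  zf <- file.path(dd, ".zarray")
  if (!file.exists(zf)) {
    # a store whose root is a group with a single dataset
    subs <- list.dirs(dd, recursive = FALSE)
    subs <- subs[file.exists(file.path(subs, ".zarray"))]
    if (is.null(dataset_key) && length(subs) == 1) return(zarr_read(subs[1]))
    stop("not a Zarr array: ", dd)
  }
  meta <- jsonlite::read_json(zf, simplifyVector = TRUE)
  if (!is.null(meta$compressor) && length(meta$compressor))
    stop("compressed Zarr chunks are not supported")
  shape <- as.integer(meta$shape)
  chunks <- as.integer(meta$chunks)
  if (length(shape) > 4) stop("arrays with more than 4 axes are not supported")
  endian <- if (substr(meta$dtype, 1, 1) == ">") "big" else "little"
  nd <- length(shape)
  ngrid <- ceiling(shape / chunks)
  # assemble in C-order orientation (reversed dims), then aperm back
  arr <- array(meta$fill_value %||% 0, dim = rev(shape))
  idx_grid <- expand.grid(lapply(ngrid, function(n) seq_len(n) - 1L))
  for (r in seq_len(nrow(idx_grid))) {
    ci <- as.integer(idx_grid[r, ])
    cf <- file.path(dd, paste(ci, collapse = "."))
    if (!file.exists(cf)) next
    con <- file(cf, "rb")
    vec <- read_typed(con, meta$dtype, prod(chunks), endian)
    close(con)
    ch <- array(vec, dim = rev(chunks)) # C-order chunk -> reversed R array
    sel <- lapply(seq_len(nd), function(a) {
      lo <- ci[a] * chunks[a] + 1L
      seq(lo, min(lo + chunks[a] - 1L, shape[a]))
    })
    keep <- lapply(seq_len(nd), function(a) seq_along(sel[[a]]))
    arr <- do.call(`[<-`, c(list(arr), rev(sel),
                            list(do.call(`[`, c(list(ch), rev(keep),
                                                list(drop = FALSE))))))
  }
  data <- aperm(arr, rev(seq_len(nd)))
  attrs <- if (file.exists(file.path(dd, ".zattrs")))
    jsonlite::read_json(file.path(dd, ".zattrs"), simplifyVector = TRUE)
  else list()
  grid_from_attrs(data, attrs, meta$dtype)
}

# ---- N5 ---------------------------------------------------------------------

n5_write <- function(grid, path, dataset_key = NULL, overwrite = FALSE) {
  dd <- zarr_dir(path, dataset_key)
  if (file.exists(file.path(dd, "attributes.json")) &&
      file.exists(file.path(dd, "0")) && !overwrite)
    stop("dataset already exists (set overwrite = TRUE): ", dd)
  dir.create(dd, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(n5 = "2.5.0"), file.path(path, "attributes.json"),
                       auto_unbox = TRUE)
  shape <- dim(grid$data)
  nd <- length(shape)
  dtype <- if (grid$semantic == "labels") "uint64" else "float64"
  meta <- c(list(dimensions = as.list(as.integer(rev(shape))), # x fastest
                 dataType = dtype,
                 blockSize = as.list(as.integer(rev(shape))),
                 compression = list(type = "raw")),
            grid_attrs(grid))
  jsonlite::write_json(meta, file.path(dd, "attributes.json"),
                       auto_unbox = TRUE, digits = NA)
  blockdir <- Reduce(file.path, c(dd, rep("0", nd - 1)))
  dir.create(blockdir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(blockdir, "0"), "wb")
  on.exit(close(con))
  writeBin(c(0L), con, size = 2L, endian = "big")                 # mode
  writeBin(as.integer(nd), con, size = 2L, endian = "big")        # numDims
  writeBin(as.integer(rev(shape)), con, size = 4L, endian = "big")
  # N5 lists dimensions x-fastest; aperm so the stored stream matches
  vec <- as.vector(aperm(grid$data, rev(seq_len(nd))))
  write_typed(con, vec,
              if (dtype == "uint64") ">u8" else ">f8", "big")
  invisible(NULL)
}

n5_read <- function(path, dataset_key = NULL) {
  dd <- zarr_dir(path, dataset_key)
  af <- file.path(dd, "attributes.json")
  if (!file.exists(af)) stop("not an N5 dataset: ", dd)
  meta <- jsonlite::read_json(af, simplifyVector = TRUE)
  if (is.null(meta$dimensions)) {
    subs <- list.dirs(dd, recursive = FALSE)
    ok <- subs[vapply(subs, function(s) {
      f <- file.path(s, "attributes.json")
      file.exists(f) &&
        !is.null(jsonlite::read_json(f, simplifyVector = TRUE)$dimensions)
    }, logical(1))]
    if (length(ok) == 1) return(n5_read(ok[1]))
    stop("not an N5 dataset: ", dd)
  }
  if (!identical(meta$compression$type, "raw"))
    stop("compressed N5 blocks are not supported")
  dims_n5 <- as.integer(meta$dimensions)   # x fastest
  nd <- length(dims_n5)
  if (nd > 4) stop("arrays with more than 4 axes are not supported")
  bs <- as.integer(meta$blockSize)
  if (!identical(bs, dims_n5)) stop("multi-block N5 datasets are not supported")
  blockfile <- Reduce(file.path, c(dd, rep("0", nd)))
  con <- file(blockfile, "rb")
  on.exit(close(con))
  readBin(con, "integer", 1, size = 2L, endian = "big")
  nd2 <- readBin(con, "integer", 1, size = 2L, endian = "big")
  readBin(con, "integer", nd2, size = 4L, endian = "big")
  dt <- switch(meta$dataType, uint64 = ">u8", int64 = ">i8",
               float64 = ">f8", float32 = ">f4",
               uint32 = ">u4", int32 = ">i4", uint16 = ">u2",
               uint8 = ">u1", stop("unsupported N5 dataType: ", meta$dataType))
  vec <- read_typed(con, dt, prod(dims_n5), "big")
  # stream is x-fastest in N5 dimension order; transpose back to (z, y, x)
  data <- aperm(array(vec, dim = dims_n5), rev(seq_len(nd)))
  grid_from_attrs(data, meta, dt)
}

# ---- TIFF -------------------------------------------------------------------

tiff_write <- function(grid, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("file already exists (set overwrite = TRUE): ", path)
  if (length(dim(grid$data)) != 3)
    stop("TIFF stacks hold (z, y, x) volumes; use Zarr/N5 for channelled grids")
  d <- dim(grid$data)
  if (grid$semantic == "labels") {
    if (max(grid$data) > 65535)
      stop("TIFF label export supports ids up to 65535; use Zarr/N5")
    pages <- lapply(seq_len(d[1]), function(z)
      matrix(grid$data[z, , ], d[2], d[3]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    rng <- range(grid$data)
    if (rng[1] < 0 || rng[2] > 1)
      stop("TIFF export of non-label grids expects values in [0, 1]")
    pages <- lapply(seq_len(d[1]), function(z)
      matrix(grid$data[z, , ], d[2], d[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  jsonlite::write_json(grid_attrs(grid), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

tiff_read <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  if (length(d) != 2) stop("only single-channel TIFF pages are supported")
  data <- array(0, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) data[z, , ] <- pages[[z]]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attrs <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (identical(attrs$semantic, "labels"))
      data <- round(data * 65535)
    return(grid_from_attrs(data, attrs, "<f8"))
  }
  vs <- voxel_size
  if (is.null(vs)) {
    bs_log("TIFF stack has no geometry metadata; assuming voxel_size (1,1,1) nm")
    vs <- c(1, 1, 1)
  }
  volume_grid(data, vs, c(0, 0, 0), semantic = "raw")
}

# ---- SWC skeletons ----------------------------------------------------------

#' Read and write skeletons in SWC format
#'
#' The SWC dialect used here stores one object per block, blocks concatenated
#' in a single file separated by `# object <id>` comments (a file without a
#' separator is a single anonymous object). Coordinates are in nanometers;
#' the radius field is ignored on read and written as 1.0. Round trips
#' preserve topology and coordinates to 1e-3 nm.
#'
#' @param path file path.
#' @return `read_skeletons()`: a list of [skeleton()] objects.
#' @export
read_skeletons <- function(path) {
  lines <- readLines(path)
  obj_id <- NA_real_
  blocks <- list()
  cur <- character()
  flush <- function() {
    if (!length(cur)) return()
    blocks[[length(blocks) + 1]] <<- list(id = obj_id, lines = cur)
    cur <<- character()
  }
  for (ln in lines) {
    if (grepl("^#\\s*object\\s+", ln)) {
      flush()
      obj_id <- as.numeric(sub("^#\\s*object\\s+", "", ln))
      next
    }
    if (grepl("^\\s*(#|$)", ln)) next
    cur <- c(cur, ln)
  }
  flush()
  lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    f <- read.table(text = b$lines,
                    col.names = c("id", "type", "x", "y", "z", "r", "parent"))
    if (any(!(f$parent %in% c(-1, f$id))))
      stop("SWC parent id not present in file: ",
           paste(setdiff(f$parent, c(-1, f$id)), collapse = ", "))
    has_parent <- f$parent != -1
    edges <- cbind(f$id[has_parent], f$parent[has_parent])
    skeleton(object_id = if (is.na(b$id)) i else b$id,
             nodes = data.frame(node_id = f$id, z = f$z, y = f$y, x = f$x),
             edges = if (nrow(edges)) edges else matrix(integer(), ncol = 2))
  })
}

#' @rdname read_skeletons
#' @param skeletons a list of [skeleton()] objects.
#' @export
write_skeletons <- function(skeletons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sk in skeletons) {
    writeLines(sprintf("# object %g", sk$object_id), con)
    # parent assignment: orient edges away from the first node via BFS
    n <- nrow(sk$nodes)
    parent <- setNames(rep(-1, n), sk$nodes$node_id)
    if (nrow(sk$edges)) {
      adj <- split(c(sk$edges[, 2], sk$edges[, 1]),
                   c(sk$edges[, 1], sk$edges[, 2]))
      visited <- setNames(rep(FALSE, n), sk$nodes$node_id)
      for (root in sk$nodes$node_id) {
        rk <- as.character(root)
        if (visited[rk]) next
        visited[rk] <- TRUE
        queue <- root
        while (length(queue)) {
          v <- queue[1]; queue <- queue[-1]
          for (w in adj[[as.character(v)]] %||% numeric()) {
            wk <- as.character(w)
            if (!visited[wk]) {
              visited[wk] <- TRUE
              parent[wk] <- v
              queue <- c(queue, w)
            }
          }
        }
      }
    }
    writeLines(sprintf("%d 0 %.3f %.3f %.3f 1.0 %d",
                       sk$nodes$node_id, sk$nodes$x, sk$nodes$y, sk$nodes$z,
                       as.integer(parent[as.character(sk$nodes$node_id)])),
               con)
  }
  invisible(NULL)
}
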