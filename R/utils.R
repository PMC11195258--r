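clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of the package consumes its own sub-seed derived
#' from a master seed by a counter-based splitting rule, so that individual
#' draws (a training iteration, a section's jitter, a pipeline stage) are
#' reproducible in isolation.
#'
#' @param master integer master seed.
#' @param index non-negative integer counter identifying the draw.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_subseed <- function(master, index) {
  m <- 2147483587
  s <- (as.numeric(master) %% m)
  ((s * 69621 + (as.numeric(index) + 1) * 10007 + 12345) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# message gated by option, used for logged warnings that are part of contracts
bs_log <- function(...) {
  if (isTRUE(getOption("bootseg.quiet", FALSE))) return(invisible(NULL))
  message(...)
}

# offsets of a world-unit ball structuring element, radius in voxels of the
# finest axis; returns k x 3 integer matrix of (dz, dy, dx)
ball_offsets <- function(radius_vox, voxel_size) {
  r_world <- radius_vox * min(voxel_size)
  rr <- pmax(0L, as.integer(floor(r_world / voxel_size + 1e-9)))
  g <- expand.grid(dz = -rr[1]:rr[1], dy = -rr[2]:rr[2], dx = -rr[3]:rr[3])
  d <- sqrt((g$dz * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 +
              (g$dx * voxel_size[3])^2)
  as.matrix(g[d <= r_world + 1e-9, , drop = FALSE])
}
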