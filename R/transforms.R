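# The M = 7 invertible tile transformations used for transformation-based
# uncertainty estimation: three rotations, two flips, a recorded block
# permutation ("patching") and a recorded color-channel permutation. Every
# spec carries enough state to invert its action on prediction maps exactly.

#' Build the fixed suite of 7 transformations
#'
#' Order is fixed (rot90, rot180, rot270, hflip, vflip, patch_shuffle,
#' color_channel) so that per-pixel agreement counting is reproducible. The
#' stochastic parameters — the patch-grid permutation and the channel
#' permutation — are drawn from `seed` and recorded inside the specs.
#'
#' @param seed integer seed for the recorded permutations
#' @param patch_grid patch grid size k (the tile is cut into k x k blocks)
#' @return list of 7 `transform_spec` objects
#' @export
transform_suite <- function(seed = 1L, patch_grid = 4L) {
  if (patch_grid < 1L) stop("patch_grid must be >= 1")
  with_seed(seed, {
    patch_perm <- sample(patch_grid^2)
    chan_perm <- sample(3L)
    list(
      transform_spec("rot90"),
      transform_spec("rot180"),
      transform_spec("rot270"),
      transform_spec("hflip"),
      transform_spec("vflip"),
      transform_spec("patch_shuffle",
                     params = list(grid = as.integer(patch_grid),
                                   perm = patch_perm)),
      transform_spec("color_channel", params = list(perm = chan_perm),
                     spatial = FALSE)
    )
  })
}

#' One invertible transformation
#'
#' @param kind one of rot90, rot180, rot270, hflip, vflip, patch_shuffle,
#'   color_channel
#' @param params kind-specific recorded randomness (permutations)
#' @param spatial whether the inverse must act on prediction maps (`FALSE`
#'   only for color_channel, whose action leaves spatial layout intact)
#' @return a `transform_spec`
#' @export
transform_spec <- function(kind, params = list(), spatial = kind != "color_channel") {
  kinds <- c("rot90", "rot180", "rot270", "hflip", "vflip",
             "patch_shuffle", "color_channel")
  kind <- match.arg(kind, kinds)
  if (kind == "patch_shuffle") {
    if (is.null(params$perm) || is.null(params$grid))
      stop("patch_shuffle needs a recorded grid and permutation")
    if (!setequal(params$perm, seq_len(params$grid^2)))
      stop("patch permutation must be a bijection on grid cells")
  }
  if (kind == "color_channel" && is.null(params$perm))
    stop("color_channel needs a recorded channel permutation")
  structure(list(kind = kind, params = params, spatial = spatial),
            class = "transform_spec")
}

# rotate an H x W x C array counter-clockwise by 90 degrees
rot90_ccw <- function(x) {
  d <- dim(x)
  aperm(x, c(2L, 1L, 3L))[d[2]:1, , , drop = FALSE]
}

rot90_cw <- function(x) {
  d <- dim(x)
  aperm(x[d[1]:1, , , drop = FALSE], c(2L, 1L, 3L))
}

apply_spatial <- function(spec, x) {
  d <- dim(x)
  switch(spec$kind,
    rot90 = {
      if (d[1] != d[2]) stop("90/270 degree rotation requires square tiles")
      rot90_ccw(x)
    },
    rot180 = x[d[1]:1, d[2]:1, , drop = FALSE],
    rot270 = {
      if (d[1] != d[2]) stop("90/270 degree rotation requires square tiles")
      rot90_cw(x)
    },
    hflip = x[, d[2]:1, , drop = FALSE],
    vflip = x[d[1]:1, , , drop = FALSE],
    patch_shuffle = patch_permute(x, spec$params$grid, spec$params$perm),
    stop("not a spatial transform: ", spec$kind)
  )
}

invert_spatial <- function(spec, x) {
  inv <- switch(spec$kind,
    rot90 = transform_spec("rot270"),
    rot270 = transform_spec("rot90"),
    rot180 = spec, hflip = spec, vflip = spec,
    patch_shuffle = transform_spec("patch_shuffle",
      params = list(grid = spec$params$grid, perm = order(spec$params$perm))),
    stop("not a spatial transform: ", spec$kind))
  apply_spatial(inv, x)
}

# permute non-overlapping blocks of a k x k grid; perm[j] = source cell of
# destination cell j (cells numbered column-major)
patch_permute <- function(x, grid, perm) {
  d <- dim(x)
  if (d[1] %% grid != 0L || d[2] %% grid != 0L)
    stop("tile dimensions must be divisible by the patch grid")
  bh <- d[1] %/% grid; bw <- d[2] %/% grid
  out <- x
  for (j in seq_len(grid^2)) {
    src <- perm[j]
    si <- (src - 1L) %% grid; sj <- (src - 1L) %/% grid
    di <- (j - 1L) %% grid; dj <- (j - 1L) %/% grid
    out[di * bh + seq_len(bh), dj * bw + seq_len(bw), ] <-
      x[si * bh + seq_len(bh), sj * bw + seq_len(bw), , drop = FALSE]
  }
  out
}

#' Apply a transformation to an image
#'
#' Spatial kinds are exact pixel permutations; `color_channel` permutes the
#' three color channels and leaves the spatial layout intact.
#'
#' @param spec a `transform_spec`
#' @param image H x W x C array
#' @return transformed array, same shape
#' @export
apply_transform <- function(spec, image) {
  stopifnot(inherits(spec, "transform_spec"))
  d <- dim(image)
  if (length(d) != 3L) stop("image must be an H x W x C array")
  if (spec$kind == "color_channel") {
    if (d[3] != length(spec$params$perm))
      stop("channel count does not match the recorded permutation")
    return(image[, , spec$params$perm, drop = FALSE])
  }
  apply_spatial(spec, image)
}

#' Invert a transformation's action on a prediction map
#'
#' Spatial specs undo their pixel permutation on the H x W x n_classes map;
#' `color_channel` is the identity (class channels are not image channels).
#'
#' @param spec a `transform_spec`
#' @param pred_map H x W x n_classes array of scores or probabilities
#' @return array of the same shape
#' @export
invert_on_prediction <- function(spec, pred_map) {
  stopifnot(inherits(spec, "transform_spec"))
  if (length(dim(pred_map)) != 3L)
    stop("pred_map must be an H x W x n_classes array")
  if (!spec$spatial) return(pred_map)
  invert_spatial(spec, pred_map)
}
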