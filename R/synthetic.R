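# Synthetic H&E-like tile generator. Tiles mimic the statistical structure of
# stained pathology tiles: pink-ish stroma background, purple-ish smooth tumor
# blobs with irregular boundaries, channel-correlated texture noise, and a
# configurable fraction of tumor-free tiles to exercise the exclusion filter.

#' Synthetic dataset configuration
#'
#' Defaults mirror the composition of the tile collection the pipeline is
#' designed around: 1,020 tiles of 640 x 640 pixels of which 569 contain no
#' tumor. Tests and examples pass smaller `n_images` / `tile_size`.
#'
#' @param n_images number of tiles to generate
#' @param tile_size side length in pixels (square tiles)
#' @param tumor_free_fraction fraction of tiles with an empty mask, in `[0, 1]`
#' @param tumor_area_range min/max tumor area as a fraction of the tile
#' @param blob_smoothness Gaussian smoothing bandwidth of the random field that
#'   shapes tumor blobs, as a fraction of `tile_size`
#' @param noise_sd intensity standard deviation of the texture noise
#' @param seed integer seed; generation is bit-reproducible for a fixed seed
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_images = 1020L, tile_size = 640L,
                             tumor_free_fraction = 569 / 1020,
                             tumor_area_range = c(0.05, 0.4),
                             blob_smoothness = 0.12, noise_sd = 0.05,
                             seed = 1L) {
  if (n_images < 1L) stop("n_images must be >= 1")
  if (tile_size < 8L) stop("tile_size must be >= 8")
  if (tumor_free_fraction < 0 || tumor_free_fraction > 1)
    stop("tumor_free_fraction must be in [0, 1]")
  if (length(tumor_area_range) != 2L || any(tumor_area_range <= 0) ||
      any(tumor_area_range >= 1) || diff(tumor_area_range) < 0)
    stop("tumor_area_range must be an increasing pair in (0, 1)")
  if (blob_smoothness <= 0) stop("blob_smoothness must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_images = as.integer(n_images),
                 tile_size = as.integer(tile_size),
                 tumor_free_fraction = tumor_free_fraction,
                 tumor_area_range = tumor_area_range,
                 blob_smoothness = blob_smoothness,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# H&E-ish base colors: eosin-pink stroma, hematoxylin-purple tumor
.stroma_rgb <- c(0.91, 0.73, 0.83)
.tumor_rgb <- c(0.52, 0.38, 0.68)

smooth_field <- function(n, sigma) {
  sigma <- min(sigma, (n - 1) / 7)  # keep the Gaussian brush inside the tile
  f <- EBImage::gblur(matrix(stats::rnorm(n * n), n, n), sigma = sigma)
  as.matrix(EBImage::imageData(f))
}

# Connected tumor blob with area (in pixels) close to `target`: threshold a
# smoothed random field and keep the superlevel component containing the field
# maximum; the threshold is found by bisection (component area is monotone in
# the threshold since superlevel sets nest).
tumor_blob <- function(n, sigma, target, range_px) {
  f <- smooth_field(n, sigma)
  pk <- which.max(f)
  lo <- min(f); hi <- max(f)
  tol <- n  # one boundary row of pixels
  best <- NULL; best_score <- Inf
  for (it in 1:30) {
    th <- (lo + hi) / 2
    bw <- f > th
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(bw)))
    m <- lab == lab[pk]
    a <- sum(m)
    # the component's area can jump when superlevel sets merge; keep the
    # candidate closest to the target, strongly preferring areas inside the
    # configured range
    outside <- max(0, range_px[1] - a, a - range_px[2])
    score <- outside * n * n + abs(a - target)
    if (score < best_score) { best <- m; best_score <- score }
    if (abs(a - target) <= tol) break
    if (a > target) lo <- th else hi <- th
  }
  storage.mode(best) <- "integer"
  best
}

render_tile <- function(n, mask, noise_sd) {
  img <- array(0, c(n, n, 3))
  shared <- smooth_field(n, sigma = 1.2)          # channel-correlated speckle
  drift <- smooth_field(n, sigma = n / 8) * 1.5   # slow staining drift
  for (ch in 1:3) {
    base <- .stroma_rgb[ch] + (.tumor_rgb[ch] - .stroma_rgb[ch]) * mask
    indep <- matrix(stats::rnorm(n * n), n, n)
    img[, , ch] <- base + noise_sd * (0.7 * shared + 0.7 * indep) + 0.04 * drift
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic tile dataset
#'
#' Produces `n_images` image samples; exactly
#' `round(tumor_free_fraction * n_images)` of them have an empty mask. Tumor
#' blobs are smooth connected regions whose area fraction is drawn from
#' `tumor_area_range`; tumor and background have distinct H&E-like color
#' distributions. Bit-reproducible for a fixed seed.
#'
#' @param config a [synthetic_config()]
#' @return list of `image_sample` objects (fields `image`, `mask`,
#'   `has_tumor`, `id`)
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$tile_size
  n_empty <- round(config$tumor_free_fraction * config$n_images)
  with_seed(config$seed, {
    empty_idx <- if (n_empty > 0L)
      sample(config$n_images, n_empty) else integer(0)
    lapply(seq_len(config$n_images), function(i) {
      has_tumor <- !(i %in% empty_idx)
      if (has_tumor) {
        a <- stats::runif(1, config$tumor_area_range[1], config$tumor_area_range[2])
        range_px <- c(config$tumor_area_range[1] * n * n - n,
                      config$tumor_area_range[2] * n * n + n)
        mask <- tumor_blob(n, config$blob_smoothness * n, round(a * n * n),
                           range_px)
      } else {
        mask <- matrix(0L, n, n)
      }
      img <- render_tile(n, mask, config$noise_sd)
      image_sample(img, mask, id = sprintf("tile_%05d", i))
    })
  })
}

#' Construct an image sample
#'
#' @param image H x W x 3 array in `[0, 1]`
#' @param mask H x W binary matrix (`{0, 1}`) or `NULL`
#' @param id sample identifier
#' @return an `image_sample` list; `has_tumor` is `TRUE` iff the mask has at
#'   least one tumor pixel
#' @export
image_sample <- function(image, mask = NULL, id = "sample") {
  d <- dim(image)
  if (length(d) != 3L) stop("image must be an H x W x C array")
  if (!is.null(mask)) {
    if (!all(dim(mask) == d[1:2]))
      stop("image and mask dimensions differ for sample ", id)
    if (!all(mask %in% c(0L, 1L)))
      stop("mask must be binary {0,1} for sample ", id)
  }
  structure(list(image = image, mask = mask,
                 has_tumor = !is.null(mask) && any(mask == 1L),
                 id = id),
            class = "image_sample")
}

#' Drop tumor-free tiles
#'
#' Keeps exactly the samples whose mask contains at least one tumor pixel,
#' preserving order. Samples without a mask are an error.
#'
#' @param samples list of `image_sample`
#' @return filtered list
#' @export
filter_tumor_present <- function(samples) {
  for (s in samples) {
    if (is.null(s$mask))
      stop("sample ", s$id, " has no mask; cannot apply the exclusion filter")
  }
  Filter(function(s) isTRUE(s$has_tumor), samples)
}

#' Test / cross-validation / labeled-unlabeled split
#'
#' Holds out `round(test_fraction * N)` samples as a disjoint test set,
#' partitions the remainder into `n_folds` near-equal folds, and within each
#' fold's training portion flags `round(labeled_fraction * N_train)` samples
#' as labeled. Deterministic for a fixed seed.
#'
#' @param samples list of `image_sample` (or a character vector of ids)
#' @param labeled_fraction fraction of each training split that is labeled
#' @param test_fraction fraction of all samples held out for testing
#' @param n_folds number of cross-validation folds (>= 2)
#' @param seed integer seed
#' @return a `semi_split`: list with `test` (ids) and `folds`, each fold a
#'   list with `labeled`, `unlabeled`, `val` id vectors
#' @export
split_semi <- function(samples, labeled_fraction = 0.1, test_fraction = 0.1,
                       n_folds = 5L, seed = 1L) {
  ids <- if (is.character(samples)) samples
         else vapply(samples, function(s) s$id, character(1))
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop("labeled_fraction must be in (0, 1]")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  N <- length(ids)
  with_seed(seed, {
    perm <- sample(ids)
    n_test <- round(test_fraction * N)
    test <- perm[seq_len(n_test)]
    rest <- perm[-seq_len(n_test)]
    fold_of <- rep(seq_len(n_folds), length.out = length(rest))
    folds <- lapply(seq_len(n_folds), function(f) {
      val <- rest[fold_of == f]
      train <- rest[fold_of != f]
      n_lab <- round(labeled_fraction * length(train))
      if (n_lab < 1L)
        stop("labeled_fraction too small: no labeled sample after rounding")
      list(labeled = train[seq_len(n_lab)],
           unlabeled = if (n_lab < length(train)) train[-seq_len(n_lab)] else character(0),
           val = val)
    })
    structure(list(test = test, folds = folds), class = "semi_split")
  })
}

#' Write samples to a fixture directory
#'
#' Layout: `images/<id>.png` (8-bit RGB), `masks/<id>.png` (8-bit grayscale,
#' values 0 and 255), `manifest.tsv` (id, has_tumor).
#'
#' @param samples list of `image_sample`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(id = character(0), has_tumor = logical(0))
  for (s in samples) {
    png::writePNG(s$image, file.path(dir, "images", paste0(s$id, ".png")))
    if (!is.null(s$mask))
      png::writePNG(matrix(as.numeric(s$mask), nrow(s$mask)),
                    file.path(dir, "masks", paste0(s$id, ".png")))
    man <- rbind(man, data.frame(id = s$id, has_tumor = s$has_tumor))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read samples back from a fixture directory
#'
#' Masks must be strictly binary (pixel values 0 or 255 on disk); a missing
#' mask or a size mismatch is an error naming the offending id.
#'
#' @param dir fixture directory written by [write_fixture()]
#' @return list of `image_sample`
#' @export
read_fixture <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  lapply(man$id, function(id) {
    ipath <- file.path(dir, "images", paste0(id, ".png"))
    mpath <- file.path(dir, "masks", paste0(id, ".png"))
    if (!file.exists(ipath)) stop("missing image for id ", id)
    if (!file.exists(mpath)) stop("missing mask for id ", id)
    img <- png::readPNG(ipath)
    msk <- png::readPNG(mpath)
    if (length(dim(msk)) > 2L) stop("mask for id ", id, " is not single-channel")
    if (!all(msk %in% c(0, 1)))
      stop("mask for id ", id, " is not binary {0,255}")
    if (!all(dim(msk) == dim(img)[1:2]))
      stop("image/mask dimensions differ for id ", id)
    m <- matrix(as.integer(msk), nrow(msk), ncol(msk))
    image_sample(img, m, id = id)
  })
}
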