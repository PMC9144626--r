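#' Two-channel MPM image container
#'
#' Holds the second-harmonic-generation (SHG) and autofluorescence (AF)
#' channels of one frame as integer matrices on a common bit depth.
#'
#' @param shg,af Numeric matrices of equal dimension.
#' @param bit_depth 8 or 12.
#' @param pixel_size Pixel pitch in micrometres.
#' @return An object of class `mpm_image`.
#' @export
mpm_image <- function(shg, af, bit_depth = 12L, pixel_size = 1) {
  shg <- as.matrix(shg); af <- as.matrix(af)
  if (!identical(dim(shg), dim(af))) stop("SHG and AF channels must share shape")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 12L)) stop("bit_depth must be 8 or 12")
  vmax <- 2^bit_depth - 1
  if (min(shg) < 0 || max(shg) > vmax || min(af) < 0 || max(af) > vmax)
    stop("intensities outside [0, 2^bit_depth - 1]")
  structure(list(shg = shg, af = af, bit_depth = bit_depth,
                 pixel_size = pixel_size),
            class = "mpm_image")
}

#' @export
print.mpm_image <- function(x, ...) {
  cat(sprintf("<mpm_image> %d x %d px, %d-bit, %.3g um/px\n",
              nrow(x$shg), ncol(x$shg), x$bit_depth, x$pixel_size))
  cat(sprintf("  SHG range [%d, %d]; AF range [%d, %d]\n",
              min(x$shg), max(x$shg), min(x$af), max(x$af)))
  invisible(x)
}

# validate a label mask: integer matrix over {0 Outer, 1 Stroma, 2 Epithelial}
check_mask <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  bad <- setdiff(unique(as.vector(mask)), c(0L, 1L, 2L))
  if (length(bad)) stop("mask contains values outside {0,1,2}: ",
                        paste(bad, collapse = ", "))
  mask
}

#' Write / read a two-channel image as multi-page 16-bit TIFF
#'
#' Page 1 is SHG, page 2 is AF; raw integer values are stored verbatim in
#' the 16-bit container so the round trip is bit-exact.
#'
#' @param image An [mpm_image()].
#' @param path Output TIFF path.
#' @return `write_mpm_image` returns `path` invisibly; `read_mpm_image`
#'   returns an `mpm_image`.
#' @export
write_mpm_image <- function(image, path) {
  stopifnot(inherits(image, "mpm_image"))
  pages <- list(image$shg / 65535, image$af / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mpm_image
#' @param bit_depth Bit depth of the stored data (metadata carried in the
#'   manifest, not the file).
#' @param pixel_size Pixel pitch in micrometres.
#' @export
read_mpm_image <- function(path, bit_depth = 12L, pixel_size = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) < 2L) stop("expected a 2-page (SHG, AF) TIFF: ", path)
  mpm_image(pages[[1]], pages[[2]], bit_depth = bit_depth,
            pixel_size = pixel_size)
}

#' Write / read a label mask as 8-bit PNG
#'
#' Pixel values are stored verbatim (0 = Outer, 1 = Stroma, 2 = Epithelial);
#' the round trip is bit-exact.
#'
#' @param mask Integer matrix over \{0, 1, 2\}.
#' @param path Output PNG path.
#' @return `write_mask` returns `path` invisibly; `read_mask` the matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- check_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  check_mask(round(m * 255))
}

#' Write / read a dataset manifest CSV
#'
#' A manifest is a data frame with one row per image: `image_id`,
#' `patient_id`, `lesion` (FA|PT), `image_path`, `mask_path`, `seed`, and
#' optionally `split` (train|test) and `pred_mask_path`. Paths are stored
#' relative to the manifest file; the loaded data frame carries the root
#' directory in `attr(, "root")`.
#'
#' @param manifest Manifest data frame.
#' @param path CSV path.
#' @return `read_manifest` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(m$image_id)) stop("duplicate image_id in manifest")
  attr(m, "root") <- dirname(normalizePath(path))
  m
}

# absolute path for a manifest path column entry
manifest_path <- function(manifest, column, i) {
  p <- manifest[[column]][i]
  root <- attr(manifest, "root")
  ifelse(is.na(p) | p == "", NA_character_,
         ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                if (is.null(root)) p else file.path(root, p)))
}

#' Convert a 12-bit image to 8-bit
#'
#' Fixed global mapping `floor(v / 16)`, the plain truncation of the four
#' least significant bits; 8-bit input passes through unchanged.
#'
#' @param image An [mpm_image()].
#' @return An 8-bit `mpm_image`.
#' @export
#' @examples
#' img <- mpm_image(matrix(4095, 2, 2), matrix(16, 2, 2))
#' convert_to_8bit(img)$shg[1, 1]  # 255
convert_to_8bit <- function(image) {
  stopifnot(inherits(image, "mpm_image"))
  if (image$bit_depth == 8L) return(image)
  mpm_image(floor(image$shg / 16), floor(image$af / 16),
            bit_depth = 8L, pixel_size = image$pixel_size)
}

#' Tile an image and mask into square blocks
#'
#' Cuts the frame into non-overlapping `block_px`-sized blocks in row-major
#' order (block rows outer). Concatenating the blocks reconstructs the
#' originals bit-exactly.
#'
#' @param image An [mpm_image()] or `NULL` for mask-only tiling.
#' @param mask Label mask matrix (may be `NULL` if `image` given).
#' @param block_px Block side in pixels; must divide the frame side.
#' @return List of blocks, each `list(shg, af, mask, block_row, block_col)`.
#' @export
tile_image <- function(image, mask, block_px = 128L) {
  ref <- if (!is.null(image)) image$shg else mask
  H <- nrow(ref); W <- ncol(ref)
  block_px <- as.integer(block_px)
  if (H %% block_px != 0L || W %% block_px != 0L)
    stop("frame side (", H, "x", W, ") not divisible by block size ", block_px)
  out <- vector("list", (H %/% block_px) * (W %/% block_px))
  k <- 0L
  for (br in seq_len(H %/% block_px)) {
    rr <- ((br - 1L) * block_px + 1L):(br * block_px)
    for (bc in seq_len(W %/% block_px)) {
      cc <- ((bc - 1L) * block_px + 1L):(bc * block_px)
      k <- k + 1L
      out[[k]] <- list(
        shg = if (!is.null(image)) image$shg[rr, cc] else NULL,
        af = if (!is.null(image)) image$af[rr, cc] else NULL,
        mask = if (!is.null(mask)) mask[rr, cc] else NULL,
        block_row = br, block_col = bc)
    }
  }
  out
}

#' Randomly split a manifest into training and test images
#'
#' Marks `floor(train_fraction * N)` images as `train` (uniform, without
#' replacement) and the remainder as `test`; deterministic per seed.
#'
#' @param manifest Manifest data frame.
#' @param train_fraction Fraction in (0, 1) of images used for training.
#' @param seed Integer seed.
#' @return The manifest with a `split` column.
#' @export
#' @examples
#' m <- data.frame(image_id = sprintf("img%02d", 1:76))
#' table(split_dataset(m, 0.5, seed = 1)$split)  # 38 train / 38 test
split_dataset <- function(manifest, train_fraction, seed = 1L) {
  n <- nrow(manifest)
  if (is.null(n) || n == 0L) stop("empty manifest")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, function() sample.int(n, n_train))
  manifest$split <- "test"
  manifest$split[idx] <- "train"
  manifest
}
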