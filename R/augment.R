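# The four augmentation strategies (in-plane rotation, masking, zoom,
# shift) and the leakage-safe split-before-augment dataset builder.
# Geometric transforms share one inverse-affine resampler; exact lattice
# motions (multiples of 90 degrees, integer shifts) reproduce exactly.

# Inverse-affine resampling about the image center. A maps output coords
# to source coords (2x2), t is an extra source-space offset.
affine_resample <- function(image, A, t = c(0, 0), fill = 0,
                            interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(image); W <- ncol(image)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  r <- rep(seq_len(H), times = W) - cr
  c <- rep(seq_len(W), each = H) - cc
  sr <- A[1, 1] * r + A[1, 2] * c + cr + t[1]
  sc <- A[2, 1] * r + A[2, 2] * c + cc + t[2]
  out <- rep(fill, H * W)
  if (interp == "nearest") {
    ir <- round(sr); ic <- round(sc)
    ok <- ir >= 1 & ir <= H & ic >= 1 & ic <= W
    out[ok] <- image[cbind(ir[ok], ic[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
    i00 <- cbind(r0[ok], c0[ok])
    v <- (1 - fr[ok]) * (1 - fc[ok]) * image[i00] +
      fr[ok] * (1 - fc[ok]) * image[i00 + c(1L, 0L)] +
      (1 - fr[ok]) * fc[ok] * image[i00 + c(0L, 1L)] +
      fr[ok] * fc[ok] * image[i00 + c(1L, 1L)]
    out[ok] <- v
    # exact border pixels (source exactly on the last row/col)
    edge <- !ok & sr >= 1 & sr <= H & sc >= 1 & sc <= W &
      abs(sr - round(sr)) < 1e-9 & abs(sc - round(sc)) < 1e-9
    out[edge] <- image[cbind(round(sr[edge]), round(sc[edge]))]
  }
  matrix(out, H, W)
}

#' Rotate a pattern in the detector plane
#'
#' Rotation about the image center, emulating in-plane particle rotation.
#' Angles that are exact multiples of 90 degrees are lattice-preserving and
#' applied exactly; other angles are interpolated (bilinear by default).
#' Pixels rotated in from outside the frame take the `fill` value.
#'
#' @param image Numeric matrix (square for exact 90-degree rotations).
#' @param angle_deg Rotation angle in degrees (counter-clockwise).
#' @param fill Fill value for exposed pixels.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return Rotated image of the same shape.
#' @export
random_rotation <- function(image, angle_deg, fill = 0,
                            interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  a <- angle_deg %% 360
  if (a == 0) return(image)
  if (nrow(image) == ncol(image) && a %% 90 == 0) {
    k <- as.integer(a / 90)
    rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    for (i in seq_len(k)) image <- rot90(image)
    return(image)
  }
  th <- angle_deg * pi / 180
  # inverse rotation maps output pixels back to source pixels
  A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L, byrow = TRUE)
  affine_resample(image, A, fill = fill, interp = interp)
}

#' Mask random rectangular blocks
#'
#' Covers `n_blocks` random rectangles with a constant fill value,
#' emulating bad pixels and parasitic-scatter exclusion regions. Unmasked
#' pixels are bit-identical to the input.
#'
#' @param image Numeric matrix.
#' @param n_blocks Number of rectangles.
#' @param block_size_range Range (min, max) of block edge length in pixels.
#' @param fill Fill value.
#' @param seed Integer seed.
#' @return Masked image.
#' @export
random_masking <- function(image, n_blocks = 1L, block_size_range = c(8L, 24L),
                           fill = 0, seed = 1L) {
  if (n_blocks == 0L) return(image)
  H <- nrow(image); W <- ncol(image)
  with_seed(seed, {
    for (b in seq_len(n_blocks)) {
      bh <- sample(block_size_range[1]:block_size_range[2], 1L)
      bw <- sample(block_size_range[1]:block_size_range[2], 1L)
      r0 <- sample.int(H, 1L)
      c0 <- sample.int(W, 1L)
      image[r0:min(H, r0 + bh - 1L), c0:min(W, c0 + bw - 1L)] <- fill
    }
    image
  })
}

#' Zoom a pattern about its center
#'
#' `factor > 1` magnifies (the border of the field of view is lost),
#' `factor < 1` shrinks (exposed border pixels take `fill`). Output shape
#' equals input shape. Emulates changes in effective detector distance or
#' wavelength.
#'
#' @inheritParams random_rotation
#' @param factor Zoom factor (> 0).
#' @return Zoomed image.
#' @export
random_zoom <- function(image, factor, fill = 0,
                        interp = c("bilinear", "nearest")) {
  assert_positive(factor, "zoom factor")
  if (factor == 1) return(image)
  A <- diag(c(1 / factor, 1 / factor))
  affine_resample(image, A, fill = fill, interp = match.arg(interp))
}

#' Shift a pattern
#'
#' Translates by `(dr, dc)` pixels (rows down, columns right), filling
#' exposed pixels; integer shifts are exact. Emulates beam-center jitter.
#'
#' @inheritParams random_rotation
#' @param dr,dc Shift in pixels along rows and columns.
#' @return Shifted image.
#' @export
random_shift <- function(image, dr, dc, fill = 0,
                         interp = c("bilinear", "nearest")) {
  if (dr == 0 && dc == 0) return(image)
  affine_resample(image, diag(2), t = c(-dr, -dc), fill = fill,
                  interp = match.arg(interp))
}

#' Augmentation configuration
#'
#' Parameter ranges for the four augmentation strategies. Each augmented
#' copy draws a rotation angle, a masked-area fraction (realized as one
#' square block), a zoom factor and a shift uniformly from these ranges.
#'
#' @param rotation_range Degrees, `c(min, max)`.
#' @param mask_fraction_range Fraction of image area to mask, in `[0, 1]`.
#' @param zoom_range Zoom factors (> 0).
#' @param shift_range Pixels, applied independently to rows and columns.
#' @param fill_value Fill for exposed/masked pixels.
#' @return An object of class `speckle_augment_config`.
#' @export
augment_config <- function(rotation_range = c(-180, 180),
                           mask_fraction_range = c(0, 0.1),
                           zoom_range = c(0.9, 1.1),
                           shift_range = c(-5, 5),
                           fill_value = 0) {
  stopifnot(rotation_range[1] <= rotation_range[2],
            mask_fraction_range[1] >= 0, mask_fraction_range[2] <= 1,
            mask_fraction_range[1] <= mask_fraction_range[2],
            all(zoom_range > 0), zoom_range[1] <= zoom_range[2],
            shift_range[1] <= shift_range[2])
  structure(list(rotation_range = rotation_range,
                 mask_fraction_range = mask_fraction_range,
                 zoom_range = zoom_range,
                 shift_range = shift_range,
                 fill_value = fill_value),
            class = "speckle_augment_config")
}

# One random augmented copy of an image: rotation, masking, zoom, shift.
augment_image <- function(image, config, seed) {
  with_seed(seed, {
    ang <- stats::runif(1, config$rotation_range[1], config$rotation_range[2])
    frac <- stats::runif(1, config$mask_fraction_range[1],
                         config$mask_fraction_range[2])
    zf <- stats::runif(1, config$zoom_range[1], config$zoom_range[2])
    sh <- round(stats::runif(2, config$shift_range[1], config$shift_range[2]))
    img <- random_rotation(image, ang, fill = config$fill_value)
    side <- round(sqrt(frac * length(image)))
    if (side >= 1) {
      img <- random_masking(img, 1L, c(side, side), fill = config$fill_value,
                            seed = sample.int(.Machine$integer.max, 1L))
    }
    img <- random_zoom(img, zf, fill = config$fill_value)
    random_shift(img, sh[1], sh[2], fill = config$fill_value)
  })
}

#' Split a dataset, then augment each partition
#'
#' Source patterns are partitioned into train/validation/test first
#' (stratified by label, floor-plus-largest-remainder rounding); augmented
#' copies are generated afterwards and inherit the partition of their
#' source, so no information leaks across partitions through augmentation.
#'
#' @param data Pattern tibble of source (un-augmented) patterns.
#' @param fractions Named numeric vector summing to 1, e.g.
#'   `c(train = 0.5, val = 0.25, test = 0.25)`.
#' @param config An [augment_config()].
#' @param n_augment_per_source Augmented copies per source pattern (0 for a
#'   plain split).
#' @param seed Master seed.
#' @param augment_partitions Partitions that receive augmented copies
#'   (default all with positive fraction).
#' @return A named list of tibbles, one per partition, each carrying the
#'   `partition` column; augmented rows have `is_augmented = TRUE` and the
#'   `source_id` of their parent.
#' @export
split_then_augment <- function(data, fractions = c(train = 0.5, val = 0.25,
                                                   test = 0.25),
                               config = augment_config(),
                               n_augment_per_source = 0L,
                               seed = 1L,
                               augment_partitions = NULL) {
  if (nrow(data) == 0L) stop("dataset is empty")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(names(fractions)) || any(names(fractions) == "")) {
    stop("fractions must be named")
  }
  if (any(data$is_augmented)) {
    stop("split_then_augment expects un-augmented source patterns")
  }
  parts <- names(fractions)
  data$partition <- NA_character_
  # stratified assignment of sources
  for (cls in unique(data$label)) {
    idx <- which(data$label == cls)
    idx <- with_seed(derive_seed(seed, "split", cls), sample(idx))
    n <- length(idx)
    base <- floor(fractions * n)
    rem <- n - sum(base)
    if (rem > 0L) {
      extra <- order(fractions * n - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    assign_part <- rep(parts, times = base)
    data$partition[idx] <- assign_part
    missing_cls <- parts[fractions > 0 & base == 0]
    if (length(missing_cls) > 0L) {
      stop("class '", cls, "' has no patterns in partition(s): ",
           paste(missing_cls, collapse = ", "))
    }
  }
  augment_partitions <- augment_partitions %||% parts[fractions > 0]

  out <- lapply(parts, function(pt) {
    sub <- data[data$partition == pt, , drop = FALSE]
    if (n_augment_per_source > 0L && pt %in% augment_partitions &&
        nrow(sub) > 0L) {
      aug <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
        row <- sub[i, , drop = FALSE]
        purrr::map_dfr(seq_len(n_augment_per_source), function(k) {
          a <- row
          a$image <- list(augment_image(
            row$image[[1]], config,
            derive_seed(seed, "aug", row$source_id, k)))
          a$is_augmented <- TRUE
          a
        })
      })
      sub <- dplyr::bind_rows(sub, aug)
    }
    sub
  })
  names(out) <- parts
  audit_split(out)
  out
}

#' Audit a split for augmentation leakage
#'
#' Verifies that no `source_id` appears in more than one partition and that
#' every augmented pattern sits in the same partition as its un-augmented
#' source. Errors on the first violation.
#'
#' @param splits Named list of pattern tibbles (as returned by
#'   [split_then_augment()]), or a single tibble with a `partition` column.
#' @return `TRUE` invisibly if the split is leakage-free.
#' @export
audit_split <- function(splits) {
  if (is.data.frame(splits)) {
    splits <- split(splits, splits$partition)
  }
  all <- dplyr::bind_rows(purrr::imap(splits, function(d, nm) {
    d$partition <- nm
    d
  }))
  by_src <- tapply(all$partition, all$source_id,
                   function(p) length(unique(p)))
  bad <- names(by_src)[by_src > 1L]
  if (length(bad) > 0L) {
    stop("data leakage: source_id(s) present in multiple partitions: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  src_part <- all$partition[!all$is_augmented]
  names(src_part) <- all$source_id[!all$is_augmented]
  aug <- all[all$is_augmented, , drop = FALSE]
  mismatch <- aug$partition != src_part[aug$source_id]
  if (any(is.na(mismatch) | mismatch)) {
    stop("data leakage: augmented pattern(s) split from their source: ",
         paste(utils::head(aug$source_id[is.na(mismatch) | mismatch], 5L),
               collapse = ", "))
  }
  invisible(TRUE)
}
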