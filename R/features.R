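#' Gray-level bin boundaries for the bounded-histogram partition
#'
#' The 8-bit intensity range \[0, 255\] is tiled by eight contiguous bins of
#' 32 gray levels each: \[0, 31\], \[32, 63\], ..., \[224, 255\]. Both feature
#' classes (CHi and Ci) count bin occupancy over this partition, so the bins
#' are inclusive at both ends and neither overlap nor leave gaps.
#'
#' @return A data frame with columns `bin` (1..8), `lower` and `upper`
#'   (inclusive gray-level bounds).
#' @export
#' @examples
#' intensity_bins()
intensity_bins <- function() {
  data.frame(bin = 1:8, lower = 32L * (0:7), upper = 32L * (1:8) - 1L)
}

#' Construct a lesion sample (image + binary mask + label)
#'
#' Bundles one grayscale ultrasound image, its binary ground-truth lesion
#' mask and the class label into a validated `lesion_sample` object. The
#' label coding follows the dataset convention: 0 = malignant, 1 = benign.
#'
#' @param image Integer matrix of intensities in \[0, 255\].
#' @param mask Matrix of the same dimensions with entries in \{0, 1\} (a
#'   0/255-coded mask is accepted and binarized).
#' @param label Class label, 0 (malignant) or 1 (benign).
#' @param sample_id Optional identifier carried through to feature records.
#' @return An object of class `lesion_sample` with elements `image`, `mask`,
#'   `label` and `sample_id`.
#' @export
lesion_sample <- function(image, mask, label, sample_id = NA_character_) {
  image <- as.matrix(image)
  mask <- as.matrix(mask)
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask dimensions differ (",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"), ")")
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    stop("image intensities must be finite and within [0, 255]")
  }
  if (any(image != round(image))) {
    stop("image intensities must be integer gray levels")
  }
  if (!all(mask %in% c(0, 1))) mask <- binarize_mask(mask)
  if (sum(mask) < 1) stop("empty lesion: mask has no nonzero cell")
  if (!label %in% c(0, 1)) stop("label must be 0 (malignant) or 1 (benign)")
  structure(
    list(image = image, mask = mask, label = as.integer(label),
         sample_id = sample_id),
    class = "lesion_sample"
  )
}

#' Binarize a stored mask image
#'
#' Ground-truth masks are commonly stored as 8-bit images with lesion pixels
#' at 255; any nonzero pixel (including anti-aliased boundary values) counts
#' as lesion.
#'
#' @param raw_mask Numeric matrix with values in \[0, 255\].
#' @return Integer matrix of \{0, 1\} with the same dimensions.
#' @export
binarize_mask <- function(raw_mask) {
  raw_mask <- as.matrix(raw_mask)
  if (length(raw_mask) == 0) stop("raw_mask is empty")
  out <- (raw_mask > 0) * 1L
  if (sum(out) == 0) stop("empty lesion: mask has no nonzero cell")
  dim(out) <- dim(raw_mask)
  out
}

#' Overlay the mask onto the image to obtain the region of interest
#'
#' The ROI is the elementwise product of image and mask: lesion pixels keep
#' their gray value, background pixels are forced to 0. The mask area S is
#' the number of lesion pixels.
#'
#' @param sample A [lesion_sample()].
#' @return A list of class `roi_image` with `values` (masked image), `S`
#'   (lesion area in pixels) and `mask` (kept because an in-mask pixel of
#'   gray value 0 is indistinguishable from background in `values` alone).
#' @export
make_roi <- function(sample) {
  stopifnot(inherits(sample, "lesion_sample"))
  structure(
    list(values = sample$image * sample$mask, S = sum(sample$mask),
         mask = sample$mask),
    class = "roi_image"
  )
}

#' Full-frame normalized intensity histogram
#'
#' h(i) is the fraction of all M*N image cells equal to gray level i,
#' i = 0..255. Because every cell falls in exactly one level the histogram
#' sums to 1 exactly. Applied to a masked image, the background zeros all
#' land in level 0.
#'
#' @param roi A `roi_image` (or any integer matrix in \[0, 255\]).
#' @return Object of class `intensity_histogram`: list with `h` (256
#'   fractions, named "0".."255"), `counts` (integer tallies) and
#'   `normalizer` (M*N). The integer counts are kept so downstream bin sums
#'   can be formed in integer arithmetic and divided once.
#' @export
normalized_histogram <- function(roi) {
  values <- if (inherits(roi, "roi_image")) roi$values else as.matrix(roi)
  mn <- length(values)
  stopifnot(mn >= 1)
  counts <- tabulate(as.integer(values) + 1L, nbins = 256L)
  structure(
    list(h = stats::setNames(counts / mn, 0:255), counts = counts,
         normalizer = mn),
    class = "intensity_histogram"
  )
}

#' Bounded-histogram features CH1..CH8
#'
#' CHk sums the normalized histogram over the k-th 32-level bin, so CHk is
#' the fraction of all image cells whose gray value lies in that bin. The
#' eight bins partition \[0, 255\], hence sum(CH) = 1.
#'
#' @param h An `intensity_histogram`, or a plain 256-vector of fractions.
#' @return Named numeric vector CH1..CH8. For an `intensity_histogram` the
#'   bin sums are formed over the integer counts and divided once by M*N,
#'   which keeps the count identities with the Ci class exact.
#' @export
bounded_histogram_features <- function(h) {
  bin <- rep(1:8, each = 32)
  if (inherits(h, "intensity_histogram")) {
    ch <- as.vector(rowsum(h$counts, bin)) / h$normalizer
  } else {
    stopifnot(length(h) == 256)
    ch <- as.vector(rowsum(as.numeric(h), bin))
  }
  stats::setNames(ch, paste0("CH", 1:8))
}

#' Grayscale-density features C1..C8
#'
#' Ck is the fraction of in-mask (lesion) pixels whose gray value lies in
#' the k-th 32-level bin, i.e. the area of the bin's pixel set divided by
#' the ground-truth lesion area S. sum(C) = 1.
#'
#' @param roi A `roi_image` from [make_roi()], or a plain matrix together
#'   with `mask`.
#' @param mask Binary matrix marking lesion pixels; defaults to the mask
#'   stored in `roi`.
#' @return Named numeric vector C1..C8.
#' @export
grayscale_density_features <- function(roi, mask = NULL) {
  if (inherits(roi, "roi_image")) {
    values <- roi$values
    if (is.null(mask)) mask <- roi$mask
  } else {
    values <- as.matrix(roi)
    if (is.null(mask)) stop("mask is required when roi is a plain matrix")
  }
  mask <- as.matrix(mask)
  stopifnot(all(dim(values) == dim(mask)))
  inside <- as.integer(values[mask == 1])
  s <- length(inside)
  if (s < 1) stop("empty lesion: mask has no nonzero cell")
  counts <- tabulate(inside %/% 32L + 1L, nbins = 8L)
  stats::setNames(counts / s, paste0("C", 1:8))
}

#' Extract the 16-feature record from one lesion sample
#'
#' Composes mask overlay, full-frame histogram and the two bin-occupancy
#' feature classes. CHi is normalized by the full frame (background zeros
#' fall in bin 1) while Ci is normalized by the lesion area, which makes the
#' two classes correlated through the shared bin counts but not identical:
#' for bins 2..8, CHk * M * N = Ck * S exactly.
#'
#' @param sample A [lesion_sample()].
#' @return A one-row data frame with columns `sample_id`, `CH1`..`CH8`,
#'   `C1`..`C8`, `label`.
#' @export
#' @examples
#' img <- matrix(0L, 4, 4); img[1:2, 1:4] <- 160L
#' msk <- matrix(0L, 4, 4); msk[1:2, 1:4] <- 1L
#' extract_features(lesion_sample(img, msk, label = 1))
extract_features <- function(sample) {
  stopifnot(inherits(sample, "lesion_sample"))
  roi <- make_roi(sample)
  ch <- bounded_histogram_features(normalized_histogram(roi))
  cd <- grayscale_density_features(roi, sample$mask)
  out <- data.frame(sample_id = sample$sample_id, as.list(ch), as.list(cd),
                    label = sample$label, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract features for a list of lesion samples
#'
#' @param samples List of [lesion_sample()] objects.
#' @return Data frame with one row per sample (columns as in
#'   [extract_features()]).
#' @export
extract_features_batch <- function(samples) {
  stopifnot(length(samples) >= 1)
  out <- do.call(rbind, lapply(samples, extract_features))
  rownames(out) <- NULL
  out
}

#' Names of the feature columns for a feature class
#'
#' @param feature_class One of `"chi"`, `"ci"`, `"both"`.
#' @return Character vector of column names.
#' @export
feature_class_columns <- function(feature_class = c("chi", "ci", "both")) {
  feature_class <- match.arg(feature_class)
  switch(feature_class,
         chi = paste0("CH", 1:8),
         ci = paste0("C", 1:8),
         both = c(paste0("CH", 1:8), paste0("C", 1:8)))
}
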