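# Interchange formats: feature CSV (sample_id,CH1..CH8,C1..C8,label) and
# image/mask directory layouts. CSV dialect is fixed: comma delimiter,
# period decimals, UTF-8, LF.

.feature_header <- function() {
  c("sample_id", paste0("CH", 1:8), paste0("C", 1:8), "label")
}

#' Write a feature table to CSV
#'
#' @param records Data frame with columns `sample_id`, `CH1`..`CH8`,
#'   `C1`..`C8`, `label`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature_csv <- function(records, path) {
  miss <- setdiff(.feature_header(), names(records))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  records <- records[, .feature_header()]
  num <- setdiff(.feature_header(), c("sample_id", "label"))
  for (cn in num) records[[cn]] <- formatC(records[[cn]], digits = 15, format = "g")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.feature_header(), collapse = ","), con, sep = "\n")
  apply_rows <- do.call(paste, c(unname(records), list(sep = ",")))
  writeLines(apply_rows, con, sep = "\n")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Validates the exact header, numeric cells, label coding (0 = malignant,
#' 1 = benign) and — as a soft audit — the partition identities sum(CH) = 1
#' and sum(C) = 1; rows violating the identities beyond `1e-9` are kept but
#' reported with a warning.
#'
#' @param path CSV path.
#' @return Data frame of feature records.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("feature CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df), .feature_header())) {
    stop("malformed feature CSV header; expected ",
         paste(.feature_header(), collapse = ","))
  }
  num <- setdiff(.feature_header(), c("sample_id", "label"))
  for (cn in num) {
    if (!is.numeric(df[[cn]])) stop("non-numeric cells in column ", cn)
  }
  bad_label <- which(!df$label %in% c(0, 1))
  if (length(bad_label)) {
    stop("labels outside {0,1} at row(s) ", paste(bad_label, collapse = ", "))
  }
  ch_dev <- abs(rowSums(df[, paste0("CH", 1:8)]) - 1)
  c_dev <- abs(rowSums(df[, paste0("C", 1:8)]) - 1)
  off <- which(ch_dev > 1e-9 | c_dev > 1e-9)
  if (length(off)) {
    warning("rows with bin sums deviating from 1: ",
            paste(utils::head(off, 10), collapse = ", "))
  }
  df$label <- as.integer(df$label)
  df
}

# read one grayscale 8-bit image; 3-channel inputs are collapsed by the
# Rec. 601 luma weights then rounded back to 8-bit
.read_gray8 <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(arr)) == 3) {
    k <- dim(arr)[3]
    arr <- if (k >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  .clip255(arr * 255)
}

#' Read one image/mask pair as a lesion sample
#'
#' Several mask files for the same image (multi-lesion cases) are combined
#' by union before binarization.
#'
#' @param image_path Path to the grayscale lesion image (PNG or TIFF).
#' @param mask_paths One or more mask image paths.
#' @param label 0 (malignant) or 1 (benign).
#' @param sample_id Identifier; defaults to the image file stem.
#' @return A [lesion_sample()].
#' @export
read_lesion_pair <- function(image_path, mask_paths, label,
                             sample_id = NULL) {
  img <- .read_gray8(image_path)
  masks <- lapply(mask_paths, .read_gray8)
  for (m in masks) {
    if (!all(dim(m) == dim(img))) {
      stop("mask dimensions differ from image for ", image_path)
    }
  }
  union_mask <- Reduce(`+`, masks)
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(image_path))
  }
  lesion_sample(img, binarize_mask(union_mask), label, sample_id = sample_id)
}

#' Read a lesion image directory
#'
#' Two dialects are accepted. With a `manifest.csv` (columns `image_path`,
#' `mask_path`, `label`; paths relative to `dir`), the manifest wins. Without
#' one, the directory is scanned for class subfolders `benign/` and
#' `malignant/` holding `<stem>.png` images paired with `<stem>_mask.png`
#' (plus optional `<stem>_mask_1.png`, ... for multi-lesion cases); a
#' `normal/` subfolder, if present, is skipped.
#'
#' @param dir Directory path.
#' @param manifest Optional explicit manifest CSV path.
#' @return List of [lesion_sample()] objects.
#' @export
read_lesion_dir <- function(dir, manifest = NULL) {
  if (is.null(manifest)) {
    cand <- file.path(dir, "manifest.csv")
    if (file.exists(cand)) manifest <- cand
  }
  if (!is.null(manifest)) {
    mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("image_path", "mask_path", "label")
    if (!all(need %in% names(mf))) {
      stop("manifest must have columns ", paste(need, collapse = ", "))
    }
    return(lapply(seq_len(nrow(mf)), function(i) {
      read_lesion_pair(file.path(dir, mf$image_path[i]),
                       strsplit(mf$mask_path[i], ";")[[1]] |>
                         (\(p) file.path(dir, p))(),
                       mf$label[i])
    }))
  }
  out <- list()
  for (cls in c("malignant", "benign")) {
    sub <- file.path(dir, cls)
    if (!dir.exists(sub)) next
    files <- list.files(sub, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
    stems <- files[!grepl("_mask(_[0-9]+)?\\.[^.]+$", files)]
    for (f in stems) {
      stem <- tools::file_path_sans_ext(f)
      ext <- tools::file_ext(f)
      masks <- list.files(sub, pattern = paste0("^", stem, "_mask(_[0-9]+)?\\.",
                                                ext, "$"))
      if (!length(masks)) stop("no mask found for image ", file.path(sub, f))
      out[[length(out) + 1]] <- read_lesion_pair(
        file.path(sub, f), file.path(sub, masks),
        label = if (cls == "malignant") 0L else 1L)
    }
  }
  if (!length(out)) stop("no image/mask pairs found under ", dir)
  out
}
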