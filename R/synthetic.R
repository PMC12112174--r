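# Synthetic ultrasound-like lesion images. These are fixture-engineering
# constructs (no physical speckle model): what matters downstream is the
# gray-bin occupancy contrast between classes, not speckle statistics.

#' Parameters of the synthetic lesion generator
#'
#' Defines the emulated imaging conditions: an 8-bit speckled background,
#' benign lesions as smooth dark ellipses (hypoechoic interior around gray
#' level 70, i.e. bin 3), malignant lesions as spiculated star-convex shapes
#' with a brighter, more heterogeneous interior and sparse near-white
#' microcalcification spots (gray >= 224, bin 8). The defaults are the
#' generator's fixed study conditions; see the package vignette for the
#' rationale behind each value.
#'
#' @param image_size Integer (rows, cols), default `c(128, 128)`.
#' @param class_label 0 (malignant) or 1 (benign).
#' @param benign_intensity_band `c(mean, sd)` of benign interior gray levels.
#' @param malignant_intensity_band `c(mean, sd)` of malignant interiors.
#' @param spiculation_amplitude Radial boundary perturbation as a fraction of
#'   the base radius; 0 for benign, 0.35 for malignant.
#' @param calcification_rate Expected number of bright (>= 224) spots per
#'   malignant lesion (Poisson).
#' @param background_band `c(mean, sd)` of the background speckle.
#' @param radius_range Base lesion radius as a fraction of the smaller image
#'   dimension, drawn uniformly from this range.
#' @return A list of class `synthetic_lesion_spec`.
#' @export
synthetic_lesion_spec <- function(image_size = c(128L, 128L),
                                  class_label = 1L,
                                  benign_intensity_band = c(70, 12),
                                  malignant_intensity_band = c(120, 25),
                                  spiculation_amplitude = if (class_label == 0) 0.35 else 0,
                                  calcification_rate = 6,
                                  background_band = c(40, 10),
                                  radius_range = c(0.15, 0.28)) {
  stopifnot(length(image_size) == 2, all(image_size >= 16),
            class_label %in% c(0, 1),
            benign_intensity_band[2] >= 0, malignant_intensity_band[2] >= 0,
            spiculation_amplitude >= 0, spiculation_amplitude < 1,
            calcification_rate >= 0, background_band[2] >= 0,
            radius_range[1] > 0, radius_range[2] >= radius_range[1])
  structure(list(
    image_size = as.integer(image_size),
    class_label = as.integer(class_label),
    benign_intensity_band = benign_intensity_band,
    malignant_intensity_band = malignant_intensity_band,
    spiculation_amplitude = spiculation_amplitude,
    calcification_rate = calcification_rate,
    background_band = background_band,
    radius_range = radius_range
  ), class = "synthetic_lesion_spec")
}

# clipped-Gaussian 8-bit draw
.clip255 <- function(x) pmin(pmax(round(x), 0), 255)

#' Generate one synthetic lesion sample
#'
#' Benign masks are smooth ellipses; malignant masks are star-convex shapes
#' whose boundary radius r(theta) = r0 * (1 + a * P(theta)) is perturbed by a
#' low-order random harmonic sum P (3-8 harmonics, random phases, normalised
#' to unit peak), producing spiculated but non-self-intersecting outlines.
#' Interior and background intensities are clipped Gaussians from the class
#' bands; malignant lesions additionally receive Poisson-many small bright
#' discs emulating microcalcifications. If the lesion area falls below 1% of
#' the frame the shape is regrown with an enlarged radius (at most 10 tries).
#'
#' @param spec A [synthetic_lesion_spec()].
#' @param seed Integer seed; the same seed reproduces the sample bit for bit.
#' @param sample_id Identifier stored on the sample.
#' @return A [lesion_sample()].
#' @export
generate_lesion <- function(spec = synthetic_lesion_spec(), seed = 1L,
                            sample_id = NA_character_) {
  stopifnot(inherits(spec, "synthetic_lesion_spec"))
  set.seed(as.integer(seed))
  M <- spec$image_size[1]; N <- spec$image_size[2]
  min_area <- ceiling(0.01 * M * N)

  r0 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2]) * min(M, N)
  mask <- NULL
  for (attempt in 1:10) {
    cx <- M / 2 + stats::runif(1, -0.08, 0.08) * M
    cy <- N / 2 + stats::runif(1, -0.08, 0.08) * N
    rows <- matrix(seq_len(M), M, N) - cx
    cols <- matrix(seq_len(N), M, N, byrow = TRUE) - cy
    if (spec$spiculation_amplitude > 0) {
      K <- sample(3:8, 1)
      amp <- stats::runif(K); phase <- stats::runif(K, 0, 2 * pi)
      theta <- atan2(cols, rows)
      pert <- matrix(0, M, N)
      for (k in seq_len(K)) pert <- pert + amp[k] * cos(k * theta + phase[k])
      pert <- pert / max(abs(range(pert)), 1e-12)
      rtheta <- r0 * (1 + spec$spiculation_amplitude * pert)
      cand <- (sqrt(rows^2 + cols^2) <= rtheta) * 1L
    } else {
      b <- r0 * stats::runif(1, 0.6, 1)
      ang <- stats::runif(1, 0, pi)
      u <- rows * cos(ang) + cols * sin(ang)
      v <- -rows * sin(ang) + cols * cos(ang)
      cand <- ((u / r0)^2 + (v / b)^2 <= 1) * 1L
    }
    dim(cand) <- c(M, N)
    if (sum(cand) >= min_area) { mask <- cand; break }
    r0 <- r0 * 1.3
  }
  if (is.null(mask)) stop("lesion degenerated below minimum area after 10 attempts")

  band <- if (spec$class_label == 0) spec$malignant_intensity_band else spec$benign_intensity_band
  img <- matrix(stats::rnorm(M * N, spec$background_band[1], spec$background_band[2]), M, N)
  inside <- mask == 1
  img[inside] <- stats::rnorm(sum(inside), band[1], band[2])

  if (spec$class_label == 0 && spec$calcification_rate > 0) {
    n_calc <- stats::rpois(1, spec$calcification_rate)
    if (n_calc > 0) {
      idx <- which(inside)
      # rejection placement with a minimum separation keeps the spots
      # distinct instead of merging into one bright blob
      centers <- integer(0)
      for (cc in seq_len(min(n_calc, length(idx)))) {
        for (try_ in 1:30) {
          cand <- idx[sample.int(length(idx), 1)]
          if (!length(centers)) { ok <- TRUE } else {
            dr <- (cand - 1) %% M - (centers - 1) %% M
            dc <- (cand - 1) %/% M - (centers - 1) %/% M
            ok <- all(dr^2 + dc^2 > 36)
          }
          if (ok) { centers <- c(centers, cand); break }
        }
      }
      rowc <- (centers - 1) %% M + 1
      colc <- (centers - 1) %/% M + 1
      for (s in seq_along(centers)) {
        rad <- sample(1:2, 1)
        lum <- stats::runif(1, 224, 255)
        rr <- pmax(1, rowc[s] - rad):pmin(M, rowc[s] + rad)
        cc <- pmax(1, colc[s] - rad):pmin(N, colc[s] + rad)
        for (i in rr) for (j in cc) {
          if (mask[i, j] == 1 && (i - rowc[s])^2 + (j - colc[s])^2 <= rad^2) {
            img[i, j] <- lum
          }
        }
      }
    }
  }

  lesion_sample(.clip255(img), mask, spec$class_label, sample_id = sample_id)
}

#' Generate a seeded cohort of synthetic lesion samples
#'
#' Per-sample seeds are drawn deterministically from the cohort seed, so the
#' cohort is reproducible as a whole while samples stay independent. The
#' returned sample order is shuffled. The default class sizes mirror the
#' 211 malignant / 438 benign composition of the public breast-ultrasound
#' image collection the feature method was developed on.
#'
#' @param n_malignant,n_benign Class sizes.
#' @param seed Cohort seed.
#' @param malignant_spec,benign_spec Per-class [synthetic_lesion_spec()]s.
#' @return A list of class `synthetic_cohort` with `samples` (list of
#'   [lesion_sample()]), `class_counts` and `seed`.
#' @export
generate_cohort <- function(n_malignant = 211L, n_benign = 438L, seed = 1L,
                            malignant_spec = synthetic_lesion_spec(class_label = 0L),
                            benign_spec = synthetic_lesion_spec(class_label = 1L)) {
  stopifnot(n_malignant >= 0, n_benign >= 0, n_malignant + n_benign >= 1)
  set.seed(as.integer(seed))
  n <- n_malignant + n_benign
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  order_idx <- sample.int(n)
  labels <- rep(c(0L, 1L), c(n_malignant, n_benign))
  ids <- c(sprintf("mal_%04d", seq_len(n_malignant)),
           sprintf("ben_%04d", seq_len(n_benign)))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    spc <- if (labels[i] == 0) malignant_spec else benign_spec
    samples[[i]] <- generate_lesion(spc, seed = sub_seeds[i], sample_id = ids[i])
  }
  structure(list(samples = samples[order_idx],
                 class_counts = c(n_malignant = n_malignant, n_benign = n_benign),
                 seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' Write a cohort to disk as image/mask PNG pairs plus a manifest
#'
#' Uses the `<class>/<stem>.png` + `<stem>_mask.png` layout with a
#' `manifest.csv` (columns `image_path,mask_path,label`) so the written tree
#' can be re-read by [read_lesion_dir()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  for (d in file.path(dir, c("malignant", "benign"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  rows <- lapply(cohort$samples, function(s) {
    sub <- if (s$label == 0) "malignant" else "benign"
    ip <- file.path(sub, paste0(s$sample_id, ".png"))
    mp <- file.path(sub, paste0(s$sample_id, "_mask.png"))
    png::writePNG(s$image / 255, file.path(dir, ip))
    png::writePNG(s$mask * 1.0, file.path(dir, mp))
    data.frame(image_path = ip, mask_path = mp, label = s$label)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
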