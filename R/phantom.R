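# Synthetic CT-like phantom generator. Emulates, at desk scale, abdominal
# slices with a bright organ parenchyma, darker tumour-like blobs (the
# segmentation targets) and bright vessel-like tubular confounders that are
# deliberately excluded from the ground-truth mask.

#' Specification of a synthetic phantom
#'
#' Describes the geometry and intensity statistics of a 2-D CT-like phantom:
#' an elliptical organ on a dark background, a random number of darker
#' circular tumour blobs inside the organ, and bright tubular vessel
#' confounders which are never part of the ground-truth mask. All intensities
#' are on the normalized `[0, 1]` scale.
#'
#' @param height,width Image size in pixels.
#' @param organ_center Organ ellipse centre as fractions of (height, width).
#' @param organ_axes Organ ellipse semi-axes as fractions of (height, width).
#' @param organ_intensity_mean,organ_intensity_sd Parenchyma intensity; the
#'   mean is jittered per phantom by a normal draw with this sd.
#' @param tumor_count_range Integer interval `c(min, max)` for the number of
#'   tumour blobs.
#' @param tumor_radius_range Tumour radius interval in pixels.
#' @param tumor_intensity_mean,tumor_intensity_sd Tumour intensity (darker
#'   than parenchyma by convention, so instance-dependent noise has a
#'   well-defined intensity cue).
#' @param vessel_count Number of bright tubular confounders.
#' @param vessel_intensity Vessel intensity (brighter than parenchyma).
#' @param background_intensity Background level.
#' @param noise_sd Additive Gaussian acquisition noise, intensity units.
#' @param seed Default seed used when [generate_phantom()] is called without
#'   one.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64,
                         organ_center = c(0.5, 0.5),
                         organ_axes = c(0.42, 0.38),
                         organ_intensity_mean = 0.55,
                         organ_intensity_sd = 0.02,
                         tumor_count_range = c(1, 3),
                         tumor_radius_range = c(4, 7),
                         tumor_intensity_mean = 0.30,
                         tumor_intensity_sd = 0.02,
                         vessel_count = 2,
                         vessel_intensity = 0.85,
                         background_intensity = 0.12,
                         noise_sd = 0.03,
                         seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               organ_center = organ_center, organ_axes = organ_axes,
               organ_intensity_mean = organ_intensity_mean,
               organ_intensity_sd = organ_intensity_sd,
               tumor_count_range = as.integer(round(tumor_count_range)),
               tumor_radius_range = tumor_radius_range,
               tumor_intensity_mean = tumor_intensity_mean,
               tumor_intensity_sd = tumor_intensity_sd,
               vessel_count = as.integer(vessel_count),
               vessel_intensity = vessel_intensity,
               background_intensity = background_intensity,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  ints <- c(spec$organ_intensity_mean, spec$tumor_intensity_mean,
            spec$vessel_intensity, spec$background_intensity)
  if (any(ints < 0) || any(ints > 1)) {
    stop("all intensity parameters must lie in [0, 1]", call. = FALSE)
  }
  if (any(spec$tumor_radius_range <= 0)) {
    stop("tumour radii must be positive", call. = FALSE)
  }
  if (any(spec$tumor_count_range < 0) || spec$vessel_count < 0) {
    stop("count ranges must be non-negative", call. = FALSE)
  }
  if (diff(spec$tumor_count_range) < 0 || diff(spec$tumor_radius_range) < 0) {
    stop("ranges must be ordered c(min, max)", call. = FALSE)
  }
  ax_px <- spec$organ_axes * c(spec$height, spec$width)
  if (max(spec$tumor_radius_range) >= min(ax_px)) {
    stop("tumour radius exceeds the organ semi-axes; reduce tumor_radius_range",
         call. = FALSE)
  }
  invisible(spec)
}

#' Construct an image sample
#'
#' Bundles an image with its mask and a purity tag. Clean samples carry the
#' accurate ground-truth mask; noisy samples carry a corrupted mask together
#' with a log of the corruption steps that produced it.
#'
#' @param id Sample identifier.
#' @param image Numeric matrix of intensities in `[0, 1]`.
#' @param mask Binary matrix (0/1), same shape as `image`.
#' @param purity `"clean"` or `"noisy"`.
#' @param corruption_log Character vector describing applied corruption;
#'   must be empty for clean samples.
#' @param meta Optional list of provenance (e.g. the vessel region).
#' @return An object of class `image_sample`.
#' @export
image_sample <- function(id, image, mask, purity = c("clean", "noisy"),
                         corruption_log = character(0), meta = list()) {
  purity <- match.arg(purity)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  assert_binary_mask(mask)
  assert_same_shape(image, mask, c("image", "mask"))
  if (purity == "clean" && length(corruption_log) > 0) {
    stop("clean samples must have an empty corruption_log", call. = FALSE)
  }
  structure(list(id = as.character(id), image = image, mask = mask,
                 purity = purity, corruption_log = corruption_log,
                 meta = meta),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("<image_sample> id=%s  %dx%d  purity=%s  fg=%d px%s\n",
              x$id, nrow(x$image), ncol(x$image), x$purity, sum(x$mask),
              if (length(x$corruption_log))
                paste0("  [", paste(x$corruption_log, collapse = "; "), "]")
              else ""))
  invisible(x)
}

# Rasterize a filled ellipse; cy/cx/ay/ax in pixel units (1-based centres).
ellipse_mask <- function(H, W, cy, cx, ay, ax) {
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((i - cy) / ay)^2 + ((j - cx) / ax)^2 <= 1
}

disc_mask <- function(H, W, cy, cx, r) {
  ellipse_mask(H, W, cy, cx, r, r)
}

# Paint a thick line segment; returns a logical matrix.
segment_mask <- function(H, W, y0, x0, y1, x1, thickness) {
  len <- max(abs(y1 - y0), abs(x1 - x0), 1)
  t <- seq(0, 1, length.out = ceiling(len) * 2 + 1)
  ys <- y0 + t * (y1 - y0)
  xs <- x0 + t * (x1 - x0)
  out <- matrix(FALSE, H, W)
  r <- max(0.5, thickness / 2)
  for (k in seq_along(t)) {
    i0 <- max(1L, floor(ys[k] - r)); i1 <- min(H, ceiling(ys[k] + r))
    j0 <- max(1L, floor(xs[k] - r)); j1 <- min(W, ceiling(xs[k] + r))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - ys[k])^2, (jj - xs[k])^2, `+`)
    out[ii, jj] <- out[ii, jj] | (d2 <= r^2)
  }
  out
}

#' Generate one synthetic phantom with its ground-truth mask
#'
#' Draws an elliptical organ, a seeded number of non-overlapping darker
#' tumour blobs (the mask foreground), bright vessel-like confounders
#' (never in the mask), and additive Gaussian acquisition noise. The image
#' is quantized to the 8-bit grid at the end so that a PNG write/read
#' round-trips exactly. Identical `(spec, seed)` gives bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return An [image_sample()] with `purity = "clean"`. The vessel region is
#'   retained in `meta$vessel_mask`.
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  H <- spec$height; W <- spec$width
  with_seed(mix_seed(seed, 101L), {
    cy <- spec$organ_center[1] * H; cx <- spec$organ_center[2] * W
    ay <- spec$organ_axes[1] * H;   ax <- spec$organ_axes[2] * W
    organ <- ellipse_mask(H, W, cy, cx, ay, ax)

    img <- matrix(spec$background_intensity, H, W)
    organ_int <- clamp01(spec$organ_intensity_mean +
                           spec$organ_intensity_sd * rnorm(1))
    img[organ] <- organ_int

    # tumours: rejection-sampled, fully inside the organ, non-overlapping
    k <- if (diff(spec$tumor_count_range) == 0) spec$tumor_count_range[1]
         else sample(spec$tumor_count_range[1]:spec$tumor_count_range[2], 1)
    mask <- matrix(0, H, W)
    centres <- matrix(numeric(0), ncol = 3)  # cy, cx, r
    placed <- 0
    tries <- 0
    while (placed < k && tries < 2000) {
      tries <- tries + 1
      r <- runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
      u <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
      ty <- cy + rad * (ay - r - 1) * sin(u)
      tx <- cx + rad * (ax - r - 1) * cos(u)
      if (((ty - cy) / (ay - r - 1))^2 + ((tx - cx) / (ax - r - 1))^2 > 1) next
      ok <- TRUE
      if (nrow(centres) > 0) {
        d <- sqrt((centres[, 1] - ty)^2 + (centres[, 2] - tx)^2)
        ok <- all(d > centres[, 3] + r + 1)
      }
      if (!ok) next
      tint <- clamp01(spec$tumor_intensity_mean +
                        spec$tumor_intensity_sd * rnorm(1))
      blob <- disc_mask(H, W, ty, tx, r)
      img[blob] <- tint
      mask[blob] <- 1
      centres <- rbind(centres, c(ty, tx, r))
      placed <- placed + 1
    }
    if (placed < k) {
      stop("could not place non-overlapping tumours; spec too crowded",
           call. = FALSE)
    }

    # vessel confounders: bright thin tubes inside the organ, never in mask
    vessel <- matrix(FALSE, H, W)
    if (spec$vessel_count > 0) {
      for (v in seq_len(spec$vessel_count)) {
        u <- runif(1, 0, 2 * pi)
        y0 <- cy + 0.7 * ay * sin(u); x0 <- cx + 0.7 * ax * cos(u)
        u2 <- u + pi + runif(1, -0.8, 0.8)
        y1 <- cy + 0.7 * ay * sin(u2); x1 <- cx + 0.7 * ax * cos(u2)
        vessel <- vessel | segment_mask(H, W, y0, x0, y1, x1,
                                        thickness = runif(1, 1.2, 2.2))
      }
      vessel <- vessel & organ & mask == 0
      img[vessel] <- spec$vessel_intensity
    }

    img <- clamp01(img + spec$noise_sd * rnorm(H * W))
    img <- round(img * 255) / 255  # 8-bit grid: file round-trips are exact

    image_sample(id = sprintf("phantom_%d", seed), image = img, mask = mask,
                 purity = "clean",
                 meta = list(vessel_mask = vessel * 1, seed = seed))
  })
}

# ---- file I/O --------------------------------------------------------------

#' Write / read a grayscale grid
#'
#' PNG is the default interchange format (masks are stored as 0/255); a
#' single-slice NIfTI writer is provided for pipelines that expect medical
#' formats. `read_gray()` dispatches on the file extension.
#'
#' @param x Numeric matrix in `[0, 1]`.
#' @param path Output path; extension `.png` or `.nii`/`.nii.gz`.
#' @export
write_gray <- function(x, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(x), path)
  } else {
    png::writePNG(x, path)
  }
  invisible(path)
}

#' @rdname write_gray
#' @export
read_gray <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    x <- RNifti::readNifti(path)
    matrix(as.numeric(x), nrow = dim(x)[1], ncol = dim(x)[2])
  } else {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3) x <- x[, , 1]
    x
  }
}

#' Generate a dataset of phantoms with a controlled label-noise rate
#'
#' Writes `n` image/mask pairs under `out_dir`. A seeded subset of
#' `round(n * noise_rate)` samples has its mask replaced by a corrupted
#' version produced by `plan`; the accurate mask of every sample is always
#' written to a `_truth` sidecar, which is used for evaluation only and never
#' shown to training under `purity = "noisy"`.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of samples (>= 1).
#' @param noise_rate Fraction of samples receiving corrupted masks.
#' @param plan A [corruption_plan()]; defaults to
#'   [default_corruption_plan()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed controlling phantom content, the noisy subset
#'   and every corruption draw.
#' @param split Split tag written to the manifest.
#' @return A `dataset_manifest` data.frame with columns
#'   `id, image, mask, purity, split` (paths relative to `out_dir`), with
#'   attributes `dir` and `noise_rate`.
#' @export
generate_dataset <- function(spec, n, noise_rate, plan = default_corruption_plan(),
                             out_dir, seed = 1L, split = "train") {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (noise_rate < 0 || noise_rate > 1) {
    stop("`noise_rate` must lie in [0, 1]", call. = FALSE)
  }
  validate_corruption_plan(plan)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create `out_dir`", call. = FALSE)

  n_noisy <- round(n * noise_rate)
  noisy_idx <- if (n_noisy > 0) {
    with_seed(mix_seed(seed, 7L), sample(n, n_noisy))
  } else {
    integer(0)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_phantom(spec, seed = mix_seed(seed, 1000L + i))
    id <- sprintf("%s_%03d", split, i)
    img_p <- paste0(id, ".png")
    msk_p <- paste0(id, "_mask.png")
    truth_p <- paste0(id, "_mask_truth.png")
    write_gray(s$image, file.path(out_dir, img_p))
    write_gray(s$mask, file.path(out_dir, truth_p))
    purity <- "clean"
    if (i %in% noisy_idx) {
      corrupted <- apply_corruption_plan(s$mask, plan, image = s$image,
                                         seed = mix_seed(seed, 2000L + i))
      write_gray(corrupted, file.path(out_dir, msk_p))
      purity <- "noisy"
    } else {
      write_gray(s$mask, file.path(out_dir, msk_p))
    }
    rows[[i]] <- data.frame(id = id, image = img_p, mask = msk_p,
                            purity = purity, split = split,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, paste0("manifest_", split, ".csv")),
                   row.names = FALSE)
  attr(manifest, "dir") <- out_dir
  attr(manifest, "noise_rate") <- noise_rate
  class(manifest) <- c("dataset_manifest", "data.frame")
  manifest
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param path Path to a manifest CSV.
#' @return A `dataset_manifest` whose `dir` attribute points at the manifest's
#'   directory.
#' @export
read_manifest <- function(path) {
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "image", "mask", "purity", "split")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns id,image,mask,purity,split", call. = FALSE)
  }
  if (anyDuplicated(manifest$id)) stop("manifest ids must be unique", call. = FALSE)
  attr(manifest, "dir") <- dirname(path)
  attr(manifest, "noise_rate") <- mean(manifest$purity == "noisy")
  class(manifest) <- c("dataset_manifest", "data.frame")
  manifest
}

# Load every sample referenced by a manifest into memory. Returns a list of
# image_sample objects; truth masks come from the `_truth` sidecars.
load_samples <- function(manifest, with_truth = TRUE) {
  dir <- attr(manifest, "dir")
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img <- read_gray(file.path(dir, row$image))
    msk <- round(read_gray(file.path(dir, row$mask)))
    s <- image_sample(row$id, img, msk, purity = row$purity,
                      corruption_log = if (row$purity == "noisy") "from plan"
                                       else character(0))
    if (with_truth) {
      tp <- file.path(dir, sub("\\.png$", "_truth.png", row$mask))
      if (file.exists(tp)) s$meta$truth <- round(read_gray(tp))
    }
    s
  })
}
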