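# Label-noise simulators: class-level transition matrices (symmetric and
# asymmetric), per-pixel corruption fields (instance- and position-dependent
# flip probabilities), and structured clinical corruptions (misalignment,
# bleed into adjacent structures, inconsistent boundaries, random speckle,
# incomplete/cut-off labels). All operators are seeded and map binary masks
# to binary masks of the same shape.

#' Symmetric label-transition matrix
#'
#' Row-stochastic matrix with diagonal `1 - rho` and equal off-diagonals
#' `rho / (c - 1)`: every true class is flipped to any other class with the
#' same probability.
#'
#' @param rho Noise rate in `[0, 1]`.
#' @param c Number of classes (>= 2).
#' @return A `c x c` matrix of class `transition_matrix`.
#' @export
symmetric_transition <- function(rho, c = 2L) {
  if (!is.numeric(rho) || rho < 0 || rho > 1) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  if (c < 2) stop("`c` must be >= 2", call. = FALSE)
  p <- matrix(rho / (c - 1), c, c)
  diag(p) <- 1 - rho
  structure(p, class = c("transition_matrix", "matrix"))
}

#' Asymmetric binary label-transition matrix
#'
#' `[[1 - rho01, rho01], [rho10, 1 - rho10]]`: background flips to foreground
#' with probability `rho01`, foreground to background with `rho10`.
#'
#' @param rho01,rho10 Flip probabilities in `[0, 1]`.
#' @return A 2x2 `transition_matrix` (row 1 = true background).
#' @export
asymmetric_transition <- function(rho01, rho10) {
  if (any(c(rho01, rho10) < 0) || any(c(rho01, rho10) > 1)) {
    stop("flip rates must lie in [0, 1]", call. = FALSE)
  }
  p <- matrix(c(1 - rho01, rho10, rho01, 1 - rho10), 2, 2)
  structure(p, class = c("transition_matrix", "matrix"))
}

#' Apply class-level transition noise to a binary mask
#'
#' Each pixel's label is redrawn independently from the transition-matrix row
#' selected by its true label.
#'
#' @param mask Binary matrix.
#' @param t A 2x2 [symmetric_transition()] / [asymmetric_transition()].
#' @param seed Integer seed.
#' @return Binary matrix of the same shape.
#' @export
apply_transition_noise <- function(mask, t, seed) {
  assert_binary_mask(mask)
  if (!all(dim(t) == c(2, 2))) stop("`t` must be 2x2", call. = FALSE)
  p_flip <- ifelse(mask == 0, t[1, 2], t[2, 1])
  with_seed(mix_seed(seed, 31L), {
    u <- matrix(runif(length(mask)), nrow(mask), ncol(mask))
    out <- ifelse(u < p_flip, 1 - mask, mask)
    out
  })
}

#' Per-pixel corruption-field specification
#'
#' Base flip rates plus two covariate-driven terms: a positional term that
#' raises flip probability within distance `boundary_dist` of the mask
#' boundary (annotator uncertainty concentrates at edges), and an
#' instance-dependent term that raises background-to-foreground flips where
#' the image intensity resembles the tumour reference intensity (bright
#' vessel-like or dark lesion-like structures attract false annotations).
#'
#' @param b01,b10 Base flip rates (background->foreground, foreground->background).
#' @param boundary_weight Added to both flip rates inside the boundary band.
#' @param boundary_dist Band half-width, pixels.
#' @param intensity_weight Peak of the intensity-similarity term on `p01`.
#' @param intensity_ref Tumour reference intensity.
#' @param intensity_scale Gaussian width of the similarity kernel.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(b01 = 0.02, b10 = 0.02,
                       boundary_weight = 0.3, boundary_dist = 2,
                       intensity_weight = 0.2, intensity_ref = 0.30,
                       intensity_scale = 0.06) {
  structure(list(b01 = b01, b10 = b10, boundary_weight = boundary_weight,
                 boundary_dist = boundary_dist,
                 intensity_weight = intensity_weight,
                 intensity_ref = intensity_ref,
                 intensity_scale = intensity_scale),
            class = "field_spec")
}

#' Corruption field: per-pixel flip probabilities
#'
#' @param p01 Matrix of background-to-foreground flip probabilities.
#' @param p10 Matrix of foreground-to-background flip probabilities.
#' @return An object of class `corruption_field`.
#' @export
corruption_field <- function(p01, p10) {
  assert_same_shape(p01, p10, c("p01", "p10"))
  assert_prob_range(p01, "p01")
  assert_prob_range(p10, "p10")
  structure(list(p01 = p01, p10 = p10), class = "corruption_field")
}

# Distance of every pixel to the mask boundary (0 on the boundary side).
boundary_distance <- function(mask) {
  if (all(mask == 0) || all(mask == 1)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  d_in <- EBImage::distmap(mask)        # fg pixels: distance to background
  d_out <- EBImage::distmap(1 - mask)   # bg pixels: distance to foreground
  d <- matrix(0, nrow(mask), ncol(mask))
  d[mask == 1] <- d_in[mask == 1]
  d[mask == 0] <- d_out[mask == 0]
  d
}

#' Build a per-pixel corruption field from image and mask covariates
#'
#' Combines base rates, a positional boundary band, and an
#' intensity-similarity term, clipped to `[0, 1]`.
#'
#' @param image Intensity matrix.
#' @param mask Binary matrix, same shape.
#' @param spec A [field_spec()].
#' @return A [corruption_field()].
#' @export
build_corruption_field <- function(image, mask, spec) {
  assert_binary_mask(mask)
  assert_same_shape(image, mask, c("image", "mask"))
  H <- nrow(mask); W <- ncol(mask)
  p01 <- matrix(spec$b01, H, W)
  p10 <- matrix(spec$b10, H, W)
  if (spec$boundary_weight > 0) {
    d <- boundary_distance(mask)
    band <- d <= spec$boundary_dist
    p01[band] <- p01[band] + spec$boundary_weight
    p10[band] <- p10[band] + spec$boundary_weight
  }
  if (spec$intensity_weight > 0) {
    sim <- exp(-((image - spec$intensity_ref)^2) / (2 * spec$intensity_scale^2))
    p01 <- p01 + spec$intensity_weight * sim
  }
  corruption_field(clamp01(p01), clamp01(p10))
}

#' Apply a per-pixel corruption field to a binary mask
#'
#' Pixel `w` flips with probability `p01(w)` if it is background and `p10(w)`
#' if it is foreground.
#'
#' @param mask Binary matrix.
#' @param f A [corruption_field()].
#' @param seed Integer seed.
#' @return Binary matrix of the same shape.
#' @export
apply_field_noise <- function(mask, f, seed) {
  assert_binary_mask(mask)
  assert_same_shape(mask, f$p01, c("mask", "p01"))
  p_flip <- ifelse(mask == 0, f$p01, f$p10)
  with_seed(mix_seed(seed, 37L), {
    u <- matrix(runif(length(mask)), nrow(mask), ncol(mask))
    ifelse(u < p_flip, 1 - mask, mask)
  })
}

#' Structured clinical mask corruptions
#'
#' Five corruption families mirroring how clinical annotations actually
#' fail: `shift` (mask misaligned with anatomy), `bleed` (label bleeds into
#' adjacent structures; morphological dilation), `deform` (inconsistent /
#' conflicting boundaries; a seeded smooth random warp), `speckle` (random
#' non-anatomic blobs toggled), and `truncate` (incomplete or cut-off
#' labels; foreground removed in a band from one edge).
#'
#' @param mask Binary matrix.
#' @param kind One of `"shift"`, `"bleed"`, `"deform"`, `"speckle"`,
#'   `"truncate"`.
#' @param params Kind-specific parameters: shift `list(dy, dx)`; bleed
#'   `list(radius)`; deform `list(magnitude, sigma)` (displacement sd in
#'   pixels, Gaussian smoothing scale); speckle `list(density, radius_range)`;
#'   truncate `list(fraction, edge)` with edge one of
#'   `"bottom","top","left","right"`.
#' @param seed Integer seed (used by `deform` and `speckle`).
#' @return Binary matrix of the same shape.
#' @export
apply_structured_corruption <- function(mask, kind, params = list(), seed = 1L) {
  assert_binary_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  switch(kind,
    shift = {
      dy <- as.integer(params$dy %||% 0); dx <- as.integer(params$dx %||% 0)
      out <- matrix(0, H, W)
      src_i <- seq_len(H) - dy; src_j <- seq_len(W) - dx
      ok_i <- src_i >= 1 & src_i <= H; ok_j <- src_j >= 1 & src_j <= W
      out[which(ok_i), which(ok_j)] <- mask[src_i[ok_i], src_j[ok_j]]
      out
    },
    bleed = {
      r <- as.integer(params$radius %||% 1)
      if (r <= 0) return(mask)
      brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
      out <- EBImage::dilate(mask, brush)
      matrix(as.numeric(out > 0), H, W)
    },
    deform = {
      mag <- params$magnitude %||% 2
      sg <- params$sigma %||% 4
      if (mag == 0) return(mask)
      with_seed(mix_seed(seed, 41L), {
        u <- EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = sg)
        v <- EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = sg)
        u <- u / max(stats::sd(u), 1e-8) * mag
        v <- v / max(stats::sd(v), 1e-8) * mag
        i <- matrix(seq_len(H), H, W); j <- matrix(seq_len(W), H, W, byrow = TRUE)
        si <- pmin(H, pmax(1, round(i + u)))
        sj <- pmin(W, pmax(1, round(j + v)))
        matrix(mask[cbind(as.vector(si), as.vector(sj))], H, W)
      })
    },
    speckle = {
      dens <- params$density %||% 0.001
      rr <- params$radius_range %||% c(1, 2)
      n_blobs <- round(dens * H * W)
      if (n_blobs == 0) return(mask)
      with_seed(mix_seed(seed, 43L), {
        out <- mask
        for (b in seq_len(n_blobs)) {
          cy <- runif(1, 1, H); cx <- runif(1, 1, W)
          r <- runif(1, rr[1], rr[2])
          blob <- disc_mask(H, W, cy, cx, r)
          out[blob] <- 1 - out[blob]
        }
        out
      })
    },
    truncate = {
      f <- params$fraction %||% 0.5
      edge <- params$edge %||% "bottom"
      n_cut <- round(f * if (edge %in% c("bottom", "top")) H else W)
      if (n_cut == 0) return(mask)
      out <- mask
      switch(edge,
             bottom = { out[(H - n_cut + 1):H, ] <- 0 },
             top    = { out[seq_len(n_cut), ] <- 0 },
             left   = { out[, seq_len(n_cut)] <- 0 },
             right  = { out[, (W - n_cut + 1):W] <- 0 },
             stop("unknown truncate edge", call. = FALSE))
      out
    },
    stop(sprintf("unknown corruption kind '%s'", kind), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- corruption plans ------------------------------------------------------

#' Corruption plans: ordered, seeded compositions of noise operators
#'
#' A plan is an ordered list of steps applied left-to-right; each step draws
#' its own seeded substream so the composition is a pure function of
#' `(mask, image, plan, seed)`. The empty plan is exactly the identity.
#'
#' @param ... Steps built with [step_symmetric()], [step_asymmetric()],
#'   [step_field()] or [step_structured()].
#' @return An object of class `corruption_plan`.
#' @export
corruption_plan <- function(...) {
  steps <- list(...)
  plan <- structure(list(steps = steps), class = "corruption_plan")
  validate_corruption_plan(plan)
  plan
}

#' @rdname corruption_plan
#' @param rho,rho01,rho10 Transition-noise rates.
#' @export
step_symmetric <- function(rho) {
  structure(list(type = "symmetric", rho = rho), class = "corruption_step")
}

#' @rdname corruption_plan
#' @export
step_asymmetric <- function(rho01, rho10) {
  structure(list(type = "asymmetric", rho01 = rho01, rho10 = rho10),
            class = "corruption_step")
}

#' @rdname corruption_plan
#' @param spec A [field_spec()].
#' @export
step_field <- function(spec = field_spec()) {
  structure(list(type = "field", spec = spec), class = "corruption_step")
}

#' @rdname corruption_plan
#' @param kind,params As in [apply_structured_corruption()].
#' @export
step_structured <- function(kind, params = list()) {
  structure(list(type = "structured", kind = kind, params = params),
            class = "corruption_step")
}

validate_corruption_plan <- function(plan) {
  if (!inherits(plan, "corruption_plan")) {
    stop("`plan` must be a corruption_plan", call. = FALSE)
  }
  for (s in plan$steps) {
    if (!inherits(s, "corruption_step")) {
      stop("every plan element must be a corruption_step", call. = FALSE)
    }
  }
  invisible(plan)
}

#' Default corruption plan
#'
#' Label bleed (dilation radius 2) + a smooth boundary-warping deformation +
#' symmetric speckle at rate 0.15 — a stand-in mixture covering the main
#' clinical corruption families; fully configurable via [corruption_plan()].
#'
#' @export
default_corruption_plan <- function() {
  corruption_plan(step_structured("bleed", list(radius = 2)),
                  step_structured("deform", list(magnitude = 2, sigma = 4)),
                  step_symmetric(0.15))
}

#' Apply a corruption plan to a mask
#'
#' @param mask Binary matrix.
#' @param plan A [corruption_plan()].
#' @param image Intensity matrix, required by `field` steps whose spec uses
#'   intensity covariates.
#' @param seed Integer seed; step `k` uses substream `mix_seed(seed, k)`.
#' @return The corrupted binary mask, with attribute `corruption_log`.
#' @export
apply_corruption_plan <- function(mask, plan, image = NULL, seed = 1L) {
  validate_corruption_plan(plan)
  assert_binary_mask(mask)
  out <- mask
  log <- character(0)
  for (k in seq_along(plan$steps)) {
    s <- plan$steps[[k]]
    sk <- mix_seed(seed, 500L + k)
    out <- switch(s$type,
      symmetric = apply_transition_noise(out, symmetric_transition(s$rho), sk),
      asymmetric = apply_transition_noise(out,
                     asymmetric_transition(s$rho01, s$rho10), sk),
      field = {
        if (is.null(image)) stop("field step requires `image`", call. = FALSE)
        apply_field_noise(out, build_corruption_field(image, out, s$spec), sk)
      },
      structured = apply_structured_corruption(out, s$kind, s$params, sk),
      stop("unknown step type", call. = FALSE))
    log <- c(log, switch(s$type,
      symmetric = sprintf("symmetric(rho=%g)", s$rho),
      asymmetric = sprintf("asymmetric(%g,%g)", s$rho01, s$rho10),
      field = "field",
      structured = sprintf("structured(%s)", s$kind)))
  }
  attr(out, "corruption_log") <- log
  out
}
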