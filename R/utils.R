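# Internal helpers: seeded sub-streams, validation, small numerics.

# Deterministically derive an integer sub-seed from a base seed and a set of
# integer tags. Keeps every source of randomness on an independent stream so
# that enabling or disabling one training component never shifts the draws
# of another. All arithmetic stays below 2^53, result below 2^31.
mix_seed <- function(seed, ...) {
  ids <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 104729
  for (v in ids) {
    h <- (h * 69069 + (v %% 2147483629) + 17) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

clamp01 <- function(x) {
  # keeps dims (pmax(0, x) would take attributes from the scalar)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

is_binary_mask <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m %in% c(0, 1))
}

assert_binary_mask <- function(m, what = "mask") {
  if (!is_binary_mask(m)) {
    stop(sprintf("`%s` must be a numeric matrix with values in {0, 1}", what),
         call. = FALSE)
  }
  invisible(m)
}

assert_same_shape <- function(a, b, what = c("a", "b")) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(sprintf("`%s` and `%s` must have identical shapes", what[1], what[2]),
         call. = FALSE)
  }
  invisible(NULL)
}

assert_prob_range <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
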