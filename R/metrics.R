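# Overlap metrics and cohort statistics. All four indices are reported as
# percentages: DSC = 2|A∩B|/(|A|+|B|), JSC = |A∩B|/|A∪B|, and their exact
# complements SVD = 100 - DSC, VOE = 100 - JSC.

#' Overlap scores for one predicted/reference mask pair
#'
#' @param pred_mask,ref_mask Binary matrices of equal shape.
#' @return Named numeric vector `c(dsc, jsc, svd, voe)` in `[0, 100]`.
#'   When both masks are empty the pair is scored as perfect agreement
#'   (DSC = JSC = 100) and a message is logged.
#' @export
segmentation_scores <- function(pred_mask, ref_mask) {
  assert_binary_mask(pred_mask, "pred_mask")
  assert_binary_mask(ref_mask, "ref_mask")
  assert_same_shape(pred_mask, ref_mask, c("pred_mask", "ref_mask"))
  a <- sum(pred_mask); b <- sum(ref_mask)
  if (a == 0 && b == 0) {
    message("both masks empty: scored as perfect agreement")
    return(c(dsc = 100, jsc = 100, svd = 0, voe = 0))
  }
  inter <- sum(pred_mask * ref_mask)
  dsc <- 100 * 2 * inter / (a + b)
  jsc <- 100 * inter / (a + b - inter)
  c(dsc = dsc, jsc = jsc, svd = 100 - dsc, voe = 100 - jsc)
}

#' Score a set of cases
#'
#' @param pred_masks,ref_masks Lists of binary matrices, matched by position.
#' @param ids Case identifiers.
#' @return A `score_table` data.frame with columns `id, dsc, jsc, svd, voe`.
#' @export
score_table <- function(pred_masks, ref_masks, ids = seq_along(pred_masks)) {
  if (length(pred_masks) != length(ref_masks)) {
    stop("prediction and reference lists differ in length", call. = FALSE)
  }
  rows <- t(mapply(segmentation_scores, pred_masks, ref_masks))
  out <- data.frame(id = as.character(ids), rows, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Cohort summary: mean and 95% t-interval per metric
#'
#' The interval is `mean ± t_{n-1, 1-(1-level)/2} * s / sqrt(n)` over
#' per-case scores (a percentile bootstrap is available via
#' `method = "bootstrap"`). Intervals are not clipped to `[0, 100]`.
#'
#' @param scores A `score_table` (or data.frame with metric columns).
#' @param level Confidence level.
#' @param method `"t"` or `"bootstrap"`.
#' @param boot_n,boot_seed Bootstrap resamples and seed.
#' @return A data.frame with one row per metric: `metric, mean, lower,
#'   upper, n`.
#' @export
summarize_scores <- function(scores, level = 0.95, method = c("t", "bootstrap"),
                             boot_n = 2000, boot_seed = 1L) {
  method <- match.arg(method)
  metrics <- intersect(c("dsc", "jsc", "svd", "voe"), names(scores))
  n <- nrow(scores)
  if (n < 2) stop("cohort summary needs n >= 2 cases", call. = FALSE)
  rows <- lapply(metrics, function(m) {
    x <- scores[[m]]
    mu <- mean(x)
    if (method == "t") {
      half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
      lo <- mu - half; hi <- mu + half
    } else {
      bs <- with_seed(mix_seed(boot_seed, 53L), {
        vapply(seq_len(boot_n),
               function(i) mean(x[sample.int(n, n, replace = TRUE)]),
               numeric(1))
      })
      qs <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2),
                            names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(metric = m, mean = mu, lower = lo, upper = hi, n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sided paired t-test on matched per-case scores
#'
#' @param scores_a,scores_b Numeric vectors of equal length (>= 2), matched
#'   by case.
#' @return The two-sided p-value. All-zero differences return `p = 1` by
#'   convention (no evidence of any difference).
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors differ in length", call. = FALSE)
  }
  if (length(scores_a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- scores_a - scores_b
  if (all(d == 0) || stats::sd(d) == 0 && mean(d) == 0) return(1)
  if (stats::sd(d) == 0) return(0)  # constant nonzero difference
  stats::t.test(scores_a, scores_b, paired = TRUE)$p.value
}

#' Compare two methods metric-by-metric
#'
#' @param scores_a,scores_b `score_table`s matched by `id`.
#' @return Named vector of paired-t p-values for dsc, jsc, svd, voe.
#' @export
compare_methods <- function(scores_a, scores_b) {
  common <- intersect(scores_a$id, scores_b$id)
  a <- scores_a[match(common, scores_a$id), ]
  b <- scores_b[match(common, scores_b$id), ]
  vapply(c("dsc", "jsc", "svd", "voe"),
         function(m) paired_t_test(a[[m]], b[[m]]), numeric(1))
}

#' Complements of the overlap coefficients
#'
#' `svd_from_dsc(d) = 100 - d` and `voe_from_jsc(j) = 100 - j`; the same
#' identities the per-case scorer satisfies, exposed for checking published
#' summary tables.
#'
#' @param dsc,jsc Percent values.
#' @export
svd_from_dsc <- function(dsc) 100 - dsc

#' @rdname svd_from_dsc
#' @export
voe_from_jsc <- function(jsc) 100 - jsc
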