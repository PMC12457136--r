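# Compact CPU U-Net with a shared-encoder adaptor head.
#
# The backbone f_theta is a plain-convolution encoder-decoder with skip
# connections emitting a per-pixel foreground probability map through a
# sigmoid. The adaptor head f_theta_ada is a lightweight second decoder fed
# from the same bottleneck (no skips by default) ending in a 3x3 convolution
# with 2 output channels + sigmoid; its channels are the per-pixel
# probabilities p(labelled fg | true fg) and p(labelled fg | true bg).
# Forward and backward passes are hand-written over Rcpp kernels; the
# backward pass is verified against finite differences in the test suite.

#' Backbone configuration
#'
#' @param depth Number of resolution levels including the bottleneck
#'   (>= 2). Input sides must be divisible by `2^(depth - 1)`.
#' @param base_width Channels at the first stage; width doubles per level.
#' @param dropout_rate Bottleneck dropout used by stochastic forward passes
#'   (in `[0, 1)`).
#' @param adaptor_skips Whether the adaptor decoder also consumes encoder
#'   skip features (default `FALSE`: bottleneck only).
#' @param in_channels Input channels (1 for grayscale).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_width = 16L, dropout_rate = 0.1,
                        adaptor_skips = FALSE, in_channels = 1L) {
  if (depth < 2) stop("`depth` must be >= 2", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(depth = as.integer(depth), base_width = as.integer(base_width),
                 dropout_rate = dropout_rate, adaptor_skips = adaptor_skips,
                 in_channels = as.integer(in_channels)),
            class = "unet_config")
}

stage_width <- function(config, i) config$base_width * 2L^(i - 1L)

conv_par <- function(k, cin, cout, bias = 0) {
  # He-style initialization for ReLU stacks
  W <- array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
             dim = c(k, k, cin, cout))
  b <- rep(bias, length.out = cout)
  list(W = W, b = b)
}

#' Initialize a segmentation model
#'
#' Creates all backbone and adaptor parameters. The adaptor head bias starts
#' near the identity corruption (p(fg|fg) ~ 0.88, p(fg|bg) ~ 0.12) so early
#' training behaves like plain supervision.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for the parameter draw.
#' @return An object of class `unet_model` with elements `config` and
#'   `params` (a flat named list of arrays).
#' @export
unet_init <- function(config, seed = 1L) {
  D <- config$depth
  with_seed(mix_seed(seed, 71L), {
    p <- list()
    cin <- config$in_channels
    for (i in seq_len(D - 1)) {
      w <- stage_width(config, i)
      p[[sprintf("enc%d_c1", i)]] <- conv_par(3, cin, w)
      p[[sprintf("enc%d_c2", i)]] <- conv_par(3, w, w)
      cin <- w
    }
    wD <- stage_width(config, D)
    p[["bott_c1"]] <- conv_par(3, cin, wD)
    p[["bott_c2"]] <- conv_par(3, wD, wD)
    for (i in rev(seq_len(D - 1))) {
      w <- stage_width(config, i)
      wup <- stage_width(config, i + 1)
      p[[sprintf("dec%d_c1", i)]] <- conv_par(3, wup + w, w)
      p[[sprintf("dec%d_c2", i)]] <- conv_par(3, w, w)
    }
    p[["head"]] <- conv_par(1, stage_width(config, 1), 1)
    for (i in rev(seq_len(D - 1))) {
      w <- stage_width(config, i)
      wup <- stage_width(config, i + 1)
      cin_a <- if (config$adaptor_skips) wup + w else wup
      p[[sprintf("ada%d", i)]] <- conv_par(3, cin_a, w)
    }
    ada_head <- conv_par(3, stage_width(config, 1), 2)
    ada_head$b <- c(2, -2)
    p[["ada_head"]] <- ada_head
    structure(list(config = config, params = p), class = "unet_model")
  })
}

# ---- flat parameter vector utilities --------------------------------------

par_flatten <- function(params) {
  unlist(lapply(params, function(l) c(as.numeric(l$W), as.numeric(l$b))),
         use.names = FALSE)
}

par_unflatten <- function(v, template) {
  out <- template
  pos <- 1L
  for (nm in names(template)) {
    nw <- length(template[[nm]]$W)
    nb <- length(template[[nm]]$b)
    out[[nm]]$W <- array(v[pos:(pos + nw - 1)], dim = dim(template[[nm]]$W))
    pos <- pos + nw
    out[[nm]]$b <- v[pos:(pos + nb - 1)]
    pos <- pos + nb
  }
  out
}

zero_like <- function(params) {
  lapply(params, function(l) list(W = array(0, dim = dim(l$W)),
                                  b = numeric(length(l$b))))
}

# ---- forward / backward ----------------------------------------------------

conv_fw <- function(x, layer) {
  d <- dim(x)
  wd <- dim(layer$W)
  y <- cpp_conv2d_fw(as.numeric(x), as.numeric(layer$W), layer$b,
                     d[1], d[2], d[3], wd[4], wd[1])
  array(y, dim = c(d[1], d[2], wd[4]))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Forward pass of the backbone and adaptor
#'
#' @param model A [unet_init()] model.
#' @param image Numeric matrix; both sides divisible by `2^(depth - 1)`.
#' @param stochastic If `TRUE`, applies bottleneck dropout at
#'   `config$dropout_rate`.
#' @param feature_perturbation Optional `list(rate = r)`: extra multiplicative
#'   dropout on the bottleneck features (the feature-level perturbation stage
#'   of consistency training), applied before both decoders.
#' @param seed Seed for the stochastic draws (required when any are active).
#' @param want_cache Keep intermediate activations for [unet_backward()].
#' @return A list with `prob` (foreground probability matrix), `cmap` (a
#'   `corruption_map`: matrices `p_fg_given_fg`, `p_fg_given_bg`),
#'   `bottleneck` (feature array) and, if requested, `cache`.
#' @export
unet_forward <- function(model, image, stochastic = FALSE,
                         feature_perturbation = NULL, seed = 1L,
                         want_cache = FALSE) {
  config <- model$config
  p <- model$params
  D <- config$depth
  H <- nrow(image); W <- ncol(image)
  div <- 2L^(D - 1L)
  if (H %% div != 0 || W %% div != 0) {
    stop(sprintf("image sides must be divisible by %d for depth %d", div, D),
         call. = FALSE)
  }
  cache <- list(enc = vector("list", D - 1), dec = vector("list", D - 1),
                ada = vector("list", D - 1))
  x <- array(image, dim = c(H, W, config$in_channels))
  skips <- vector("list", D - 1)
  for (i in seq_len(D - 1)) {
    xin <- x
    a1 <- relu(conv_fw(xin, p[[sprintf("enc%d_c1", i)]]))
    a2 <- relu(conv_fw(a1, p[[sprintf("enc%d_c2", i)]]))
    d <- dim(a2)
    pl <- cpp_maxpool2_fw(as.numeric(a2), d[1], d[2], d[3])
    x <- array(pl$y, dim = c(d[1] / 2, d[2] / 2, d[3]))
    skips[[i]] <- a2
    if (want_cache) {
      cache$enc[[i]] <- list(xin = xin, a1 = a1, a2 = a2, idx = pl$idx,
                             d = d)
    }
  }
  b_in <- x
  b1 <- relu(conv_fw(b_in, p[["bott_c1"]]))
  b2 <- relu(conv_fw(b1, p[["bott_c2"]]))

  drop_mask <- NULL
  rate_total <- 0
  if (isTRUE(stochastic) && config$dropout_rate > 0) {
    rate_total <- config$dropout_rate
  }
  if (!is.null(feature_perturbation) && (feature_perturbation$rate %||% 0) > 0) {
    rate_total <- 1 - (1 - rate_total) * (1 - feature_perturbation$rate)
  }
  bott <- b2
  if (rate_total > 0) {
    drop_mask <- with_seed(mix_seed(seed, 73L), {
      array(stats::rbinom(length(b2), 1, 1 - rate_total) / (1 - rate_total),
            dim = dim(b2))
    })
    bott <- b2 * drop_mask
  }

  # main decoder
  x <- bott
  for (i in rev(seq_len(D - 1))) {
    d <- dim(x)
    up <- array(cpp_upsample2_fw(as.numeric(x), d[1], d[2], d[3]),
                dim = c(2 * d[1], 2 * d[2], d[3]))
    cat_in <- array(c(up, skips[[i]]),
                    dim = c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(skips[[i]])[3]))
    d1 <- relu(conv_fw(cat_in, p[[sprintf("dec%d_c1", i)]]))
    d2 <- relu(conv_fw(d1, p[[sprintf("dec%d_c2", i)]]))
    if (want_cache) {
      cache$dec[[i]] <- list(xin = x, cat_in = cat_in, d1 = d1, d2 = d2,
                             n_up = dim(up)[3])
    }
    x <- d2
  }
  z <- conv_fw(x, p[["head"]])
  prob <- sigmoid(matrix(z[, , 1], H, W))

  # adaptor decoder (bottleneck features only by default)
  xa <- bott
  for (i in rev(seq_len(D - 1))) {
    d <- dim(xa)
    upa <- array(cpp_upsample2_fw(as.numeric(xa), d[1], d[2], d[3]),
                 dim = c(2 * d[1], 2 * d[2], d[3]))
    ain <- if (config$adaptor_skips) {
      array(c(upa, skips[[i]]),
            dim = c(dim(upa)[1], dim(upa)[2], dim(upa)[3] + dim(skips[[i]])[3]))
    } else {
      upa
    }
    aa <- relu(conv_fw(ain, p[[sprintf("ada%d", i)]]))
    if (want_cache) {
      cache$ada[[i]] <- list(xin = xa, ain = ain, a = aa, n_up = dim(upa)[3])
    }
    xa <- aa
  }
  za <- conv_fw(xa, p[["ada_head"]])
  s <- sigmoid(za)
  cmap <- corruption_map(matrix(s[, , 1], H, W), matrix(s[, , 2], H, W))

  out <- list(prob = prob, cmap = cmap, bottleneck = b2)
  if (want_cache) {
    cache$b_in <- b_in; cache$b1 <- b1; cache$b2 <- b2
    cache$drop_mask <- drop_mask
    cache$dec_out <- x
    cache$ada_out <- xa
    cache$prob <- prob
    cache$s <- s
    cache$H <- H; cache$W <- W
    out$cache <- cache
  }
  out
}

#' Corruption map
#'
#' Per-pixel adaptor output: `p_fg_given_fg` = probability that a true
#' foreground pixel is labelled foreground; `p_fg_given_bg` = probability
#' that a true background pixel is (mis)labelled foreground.
#'
#' @param p_fg_given_fg,p_fg_given_bg Matrices in `[0, 1]`.
#' @export
corruption_map <- function(p_fg_given_fg, p_fg_given_bg) {
  assert_same_shape(p_fg_given_fg, p_fg_given_bg,
                    c("p_fg_given_fg", "p_fg_given_bg"))
  structure(list(p_fg_given_fg = p_fg_given_fg,
                 p_fg_given_bg = p_fg_given_bg),
            class = "corruption_map")
}

conv_bw <- function(x, layer, gy) {
  d <- dim(x)
  wd <- dim(layer$W)
  r <- cpp_conv2d_bw(as.numeric(x), as.numeric(layer$W), as.numeric(gy),
                     d[1], d[2], d[3], wd[4], wd[1])
  list(gx = array(r$gx, dim = d),
       gW = array(r$gw, dim = wd),
       gb = r$gb)
}

#' Backward pass: gradients of a scalar loss
#'
#' Propagates `gprob = dL/dprob` and the corruption-map gradients
#' `gcmap = list(g_fg_given_fg, g_fg_given_bg)` (either may be zero matrices)
#' through both decoders, the shared bottleneck and the encoder.
#'
#' @param model A [unet_init()] model.
#' @param cache The cache from `unet_forward(..., want_cache = TRUE)`.
#' @param gprob Matrix `dL/dprob`.
#' @param gcmap Optional list of two matrices, gradients with respect to the
#'   corruption-map channels.
#' @return A list of per-layer gradients congruent with `model$params`.
#' @export
unet_backward <- function(model, cache, gprob, gcmap = NULL) {
  config <- model$config
  p <- model$params
  D <- config$depth
  g <- zero_like(p)

  # head
  gz <- gprob * cache$prob * (1 - cache$prob)
  gz <- array(gz, dim = c(cache$H, cache$W, 1))
  r <- conv_bw(cache$dec_out, p[["head"]], gz)
  g[["head"]]$W <- r$gW; g[["head"]]$b <- r$gb
  gx <- r$gx

  gskip <- vector("list", D - 1)
  for (i in seq_len(D - 1)) {
    cc <- cache$dec[[i]]
    gd2 <- gx * (cc$d2 > 0)
    r2 <- conv_bw(cc$d1, p[[sprintf("dec%d_c2", i)]], gd2)
    g[[sprintf("dec%d_c2", i)]]$W <- r2$gW
    g[[sprintf("dec%d_c2", i)]]$b <- r2$gb
    gd1 <- r2$gx * (cc$d1 > 0)
    r1 <- conv_bw(cc$cat_in, p[[sprintf("dec%d_c1", i)]], gd1)
    g[[sprintf("dec%d_c1", i)]]$W <- r1$gW
    g[[sprintf("dec%d_c1", i)]]$b <- r1$gb
    n_up <- cc$n_up
    g_up <- r1$gx[, , seq_len(n_up), drop = FALSE]
    gskip[[i]] <- r1$gx[, , (n_up + 1):dim(r1$gx)[3], drop = FALSE]
    d <- dim(cc$xin)
    gx <- array(cpp_upsample2_bw(as.numeric(g_up), d[1], d[2], d[3]),
                dim = d)
  }
  g_bott_main <- gx  # gradient arriving at the (possibly dropped) bottleneck

  # adaptor branch
  g_bott_ada <- 0
  if (!is.null(gcmap)) {
    gza <- array(0, dim = dim(cache$s))
    gza[, , 1] <- gcmap[[1]] * cache$s[, , 1] * (1 - cache$s[, , 1])
    gza[, , 2] <- gcmap[[2]] * cache$s[, , 2] * (1 - cache$s[, , 2])
    r <- conv_bw(cache$ada_out, p[["ada_head"]], gza)
    g[["ada_head"]]$W <- r$gW; g[["ada_head"]]$b <- r$gb
    gxa <- r$gx
    for (i in seq_len(D - 1)) {
      cc <- cache$ada[[i]]
      ga <- gxa * (cc$a > 0)
      r1 <- conv_bw(cc$ain, p[[sprintf("ada%d", i)]], ga)
      g[[sprintf("ada%d", i)]]$W <- r1$gW
      g[[sprintf("ada%d", i)]]$b <- r1$gb
      n_up <- cc$n_up
      g_up <- r1$gx[, , seq_len(n_up), drop = FALSE]
      if (config$adaptor_skips) {
        gskip[[i]] <- gskip[[i]] + r1$gx[, , (n_up + 1):dim(r1$gx)[3], drop = FALSE]
      }
      d <- dim(cc$xin)
      gxa <- array(cpp_upsample2_bw(as.numeric(g_up), d[1], d[2], d[3]),
                   dim = d)
    }
    g_bott_ada <- gxa
  }

  g_bott <- g_bott_main + g_bott_ada
  if (!is.null(cache$drop_mask)) g_bott <- g_bott * cache$drop_mask

  gb2 <- g_bott * (cache$b2 > 0)
  r2 <- conv_bw(cache$b1, p[["bott_c2"]], gb2)
  g[["bott_c2"]]$W <- r2$gW; g[["bott_c2"]]$b <- r2$gb
  gb1 <- r2$gx * (cache$b1 > 0)
  r1 <- conv_bw(cache$b_in, p[["bott_c1"]], gb1)
  g[["bott_c1"]]$W <- r1$gW; g[["bott_c1"]]$b <- r1$gb
  gx <- r1$gx

  for (i in rev(seq_len(D - 1))) {
    cc <- cache$enc[[i]]
    d <- cc$d
    g_pool <- array(cpp_maxpool2_bw(as.numeric(gx), cc$idx, d[1], d[2], d[3]),
                    dim = d)
    ga2 <- (g_pool + gskip[[i]]) * (cc$a2 > 0)
    r2 <- conv_bw(cc$a1, p[[sprintf("enc%d_c2", i)]], ga2)
    g[[sprintf("enc%d_c2", i)]]$W <- r2$gW
    g[[sprintf("enc%d_c2", i)]]$b <- r2$gb
    ga1 <- r2$gx * (cc$a1 > 0)
    r1 <- conv_bw(cc$xin, p[[sprintf("enc%d_c1", i)]], ga1)
    g[[sprintf("enc%d_c1", i)]]$W <- r1$gW
    g[[sprintf("enc%d_c1", i)]]$b <- r1$gb
    gx <- r1$gx
  }
  g
}

#' Save / load a model checkpoint
#'
#' A named parameter archive with the configuration echoed alongside.
#'
#' @param model A `unet_model`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  config <- structure(x$config, class = "unet_config")
  structure(list(config = config, params = x$params), class = "unet_model")
}
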