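# Network assembly.
#
# The canonical model is a five-level encoder-decoder. Encoder: three LDA
# stages (each ending in a 2x2 max-pool) followed by two MLP stages, each a
# 3x3 stride-2 embedding convolution + an LMLP mixing block; channel
# schedule 3-16-32-128-160-256, capped at 256. Decoder mirror: two MLP
# stages (channel-reduction conv at the low resolution, bilinear x2 up, skip
# fusion, LMLP block at the fused resolution), then LDA stages interleaved
# with bilinear x2 ups and skip fusions, and a 1x1 single-channel sigmoid
# head at full resolution. Skip fusion is elementwise addition after a 1x1
# channel-matching convolution on the encoder feature.

STAGE_CHANNELS <- list(
  c(3L, 16L), c(16L, 32L), c(32L, 128L), c(128L, 160L), c(160L, 256L),
  c(256L, 160L), c(160L, 128L), c(128L, 32L), c(32L, 16L), c(16L, 3L))

VARIANT_KINDS <- list(
  lcmunet         = c("lda_a", "lda_b", "lda_b", "lmlp", "lmlp",
                      "lmlp", "lmlp", "lda_b", "lda_b", "lda_a"),
  all_lda_a       = rep("lda_a", 10L),
  lda_a_plus_b    = c("lda_a", rep("lda_b", 8L), "lda_a"),
  lda_a_plus_lmlp = c("lda_a", "lda_a", "lda_a", "lmlp", "lmlp",
                      "lmlp", "lmlp", "lda_a", "lda_a", "lda_a"))

#' Stage table of a built model
#'
#' Returns the ordered 16-stage architecture table (block stages, bilinear
#' upsamplings, and the classification head) with stage kind, channel widths
#' and resampling factor.
#'
#' @param model a model built by [build_lcmunet()] or [build_variant()].
#' @return a data.frame with columns `stage`, `kind`, `in_channels`,
#'   `out_channels`, `scale`.
#' @export
architecture_spec <- function(model) {
  model$arch
}

make_arch_table <- function(kinds) {
  ch <- STAGE_CHANNELS
  blk <- function(i) data.frame(
    kind = toupper(sub("_", "-", kinds[i])),
    in_channels = ch[[i]][1], out_channels = ch[[i]][2],
    scale = if (i <= 5) 0.5 else 1)
  up <- function(c) data.frame(kind = "BilinearUp", in_channels = c,
                               out_channels = c, scale = 2)
  rows <- list(blk(1), blk(2), blk(3), blk(4), blk(5),
               blk(6), up(160L), blk(7), up(128L), blk(8), up(32L),
               blk(9), up(16L), blk(10), up(3L),
               data.frame(kind = "SigmoidHead", in_channels = 3L,
                          out_channels = 1L, scale = 1))
  out <- do.call(rbind, rows)
  out <- cbind(stage = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

make_stage <- function(kind, a, b, pos, se_reduction) {
  encoder <- pos <= 5L
  if (kind == "lmlp") {
    if (encoder) {
      list(kind = "lmlp", encoder = TRUE, a = a, b = b,
           embed = new_conv(a, b, 3L, 3L, stride = 2L, bias = TRUE),
           embed_ln = new_ln(b),
           block = new_lmlp_block(lmlp_config(b)))
    } else {
      list(kind = "lmlp", encoder = FALSE, a = a, b = b,
           reduce = new_conv(a, b, 3L, 3L),
           reduce_bn = new_bn(b),
           block = new_lmlp_block(lmlp_config(b)))
    }
  } else {
    cfg <- lda_config(a, b, stride = if (encoder) 2L else 1L,
                      use_se = kind == "lda_b",
                      se_reduction = se_reduction)
    list(kind = kind, encoder = encoder, a = a, b = b,
         block = new_lda_block(cfg))
  }
}

#' Build the canonical segmentation network
#'
#' Assembles the full five-level CNN+MLP encoder-decoder at the canonical
#' channel schedule (3-16-32-128-160-256 and mirror).
#'
#' @param se_reduction SE bottleneck ratio used by the LDA-B stages.
#' @param seed optional integer; when given, weight initialisation is drawn
#'   from this seed for reproducibility.
#' @return a model object; see [model_forward()], [count_parameters()].
#' @export
build_lcmunet <- function(se_reduction = 2L, seed = NULL) {
  build_variant("lcmunet", se_reduction = se_reduction, seed = seed)
}

#' Build a named architecture variant
#'
#' `"lcmunet"` is the canonical model; `"all_lda_a"` replaces every block
#' stage with LDA-A; `"lda_a_plus_b"` keeps LDA-A in the first stage (and
#' its decoder mirror) and uses LDA-B elsewhere; `"lda_a_plus_lmlp"` keeps
#' the MLP stages but strips the SE modules; `"unet_baseline"` is the
#' classic five-level UNet rebuilt for parameter-count comparison.
#'
#' @param name variant name.
#' @inheritParams build_lcmunet
#' @return a model object.
#' @export
build_variant <- function(name = c("lcmunet", "all_lda_a", "lda_a_plus_b",
                                   "lda_a_plus_lmlp", "unet_baseline"),
                          se_reduction = 2L, seed = NULL) {
  if (!is.character(name) || !name[1] %in%
        c(names(VARIANT_KINDS), "unet_baseline"))
    stop("unknown variant '", name[1], "'; valid: ",
         paste(c(names(VARIANT_KINDS), "unet_baseline"), collapse = ", "))
  name <- name[1]
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (name == "unet_baseline") return(build_unet_baseline())
  kinds <- VARIANT_KINDS[[name]]
  m <- new.env(parent = emptyenv())
  m$variant <- name
  m$se_reduction <- as.integer(se_reduction)
  m$stages <- lapply(seq_along(kinds), function(i)
    make_stage(kinds[i], STAGE_CHANNELS[[i]][1], STAGE_CHANNELS[[i]][2],
               i, se_reduction))
  m$skips <- lapply(c(16L, 32L, 128L, 160L), function(c)
    list(conv = new_conv(c, c), bn = new_bn(c)))
  m$head <- new_conv(3L, 1L, bias = TRUE)
  m$arch <- make_arch_table(kinds)
  m$children <- list(stages = lapply(m$stages, stage_children),
                     skips = lapply(m$skips, function(s)
                       list(s$conv, s$bn)),
                     head = m$head)
  class(m) <- c(paste0("lcm_", name), "lcmunet_model")
  m
}

stage_children <- function(st) {
  keep <- intersect(names(st),
                    c("embed", "embed_ln", "reduce", "reduce_bn", "block"))
  lapply(keep, function(nm) {
    obj <- st[[nm]]
    if (inherits(obj, "lcm_block")) obj$children else obj
  })
}

#' Model fingerprint
#'
#' A short structural signature (variant, stage table, parameter count)
#' embedded in checkpoints; loading refuses a checkpoint whose fingerprint
#' does not match the built model.
#'
#' @param model a built model.
#' @return a single string.
#' @export
model_fingerprint <- function(model) {
  a <- model$arch
  paste(model$variant,
        paste(a$kind, a$in_channels, a$out_channels, collapse = ";"),
        count_parameters(model), sep = "|")
}

# forward / backward ----------------------------------------------------------

check_input <- function(x, channels = 3L) {
  d <- fm_dims(x)
  if (d[1] != channels)
    stop("expected ", channels, "-channel input, got ", d[1])
  if (d[2] %% 32L || d[3] %% 32L)
    stop("input height/width must be divisible by 32, got ",
         d[2], "x", d[3])
  d
}

#' Forward pass
#'
#' Runs a built model on a batch of images and returns per-pixel foreground
#' probabilities.
#'
#' @param model a model from [build_variant()].
#' @param x input array `(3, H, W, N)` with values in `[0, 1]`; H and W
#'   must be divisible by 32.
#' @param training logical; batch-statistic normalisation plus caches for
#'   [model_backward()].
#' @return probability array `(1, H, W, N)` in `[0, 1]`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  if (model$variant == "unet_baseline")
    return(unet_forward(model, x, training))
  check_input(x)
  st <- model$stages
  cc <- list()
  enc <- vector("list", 5L)
  h <- x
  for (i in 1:5) {
    s <- st[[i]]
    if (s$kind == "lmlp") {
      t <- layer_forward(s$embed, h, training)
      t <- layer_forward(s$embed_ln, t, training)
      h <- lmlp_forward(s$block, t, training)
    } else {
      h <- lda_forward(s$block, h, training)
    }
    enc[[i]] <- h
  }
  # skip projections
  sk <- vector("list", 4L)
  for (k in 1:4) {
    s <- model$skips[[k]]
    sk[[k]] <- layer_forward(s$bn, layer_forward(s$conv, enc[[k]], training),
                             training)
  }
  for (i in 6:9) {
    s <- st[[i]]
    k <- 10L - i                                  # skip level fused after up
    if (s$kind == "lmlp") {
      t <- layer_forward(s$reduce_bn, layer_forward(s$reduce, h, training),
                         training)
      u <- bilinear_up2_fwd(t)
      r <- relu_fwd(u$y)
      cc[[paste0("relu", i)]] <- r$cache
      f <- r$y + sk[[k]]
      h <- lmlp_forward(s$block, f, training)
    } else {
      t <- lda_forward(s$block, h, training)
      u <- bilinear_up2_fwd(t)
      h <- u$y + sk[[k]]
    }
  }
  s <- st[[10]]
  t <- lda_forward(s$block, h, training)
  u <- bilinear_up2_fwd(t)
  z <- layer_forward(model$head, u$y, training)
  sg <- sigmoid_fwd(z)
  cc$sig <- sg$cache
  model$cache <- cc
  sg$y
}

#' Backward pass
#'
#' Backpropagates the gradient of a scalar loss with respect to the
#' predicted probabilities through the whole network, leaving per-layer
#' weight gradients in the layer objects.
#'
#' @param model the model used in the preceding `model_forward(training
#'   = TRUE)` call.
#' @param dprob gradient array matching the forward output.
#' @return invisibly, the gradient with respect to the input images.
#' @export
model_backward <- function(model, dprob) {
  if (model$variant == "unet_baseline")
    stop("backward is not implemented for the unet_baseline comparison model")
  st <- model$stages
  cc <- model$cache
  dz <- sigmoid_bwd(cc$sig, dprob)
  g <- layer_backward(model$head, dz)
  g <- bilinear_up2_bwd(dim(g) / c(1, 2, 2, 1), g)
  g <- lda_backward(st[[10]]$block, g)
  dsk <- vector("list", 4L)                       # grads into skip branches
  for (i in 9:6) {
    s <- st[[i]]
    k <- 10L - i
    if (s$kind == "lmlp") {
      g <- lmlp_backward(s$block, g)
      dsk[[k]] <- g
      g <- relu_bwd(cc[[paste0("relu", i)]], g)
      g <- bilinear_up2_bwd(dim(g) / c(1, 2, 2, 1), g)
      g <- layer_backward(s$reduce, layer_backward(s$reduce_bn, g))
    } else {
      dsk[[k]] <- g
      g <- bilinear_up2_bwd(dim(g) / c(1, 2, 2, 1), g)
      g <- lda_backward(s$block, g)
    }
  }
  # skip projections feed encoder outputs
  denc <- vector("list", 5L)
  denc[[5]] <- g
  for (k in 1:4) {
    s <- model$skips[[k]]
    denc[[k]] <- layer_backward(s$conv, layer_backward(s$bn, dsk[[k]]))
  }
  for (i in 5:1) {
    s <- st[[i]]
    g <- denc[[i]]
    if (s$kind == "lmlp") {
      g <- lmlp_backward(s$block, g)
      g <- layer_backward(s$embed, layer_backward(s$embed_ln, g))
    } else {
      g <- lda_backward(s$block, g)
    }
    if (i > 1) denc[[i - 1]] <- denc[[i - 1]] + g
  }
  invisible(g)
}

# classic UNet baseline --------------------------------------------------------

UNET_WIDTHS <- c(64L, 128L, 256L, 512L, 1024L)

double_conv <- function(a, b) list(
  c1 = new_conv(a, b, 3L, 3L), b1 = new_bn(b),
  c2 = new_conv(b, b, 3L, 3L), b2 = new_bn(b))

build_unet_baseline <- function() {
  w <- UNET_WIDTHS
  m <- new.env(parent = emptyenv())
  m$variant <- "unet_baseline"
  m$enc <- list(double_conv(3L, w[1]), double_conv(w[1], w[2]),
                double_conv(w[2], w[3]), double_conv(w[3], w[4]),
                double_conv(w[4], w[5]))
  # 2x2 transposed convolutions, with bias
  m$ups <- lapply(4:1, function(i) new_upconv(w[i + 1], w[i]))
  m$dec <- lapply(4:1, function(i) double_conv(2L * w[i], w[i]))
  m$head <- new_conv(w[1], 1L, bias = TRUE)
  m$arch <- data.frame(stage = 1L, kind = "UNet", in_channels = 3L,
                       out_channels = 1L, scale = 1)
  m$children <- list(m$enc, m$ups, m$dec, m$head)
  class(m) <- c("lcm_unet_baseline", "lcmunet_model")
  m
}

# A 2x2 stride-2 transposed convolution is a per-position linear map to a
# 2x2 output patch: implemented as a 1x1 convolution to 4*cout channels
# followed by pixel shuffle; the bias (length cout) is added after the
# shuffle so the parameterisation matches the standard transposed layer.
new_upconv <- function(cin, cout) {
  l <- new_conv(cin, 4L * cout)
  l$params$b <- numeric(cout)
  l$meta$transposed <- TRUE
  l$meta$cout_eff <- cout
  l
}

pixel_shuffle2 <- function(x) {
  d <- fm_dims(x)
  c_out <- d[1] %/% 4L
  y <- array(0, dim = c(c_out, 2L * d[2], 2L * d[3], d[4]))
  k <- 0L
  for (dj in 0:1) for (di in 0:1) {
    k <- k + 1L
    y[, seq(1L + di, 2L * d[2], by = 2L), seq(1L + dj, 2L * d[3], by = 2L), ] <-
      x[seq.int((k - 1L) * c_out + 1L, k * c_out), , , , drop = FALSE]
  }
  y
}

dc_forward <- function(dc, x, training) {
  t <- relu_fwd(layer_forward(dc$b1, layer_forward(dc$c1, x, training),
                              training))$y
  relu_fwd(layer_forward(dc$b2, layer_forward(dc$c2, t, training),
                         training))$y
}

unet_forward <- function(m, x, training = FALSE) {
  check_input(x)
  if (dim(x)[2] %% 16L || dim(x)[3] %% 16L)
    stop("unet_baseline input must be divisible by 16")
  feats <- vector("list", 4L)
  h <- x
  for (i in 1:4) {
    h <- dc_forward(m$enc[[i]], h, training)
    feats[[i]] <- h
    h <- maxpool2_fwd(h)$y
  }
  h <- dc_forward(m$enc[[5]], h, training)
  for (j in 1:4) {
    i <- 5L - j
    u <- pixel_shuffle2(layer_forward(m$ups[[j]], h, training)) +
      m$ups[[j]]$params$b
    d <- fm_dims(u)
    cat_in <- array(0, dim = c(d[1] * 2L, d[2], d[3], d[4]))
    cat_in[seq_len(d[1]), , , ] <- feats[[i]]
    cat_in[d[1] + seq_len(d[1]), , , ] <- u
    h <- dc_forward(m$dec[[j]], cat_in, training)
  }
  sigmoid_fwd(layer_forward(m$head, h, training))$y
}
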