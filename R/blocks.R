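# Building blocks of the network.
#
# LDA blocks (convolution stage): two-part residual units built from 1x1
# channel convolutions, a depthwise 3x3, and a depthwise asymmetric 1x3/3x1
# pair, fused exclusively by elementwise addition. LDA-B additionally applies
# squeeze-and-excitation channel attention between the two parts. All spatial
# work runs at the input resolution; a 2x2 max-pool at the block end performs
# the downsampling when stride = 2.
#
# LMLP block (MLP stage): shifted, tokenized MLP mixing along the width and
# then the height axis, each followed by a depthwise 3x3 convolution, with
# two optional ADD fusions, an outer residual, and layer normalisation at the
# output. The block preserves shape; stage-level channel changes are done by
# an embedding convolution in the network assembly.

new_block <- function(kind, cfg, children) {
  b <- new.env(parent = emptyenv())
  b$kind <- kind
  b$cfg <- cfg
  b$children <- children
  b$cache <- NULL
  class(b) <- "lcm_block"
  b
}

#' Configuration for an LDA block
#'
#' @param in_channels,out_channels channel widths.
#' @param stride 1 (shape preserving) or 2 (2x2 max-pool at the block end).
#' @param use_se apply squeeze-and-excitation after the first fusion
#'   (the LDA-B variant); `FALSE` gives LDA-A.
#' @param se_reduction bottleneck ratio r of the SE module; must divide
#'   `out_channels`.
#' @param kernel_size spatial extent of the depthwise convolutions.
#' @return a list of class `lda_config`.
#' @export
lda_config <- function(in_channels, out_channels, stride = 1L,
                       use_se = FALSE, se_reduction = 2L,
                       kernel_size = 3L) {
  stopifnot(in_channels >= 1, out_channels >= 1, stride %in% c(1L, 2L),
            se_reduction >= 1, kernel_size >= 1)
  if (use_se && out_channels %% se_reduction != 0)
    stop("out_channels (", out_channels, ") must be divisible by ",
         "se_reduction (", se_reduction, ")")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride), use_se = isTRUE(use_se),
                 se_reduction = as.integer(se_reduction),
                 kernel_size = as.integer(kernel_size)),
            class = "lda_config")
}

#' Configuration for an LMLP block
#'
#' @param channels channel width (preserved by the block).
#' @param token_hidden_ratio hidden width of the token MLPs relative to
#'   `channels` (the default 1 ties the hidden width to the channel width,
#'   which the first ADD fusion requires; other values disable that fusion).
#' @param shift_size pixel step of the axial channel-group shift.
#' @param dw_kernel kernel size of the depthwise convolutions.
#' @param enable_add1,enable_add2 the two ADD fusions (token residual and
#'   width-branch carry-over); both on by default.
#' @return a list of class `lmlp_config`.
#' @export
lmlp_config <- function(channels, token_hidden_ratio = 1, shift_size = 1L,
                        dw_kernel = 3L, enable_add1 = TRUE,
                        enable_add2 = TRUE) {
  stopifnot(channels >= 1, token_hidden_ratio > 0, shift_size >= 0)
  hidden <- as.integer(round(token_hidden_ratio * channels))
  if (hidden != channels && enable_add1)
    stop("enable_add1 requires token_hidden_ratio * channels == channels")
  structure(list(channels = as.integer(channels), hidden = hidden,
                 token_hidden_ratio = token_hidden_ratio,
                 shift_size = as.integer(shift_size),
                 dw_kernel = as.integer(dw_kernel),
                 enable_add1 = isTRUE(enable_add1),
                 enable_add2 = isTRUE(enable_add2)),
            class = "lmlp_config")
}

# squeeze-and-excitation -------------------------------------------------------

new_se_module <- function(channels, reduction = 2L) {
  if (channels %% reduction != 0)
    stop("channels must be divisible by the SE reduction")
  hidden <- channels %/% reduction
  new_block("se", list(channels = channels, reduction = reduction),
            list(fc1 = new_linear(channels, hidden),
                 fc2 = new_linear(hidden, channels)))
}

se_forward <- function(b, x, training) {
  ch <- b$children
  g <- gap_fwd(x)
  h <- layer_forward(ch$fc1, g$y)
  hr <- relu_fwd(h)
  s <- layer_forward(ch$fc2, hr$y)
  ss <- sigmoid_fwd(s)
  sc <- scale_channels_fwd(x, ss$y)
  b$cache <- list(gap = g$cache, relu = hr$cache, sig = ss$cache,
                  scale = sc$cache)
  sc$y
}

se_backward <- function(b, dy) {
  ch <- b$children
  cc <- b$cache
  sb <- scale_channels_bwd(cc$scale, dy)
  ds <- sigmoid_bwd(cc$sig, sb$ds)
  dh <- layer_backward(ch$fc2, ds)
  dh <- relu_bwd(cc$relu, dh)
  dz <- layer_backward(ch$fc1, dh)
  sb$dx + gap_bwd(cc$gap, dz)
}

# LDA block --------------------------------------------------------------------

new_lda_block <- function(cfg) {
  stopifnot(inherits(cfg, "lda_config"))
  a <- cfg$in_channels; b <- cfg$out_channels; k <- cfg$kernel_size
  children <- list(
    conv1 = new_conv(a, b),                     # part I 1x1
    bn1   = new_bn(b),
    dw2   = new_dwconv(b, k, k),                # part I depthwise
    bn2   = new_bn(b),
    sc3   = new_conv(a, b),                     # part I shortcut
    bn3   = new_bn(b),
    conv4 = new_conv(b, b),                     # part II 1x1
    bn4   = new_bn(b),
    asym5 = new_dwconv(b, 1L, k),               # 1xk depthwise
    bn5   = new_bn(b),
    asym6 = new_dwconv(b, k, 1L),               # kx1 depthwise
    bn6   = new_bn(b),
    sc7   = new_dwconv(b, k, k),                # part II shortcut
    bn7   = new_bn(b)
  )
  if (cfg$use_se)
    children$se <- new_se_module(b, cfg$se_reduction)
  new_block("lda", cfg, children)
}

lda_forward <- function(blk, x, training = FALSE) {
  cfg <- blk$cfg
  if (dim(x)[1] != cfg$in_channels)
    stop("LDA block expected ", cfg$in_channels, " channels, got ",
         dim(x)[1])
  ch <- blk$children
  cc <- list()
  # part I
  t1 <- layer_forward(ch$bn1, layer_forward(ch$conv1, x, training), training)
  r1 <- relu_fwd(t1); cc$r1 <- r1$cache
  t2 <- layer_forward(ch$bn2, layer_forward(ch$dw2, r1$y, training), training)
  s3 <- layer_forward(ch$bn3, layer_forward(ch$sc3, x, training), training)
  if (!identical(dim(t2), dim(s3)))
    stop("fusion addend shapes disagree in LDA part I")
  r3 <- relu_fwd(t2 + s3); cc$r3 <- r3$cache
  po3 <- r3$y
  if (cfg$use_se) po3 <- se_forward(ch$se, po3, training)
  # part II
  t4 <- layer_forward(ch$bn4, layer_forward(ch$conv4, po3, training), training)
  r4 <- relu_fwd(t4); cc$r4 <- r4$cache
  t5 <- layer_forward(ch$bn5, layer_forward(ch$asym5, r4$y, training), training)
  r5 <- relu_fwd(t5); cc$r5 <- r5$cache
  t6 <- layer_forward(ch$bn6, layer_forward(ch$asym6, r5$y, training), training)
  s7 <- layer_forward(ch$bn7, layer_forward(ch$sc7, po3, training), training)
  if (!identical(dim(t6), dim(s7)))
    stop("fusion addend shapes disagree in LDA part II")
  r7 <- relu_fwd(t6 + s7); cc$r7 <- r7$cache
  # identity residual of the block input (parameter-free channel adapter)
  pc <- pad_channels_fwd(x, cfg$out_channels); cc$pad <- pc$cache
  r8 <- relu_fwd(r7$y + pc$y); cc$r8 <- r8$cache
  y <- r8$y
  if (cfg$stride == 2L) {
    mp <- maxpool2_fwd(y); cc$pool <- mp$cache
    y <- mp$y
  }
  blk$cache <- cc
  y
}

lda_backward <- function(blk, dy) {
  cfg <- blk$cfg
  ch <- blk$children
  cc <- blk$cache
  if (cfg$stride == 2L) dy <- maxpool2_bwd(cc$pool, dy)
  g8 <- relu_bwd(cc$r8, dy)
  dx <- pad_channels_bwd(cc$pad, g8)
  g7 <- relu_bwd(cc$r7, g8)
  # shortcut dw path
  dpo3 <- layer_backward(ch$sc7, layer_backward(ch$bn7, g7))
  # asymmetric path
  g6 <- layer_backward(ch$asym6, layer_backward(ch$bn6, g7))
  g5 <- relu_bwd(cc$r5, g6)
  g5 <- layer_backward(ch$asym5, layer_backward(ch$bn5, g5))
  g4 <- relu_bwd(cc$r4, g5)
  dpo3 <- dpo3 + layer_backward(ch$conv4, layer_backward(ch$bn4, g4))
  if (cfg$use_se) dpo3 <- se_backward(ch$se, dpo3)
  g3 <- relu_bwd(cc$r3, dpo3)
  dx <- dx + layer_backward(ch$sc3, layer_backward(ch$bn3, g3))
  g2 <- layer_backward(ch$dw2, layer_backward(ch$bn2, g3))
  g1 <- relu_bwd(cc$r1, g2)
  dx + layer_backward(ch$conv1, layer_backward(ch$bn1, g1))
}

# LMLP block -------------------------------------------------------------------

new_lmlp_block <- function(cfg) {
  stopifnot(inherits(cfg, "lmlp_config"))
  C <- cfg$channels; h <- cfg$hidden; k <- cfg$dw_kernel
  new_block("lmlp", cfg, list(
    mlp_w = new_conv(C, h, bias = TRUE),        # per-token channel MLP
    dw_w  = new_dwconv(h, k, k, bias = TRUE),
    mlp_h = new_conv(if (cfg$enable_add1) C else h, h, bias = TRUE),
    dw_h  = new_dwconv(h, k, k, bias = TRUE),
    ln    = new_ln(if (cfg$enable_add2 || cfg$enable_add1) C else h)
  ))
}

lmlp_forward <- function(blk, x, training = FALSE) {
  cfg <- blk$cfg
  if (dim(x)[1] != cfg$channels)
    stop("LMLP block expected ", cfg$channels, " channels, got ", dim(x)[1])
  ch <- blk$children
  cc <- list()
  sw <- shift_axis_fwd(x, "w", cfg$shift_size); cc$sw <- sw$cache
  xt <- sw$y                                     # tokenized, width-shifted
  yw1 <- layer_forward(ch$mlp_w, xt, training)
  yw2g <- gelu_fwd(layer_forward(ch$dw_w, yw1, training)); cc$gw <- yw2g$cache
  yw3 <- if (cfg$enable_add1) yw2g$y + xt else yw2g$y
  sh <- shift_axis_fwd(yw3, "h", cfg$shift_size); cc$sh <- sh$cache
  yh1 <- layer_forward(ch$mlp_h, sh$y, training)
  yh2g <- gelu_fwd(layer_forward(ch$dw_h, yh1, training)); cc$gh <- yh2g$cache
  yh3 <- if (cfg$enable_add2) yw3 + yh2g$y else yh2g$y
  y <- layer_forward(ch$ln, x + yh3, training)
  blk$cache <- cc
  y
}

lmlp_backward <- function(blk, dy) {
  cfg <- blk$cfg
  ch <- blk$children
  cc <- blk$cache
  g <- layer_backward(ch$ln, dy)
  dx <- g                                        # outer residual
  dyh3 <- g
  dyh2 <- gelu_bwd(cc$gh, dyh3)
  dsh <- layer_backward(ch$mlp_h, layer_backward(ch$dw_h, dyh2))
  dyw3 <- shift_axis_bwd(cc$sh, dsh)
  if (cfg$enable_add2) dyw3 <- dyw3 + dyh3
  dyw2 <- gelu_bwd(cc$gw, dyw3)
  dxt <- layer_backward(ch$mlp_w, layer_backward(ch$dw_w, dyw2))
  if (cfg$enable_add1) dxt <- dxt + dyw3
  dx + shift_axis_bwd(cc$sw, dxt)
}

# standalone primitives ---------------------------------------------------------

# Depthwise separable convolution: per-channel kxk then 1x1 pointwise, each
# followed by batch normalisation.
new_dwsep_block <- function(cin, cout, k = 3L) {
  new_block("dwsep", list(cin = cin, cout = cout, k = k), list(
    dw = new_dwconv(cin, k, k), bn1 = new_bn(cin),
    pw = new_conv(cin, cout), bn2 = new_bn(cout)))
}

dwsep_forward <- function(blk, x, training = FALSE) {
  if (dim(x)[1] != blk$cfg$cin)
    stop("expected ", blk$cfg$cin, " channels, got ", dim(x)[1])
  ch <- blk$children
  t <- layer_forward(ch$bn1, layer_forward(ch$dw, x, training), training)
  layer_forward(ch$bn2, layer_forward(ch$pw, t, training), training)
}

dwsep_backward <- function(blk, dy) {
  ch <- blk$children
  g <- layer_backward(ch$pw, layer_backward(ch$bn2, dy))
  layer_backward(ch$dw, layer_backward(ch$bn1, g))
}

# Full (non-depthwise) asymmetric pair: 1xk then kx1 convolution over all
# channel combinations, with optional batch norms.
new_asym_pair_block <- function(channels, k = 3L, bn = TRUE) {
  ch <- list(c13 = new_conv(channels, channels, 1L, k))
  if (bn) ch$bn1 <- new_bn(channels)
  ch$c31 <- new_conv(channels, channels, k, 1L)
  if (bn) ch$bn2 <- new_bn(channels)
  new_block("asym_pair", list(channels = channels, k = k, bn = bn), ch)
}

asym_pair_forward <- function(blk, x, training = FALSE) {
  if (dim(x)[1] != blk$cfg$channels)
    stop("expected ", blk$cfg$channels, " channels, got ", dim(x)[1])
  ch <- blk$children
  t <- layer_forward(ch$c13, x, training)
  if (blk$cfg$bn) t <- layer_forward(ch$bn1, t, training)
  t <- layer_forward(ch$c31, t, training)
  if (blk$cfg$bn) t <- layer_forward(ch$bn2, t, training)
  t
}

asym_pair_backward <- function(blk, dy) {
  ch <- blk$children
  g <- dy
  if (blk$cfg$bn) g <- layer_backward(ch$bn2, g)
  g <- layer_backward(ch$c31, g)
  if (blk$cfg$bn) g <- layer_backward(ch$bn1, g)
  layer_backward(ch$c13, g)
}

# dispatch ----------------------------------------------------------------------

#' Run a block forward
#'
#' Applies one building block (LDA-A/LDA-B, LMLP, SE, or one of the
#' standalone primitives) to a `(C, H, W, N)` feature map.
#'
#' @param block a block created by [new_block_module()].
#' @param x feature map array, see [feature_map()].
#' @param training logical; use batch statistics and record caches for the
#'   backward pass.
#' @return the output feature map.
#' @export
block_forward <- function(block, x, training = FALSE) {
  switch(block$kind,
    lda = lda_forward(block, x, training),
    lmlp = lmlp_forward(block, x, training),
    se = se_forward(block, x, training),
    dwsep = dwsep_forward(block, x, training),
    asym_pair = asym_pair_forward(block, x, training),
    stop("unknown block kind ", block$kind))
}

block_backward <- function(block, dy) {
  switch(block$kind,
    lda = lda_backward(block, dy),
    lmlp = lmlp_backward(block, dy),
    se = se_backward(block, dy),
    dwsep = dwsep_backward(block, dy),
    asym_pair = asym_pair_backward(block, dy),
    stop("unknown block kind ", block$kind))
}

#' Construct a building block
#'
#' User-facing constructor for the network's building blocks. `"lda_a"` and
#' `"lda_b"` take an [lda_config()] (LDA-B forces the SE module on),
#' `"lmlp"` takes an [lmlp_config()]; `"dwsep"` and `"asym_pair"` build the
#' standalone depthwise-separable and full asymmetric-pair primitives.
#'
#' @param kind one of `"lda_a"`, `"lda_b"`, `"lmlp"`, `"dwsep"`,
#'   `"asym_pair"`.
#' @param cfg the matching configuration object, or for the primitives a
#'   list with fields `cin`/`cout`/`k` (`dwsep`) or `channels`/`k`/`bn`
#'   (`asym_pair`).
#' @return a block object usable with [block_forward()] and
#'   [count_parameters()].
#' @export
new_block_module <- function(kind, cfg) {
  switch(kind,
    lda_a = {
      if (cfg$use_se) stop("lda_a must have use_se = FALSE")
      new_lda_block(cfg)
    },
    lda_b = {
      if (!cfg$use_se) stop("lda_b requires use_se = TRUE")
      new_lda_block(cfg)
    },
    lmlp = new_lmlp_block(cfg),
    dwsep = new_dwsep_block(cfg$cin, cfg$cout, cfg$k %||% 3L),
    asym_pair = new_asym_pair_block(cfg$channels, cfg$k %||% 3L,
                                    cfg$bn %||% TRUE),
    stop("unknown block kind ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
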