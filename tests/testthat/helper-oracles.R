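# Independent closed-form parameter/FLOP counting oracles, derived from the
# block definitions on paper, written separately from the package's
# enumeration/walking code. Used to pin every block and variant count.

# squeeze-and-excitation: two biased linears C -> C/r -> C
oracle_se_params <- function(C, r) {
  h <- C %/% r
  C * h + h + h * C + C
}

# LDA block: 1x1 (a->b), depthwise kxk, 1x1 shortcut (a->b), 1x1 (b->b),
# depthwise 1xk + kx1, depthwise kxk shortcut; 7 batch norms; SE optional.
oracle_lda_params <- function(a, b, use_se = FALSE, r = 2L, k = 3L) {
  conv_w <- a * b + a * b + b * b
  dw_w <- k * k * b + k * b + k * b + k * k * b
  bn <- 7L * 2L * b
  tot <- conv_w + dw_w + bn
  if (use_se) tot <- tot + oracle_se_params(b, r)
  tot
}

# LMLP mixing block: two biased 1x1 token MLPs (C->C), two biased depthwise
# kxk convolutions, one layer norm.
oracle_lmlp_block_params <- function(C, k = 3L) {
  2L * (C * C + C) + 2L * (k * k * C + C) + 2L * C
}

STAGE_AB <- list(
  c(3, 16), c(16, 32), c(32, 128), c(128, 160), c(160, 256),
  c(256, 160), c(160, 128), c(128, 32), c(32, 16), c(16, 3))

oracle_stage_params <- function(i, kind, r = 2L) {
  a <- STAGE_AB[[i]][1]; b <- STAGE_AB[[i]][2]
  if (kind == "lmlp") {
    embed <- if (i <= 5) 9L * a * b + b + 2L * b    # conv+bias, layer norm
    else 9L * a * b + 2L * b                        # conv + batch norm
    embed + oracle_lmlp_block_params(b)
  } else {
    oracle_lda_params(a, b, use_se = kind == "lda_b", r = r)
  }
}

oracle_variant_params <- function(kinds, r = 2L) {
  skips <- sum(vapply(c(16, 32, 128, 160),
                      function(c) c * c + 2L * c, 0))
  head <- 3L + 1L
  sum(vapply(seq_along(kinds),
             function(i) oracle_stage_params(i, kinds[i], r), 0)) +
    skips + head
}

VARIANT_KINDS_ORACLE <- list(
  lcmunet         = c("lda_a", "lda_b", "lda_b", "lmlp", "lmlp",
                      "lmlp", "lmlp", "lda_b", "lda_b", "lda_a"),
  all_lda_a       = rep("lda_a", 10),
  lda_a_plus_b    = c("lda_a", rep("lda_b", 8), "lda_a"),
  lda_a_plus_lmlp = c("lda_a", "lda_a", "lda_a", "lmlp", "lmlp",
                      "lmlp", "lmlp", "lda_a", "lda_a", "lda_a"))

# classic UNet: double 3x3 convs (bias-free + BN), 2x2 transposed-conv
# decoder with bias, 1x1 single-logit head
oracle_unet_params <- function() {
  w <- c(64, 128, 256, 512, 1024)
  dc <- function(a, b) 9 * a * b + 9 * b * b + 4 * b
  enc <- dc(3, w[1]) + dc(w[1], w[2]) + dc(w[2], w[3]) +
    dc(w[3], w[4]) + dc(w[4], w[5])
  ups <- sum(4 * w[2:5] * w[1:4] + w[1:4])
  dec <- dc(2 * w[4], w[4]) + dc(2 * w[3], w[3]) + dc(2 * w[2], w[2]) +
    dc(2 * w[1], w[1])
  enc + ups + dec + (w[1] + 1)
}

# MAC-count oracle for the canonical model, derived stage by stage from the
# architecture description (conv and linear layers only).
oracle_lcmunet_flops <- function(s = 256) {
  lda_f <- function(a, b, res) (2 * a * b + b * b + 24 * b) * res^2
  se_f <- function(b, r = 2) 2 * b * (b %/% r)
  mlp_block_f <- function(C, res) (2 * C * C + 18 * C) * res^2
  f <- lda_f(3, 16, s) +                               # stage 1
    lda_f(16, 32, s / 2) + se_f(32) +                  # stage 2
    lda_f(32, 128, s / 4) + se_f(128) +                # stage 3
    9 * 128 * 160 * (s / 16)^2 + mlp_block_f(160, s / 16) +
    9 * 160 * 256 * (s / 32)^2 + mlp_block_f(256, s / 32) +
    9 * 256 * 160 * (s / 32)^2 + mlp_block_f(160, s / 16) +
    9 * 160 * 128 * (s / 16)^2 + mlp_block_f(128, s / 8) +
    lda_f(128, 32, s / 8) + se_f(32) +
    lda_f(32, 16, s / 4) + se_f(16) +
    lda_f(16, 3, s / 2)
  skips <- 160^2 * (s / 16)^2 + 128^2 * (s / 8)^2 +
    32^2 * (s / 4)^2 + 16^2 * (s / 2)^2
  f + skips + 3 * s^2
}
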