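# Parameter and FLOP accounting.
#
# Parameters are counted by enumerating every trainable array in the built
# model (convolution and linear weights and biases, batch/layer norm scales
# and shifts); batch-norm running statistics are state, not parameters.
#
# FLOPs use the multiply-accumulate convention (1 MAC = 1 FLOP) over
# convolutions and linear layers only, at the resolution each layer actually
# runs at; normalisation, activations, pooling, interpolation and
# elementwise fusions are excluded, matching how lightweight-segmentation
# models are conventionally profiled.

#' Count trainable parameters
#'
#' @param model a built model, a single block, or any nested structure of
#'   layers.
#' @return integer scalar: the exact number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_layers(model), layer_n_params, 0))
}

conv_flops <- function(l, hw_out) {
  m <- l$meta
  m$kh * m$kw * m$cin * m$cout * hw_out
}

dw_flops <- function(l, hw_out) {
  m <- l$meta
  m$kh * m$kw * m$cin * hw_out
}

lda_stage_flops <- function(st, res_in) {
  hw <- res_in^2
  ch <- st$block$children
  f <- conv_flops(ch$conv1, hw) + dw_flops(ch$dw2, hw) +
    conv_flops(ch$sc3, hw) + conv_flops(ch$conv4, hw) +
    dw_flops(ch$asym5, hw) + dw_flops(ch$asym6, hw) + dw_flops(ch$sc7, hw)
  if (!is.null(ch$se)) {
    se <- ch$se$children
    f <- f + se$fc1$meta$cin * se$fc1$meta$cout +
      se$fc2$meta$cin * se$fc2$meta$cout
  }
  f
}

lmlp_block_flops <- function(blk, res) {
  hw <- res^2
  ch <- blk$children
  conv_flops(ch$mlp_w, hw) + dw_flops(ch$dw_w, hw) +
    conv_flops(ch$mlp_h, hw) + dw_flops(ch$dw_h, hw)
}

#' Count forward-pass FLOPs
#'
#' Multiply-accumulate count of one forward pass at a stated input size,
#' reported in raw MACs; divide by 1e9 for the GFLOP figure usually quoted.
#'
#' @param model a built model.
#' @param input_size spatial input extent (single integer, square input),
#'   divisible by 32.
#' @return numeric scalar, total MACs.
#' @export
count_flops <- function(model, input_size = 256L) {
  s <- as.integer(input_size)
  if (s %% 32L) stop("input_size must be divisible by 32")
  if (model$variant == "unet_baseline") return(unet_flops(model, s))
  # resolution at which each block stage's operations run
  enc_res <- c(s, s / 2, s / 4)                   # LDA stages pre-pool
  f <- 0
  for (i in 1:5) {
    st <- model$stages[[i]]
    if (st$kind == "lmlp") {
      r_out <- s / 2^i
      f <- f + conv_flops(st$embed, r_out^2) +
        lmlp_block_flops(st$block, r_out)
    } else {
      r_in <- s / 2^(i - 1)
      f <- f + lda_stage_flops(st, r_in)
    }
  }
  for (i in 6:10) {
    st <- model$stages[[i]]
    r_in <- s / 2^(10 - i + 1)                    # 8, 16, 32, 64, 128 at 256
    if (st$kind == "lmlp") {
      f <- f + conv_flops(st$reduce, r_in^2) +
        lmlp_block_flops(st$block, 2 * r_in)      # block after up + fusion
    } else {
      f <- f + lda_stage_flops(st, r_in)
    }
  }
  skip_res <- c(s / 2, s / 4, s / 8, s / 16)
  for (k in 1:4)
    f <- f + conv_flops(model$skips[[k]]$conv, skip_res[k]^2)
  f + conv_flops(model$head, s^2)
}

unet_flops <- function(m, s) {
  f <- 0
  res <- c(s, s / 2, s / 4, s / 8, s / 16)
  for (i in 1:5) {
    dc <- m$enc[[i]]
    f <- f + conv_flops(dc$c1, res[i]^2) + conv_flops(dc$c2, res[i]^2)
  }
  for (j in 1:4) {
    r <- res[5 - j]                               # decoder output resolution
    f <- f + 4 * m$ups[[j]]$meta$cin * m$ups[[j]]$meta$cout_eff * r^2 / 4
    dc <- m$dec[[j]]
    f <- f + conv_flops(dc$c1, r^2) + conv_flops(dc$c2, r^2)
  }
  f + conv_flops(m$head, s^2)
}

#' Complexity report for one model
#'
#' @param model a built model.
#' @param input_size spatial input extent for the FLOP count.
#' @return a list of class `complexity_report` with the exact parameter
#'   count, the count in millions (2 decimals), GFLOPs, and per-stage
#'   parameter breakdown.
#' @export
complexity_report <- function(model, input_size = 256L) {
  p <- count_parameters(model)
  fl <- count_flops(model, input_size)
  by_stage <- if (model$variant == "unet_baseline") NULL else
    setNames(vapply(model$stages, function(st)
      count_parameters(stage_children(st)), 0),
      paste0("stage", seq_along(model$stages)))
  structure(list(variant = model$variant, params = p,
                 params_M = round(p / 1e6, 2),
                 gflops = fl / 1e9, input_size = c(input_size, input_size),
                 params_by_stage = by_stage),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("%s @ %dx%d: %s params (%.2f M), %.3f GFLOPs\n",
              x$variant, x$input_size[1], x$input_size[2],
              format(x$params, big.mark = ","), x$params_M, x$gflops))
  invisible(x)
}

#' Complexity table over variants
#'
#' Builds each named variant and tabulates parameters and FLOPs, one row
#' per entry (duplicates allowed and reported as identical rows).
#'
#' @param variants character vector of variant names.
#' @param input_size spatial input extent.
#' @param se_reduction SE ratio passed to the builders.
#' @return a data.frame with columns `variant`, `params`, `params_M`,
#'   `gflops`, `input_size`.
#' @export
complexity_table <- function(variants, input_size = 256L,
                             se_reduction = 2L) {
  rows <- lapply(variants, function(v) {
    r <- complexity_report(build_variant(v, se_reduction = se_reduction),
                           input_size)
    data.frame(variant = v, params = r$params, params_M = r$params_M,
               gflops = round(r$gflops, 2), input_size = input_size)
  })
  if (!length(rows))
    return(data.frame(variant = character(), params = numeric(),
                      params_M = numeric(), gflops = numeric(),
                      input_size = integer()))
  do.call(rbind, rows)
}
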