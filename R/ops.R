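#' @useDynLib lcmunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif dnorm pnorm setNames
NULL

# ---------------------------------------------------------------------------
# Feature maps are numeric arrays with dim (C, H, W, N): channel first, so a
# length-C vector recycles per channel and the compiled kernels see contiguous
# channel runs. Every op here is a pure fwd/bwd pair; layer state lives in the
# layer objects (layers.R).
# ---------------------------------------------------------------------------

#' Create a feature map array
#'
#' Convenience constructor for the (channel, height, width, batch) array
#' layout used throughout the package.
#'
#' @param values numeric vector or array of length `prod(c, h, w, n)`.
#' @param c,h,w,n channel, height, width and batch extents.
#' @return a numeric array with `dim = c(c, h, w, n)`.
#' @export
feature_map <- function(values, c, h, w, n = 1L) {
  stopifnot(c > 0, h > 0, w > 0, n > 0)
  x <- array(as.double(values), dim = c(c, h, w, n))
  if (any(!is.finite(x))) stop("feature map values must be finite")
  x
}

fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("expected a (C, H, W, N) feature map array")
  d
}

# elementwise activations ----------------------------------------------------

relu_fwd <- function(x) {
  y <- .relu_fwd_cpp(x)
  list(y = y, cache = y)          # y > 0 iff x > 0
}
relu_bwd <- function(cache, dy) .relu_bwd_cpp(cache, dy)

gelu_fwd <- function(x) {
  ph <- pnorm(x)
  list(y = x * ph, cache = list(x = x, ph = ph))
}
gelu_bwd <- function(cache, dy) {
  dy * (cache$ph + cache$x * dnorm(cache$x))
}

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}
sigmoid_bwd <- function(cache, dy) dy * cache * (1 - cache)

# spatial ops ----------------------------------------------------------------

maxpool2_fwd <- function(x) {
  d <- fm_dims(x)
  if (d[2] %% 2L || d[3] %% 2L)
    stop("max pooling requires even spatial extents, got ",
         d[2], "x", d[3])
  r <- .maxpool2_fwd_cpp(x, as.integer(d))
  list(y = r$y, cache = list(amax = r$amax, dims = d))
}
maxpool2_bwd <- function(cache, dy) {
  .maxpool2_bwd_cpp(dy, cache$amax, as.integer(cache$dims))
}

bilinear_up2_fwd <- function(x) {
  d <- fm_dims(x)
  list(y = .bilinear_up2_fwd_cpp(x, as.integer(d)), cache = d)
}
bilinear_up2_bwd <- function(cache, dy) {
  .bilinear_up2_bwd_cpp(dy, as.integer(cache))
}

# Parameter-free channel adapter for identity shortcuts: zero-pads when the
# target width is larger, truncates when smaller.
pad_channels_fwd <- function(x, c_out) {
  d <- fm_dims(x)
  c_in <- d[1]
  if (c_in == c_out) return(list(y = x, cache = list(c_in = c_in, d = d)))
  y <- array(0, dim = c(c_out, d[2], d[3], d[4]))
  k <- min(c_in, c_out)
  y[seq_len(k), , , ] <- x[seq_len(k), , , , drop = FALSE]
  list(y = y, cache = list(c_in = c_in, d = d))
}
pad_channels_bwd <- function(cache, dy) {
  c_in <- cache$c_in
  c_out <- dim(dy)[1]
  if (c_in == c_out) return(dy)
  dx <- array(0, dim = cache$d)
  k <- min(c_in, c_out)
  dx[seq_len(k), , , ] <- dy[seq_len(k), , , , drop = FALSE]
  dx
}

# Axial channel-group shift: channels split into `groups` contiguous groups,
# group g displaced by offset[g] pixels along the chosen axis; vacated
# positions are zero-filled. Linear, so backward is the opposite shift.
shift_offsets <- function(channels, groups, shift_size) {
  sizes <- rep(channels %/% groups, groups)
  extra <- channels %% groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  offs <- (seq_len(groups) - (groups + 1L) / 2)
  offs <- round(offs) * shift_size
  list(sizes = sizes, offsets = as.integer(offs))
}

shift_axis_fwd <- function(x, axis = c("w", "h"), shift_size = 1L,
                           groups = 5L) {
  axis <- match.arg(axis)
  d <- fm_dims(x)
  # clamp so the largest group offset stays inside the map; on very small
  # maps the shift degrades gracefully to the identity
  extent <- d[if (axis == "w") 3 else 2]
  max_mult <- (groups - 1L) %/% 2L
  if (max_mult > 0L && abs(shift_size) * max_mult >= extent)
    shift_size <- sign(shift_size) * ((extent - 1L) %/% max_mult)
  sp <- shift_offsets(d[1], groups, shift_size)
  y <- array(0, dim = d)
  c0 <- 0L
  for (g in seq_along(sp$sizes)) {
    ch <- c0 + seq_len(sp$sizes[g]); c0 <- c0 + sp$sizes[g]
    o <- sp$offsets[g]
    if (o == 0L) { y[ch, , , ] <- x[ch, , , , drop = FALSE]; next }
    if (axis == "w") {
      n <- d[3]
      if (o > 0) y[ch, , (1 + o):n, ] <- x[ch, , 1:(n - o), , drop = FALSE]
      else       y[ch, , 1:(n + o), ] <- x[ch, , (1 - o):n, , drop = FALSE]
    } else {
      n <- d[2]
      if (o > 0) y[ch, (1 + o):n, , ] <- x[ch, 1:(n - o), , , drop = FALSE]
      else       y[ch, 1:(n + o), , ] <- x[ch, (1 - o):n, , , drop = FALSE]
    }
  }
  list(y = y, cache = list(axis = axis, shift_size = shift_size,
                           groups = groups))
}
shift_axis_bwd <- function(cache, dy) {
  shift_axis_fwd(dy, axis = cache$axis, shift_size = -cache$shift_size,
                 groups = cache$groups)$y
}

# reductions ------------------------------------------------------------------

# Global average pool: (C,H,W,N) -> (C,N) matrix.
gap_fwd <- function(x) {
  d <- fm_dims(x)
  m <- matrix(x, nrow = d[1])                 # C x (H W N)
  z <- matrix(0, d[1], d[4])
  hw <- d[2] * d[3]
  for (n in seq_len(d[4]))
    z[, n] <- rowMeans(m[, ((n - 1) * hw + 1):(n * hw), drop = FALSE])
  list(y = z, cache = d)
}
gap_bwd <- function(cache, dz) {
  d <- cache
  hw <- d[2] * d[3]
  dx <- array(0, dim = d)
  for (n in seq_len(d[4]))
    dx[, , , n] <- rep(dz[, n] / hw, times = hw)
  dx
}

# per-channel scale: y = x * s (s is C x N)
scale_channels_fwd <- function(x, s) {
  d <- fm_dims(x)
  hw <- d[2] * d[3]
  sfull <- array(0, dim = d)
  for (n in seq_len(d[4])) sfull[, , , n] <- rep(s[, n], times = hw)
  list(y = x * sfull, cache = list(x = x, sfull = sfull, d = d))
}
scale_channels_bwd <- function(cache, dy) {
  d <- cache$d
  hw <- d[2] * d[3]
  dx <- dy * cache$sfull
  g <- dy * cache$x
  m <- matrix(g, nrow = d[1])
  ds <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4]))
    ds[, n] <- rowSums(m[, ((n - 1) * hw + 1):(n * hw), drop = FALSE])
  list(dx = dx, ds = ds)
}
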