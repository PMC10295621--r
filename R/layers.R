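# Trainable layers. Each layer is a small environment holding its weights,
# gradients and forward cache; blocks (blocks.R) compose them and orchestrate
# the branch/fusion topology. Convolutions are bias-free wherever a batch
# norm follows (the norm's shift absorbs the bias).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

new_layer <- function(type, meta, params) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$meta <- meta
  l$params <- params
  l$grads <- NULL
  l$cache <- NULL
  class(l) <- "lcm_layer"
  l
}

he_init <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

#' @noRd
new_conv <- function(cin, cout, kh = 1L, kw = 1L, stride = 1L,
                     bias = FALSE, pad = NULL) {
  if (is.null(pad)) pad <- c((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
  W <- matrix(he_init(cin * kh * kw * cout, kh * kw * cin),
              nrow = cin * kh * kw, ncol = cout)
  params <- list(W = W)
  if (bias) params$b <- numeric(cout)
  new_layer("conv",
            list(cin = cin, cout = cout, kh = kh, kw = kw,
                 stride = stride, pad = pad, bias = bias),
            params)
}

new_dwconv <- function(c, kh = 3L, kw = 3L, bias = FALSE) {
  params <- list(W = array(he_init(c * kh * kw, kh * kw), dim = c(c, kh, kw)))
  if (bias) params$b <- numeric(c)
  new_layer("dwconv", list(cin = c, cout = c, kh = kh, kw = kw,
                           stride = 1L, bias = bias), params)
}

new_bn <- function(c) {
  l <- new_layer("bn", list(cin = c, cout = c),
                 list(gamma = rep(1, c), beta = numeric(c)))
  l$running_mean <- numeric(c)
  l$running_var <- rep(1, c)
  l
}

new_ln <- function(c) {
  new_layer("ln", list(cin = c, cout = c),
            list(gamma = rep(1, c), beta = numeric(c)))
}

new_linear <- function(cin, cout, bias = TRUE) {
  params <- list(W = matrix(he_init(cout * cin, cin), cout, cin))
  if (bias) params$b <- numeric(cout)
  new_layer("linear", list(cin = cin, cout = cout, bias = bias), params)
}

# forward / backward ---------------------------------------------------------

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = {
      m <- l$meta
      y <- .conv2d_fwd_cpp(x, as.integer(fm_dims(x)), l$params$W,
                           m$kh, m$kw, m$stride, m$pad[1], m$pad[2])
      if (m$bias) y <- y + l$params$b
      l$cache <- x
      y
    },
    dwconv = {
      m <- l$meta
      y <- .dwconv_fwd_cpp(x, as.integer(fm_dims(x)), l$params$W, m$kh, m$kw)
      if (m$bias) y <- y + l$params$b
      l$cache <- x
      y
    },
    bn = bn_forward(l, x, training),
    ln = ln_forward(l, x),
    linear = {
      y <- l$params$W %*% x
      if (!is.null(l$params$b)) y <- y + l$params$b
      l$cache <- x
      y
    },
    stop("unknown layer type ", l$type)
  )
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      m <- l$meta
      x <- l$cache
      r <- .conv2d_bwd_cpp(x, as.integer(fm_dims(x)), l$params$W, dy,
                           m$kh, m$kw, m$stride, m$pad[1], m$pad[2])
      l$grads <- list(W = r$dw)
      if (m$bias) l$grads$b <- rowSums(matrix(dy, nrow = m$cout))
      r$dx
    },
    dwconv = {
      m <- l$meta
      x <- l$cache
      r <- .dwconv_bwd_cpp(x, as.integer(fm_dims(x)), l$params$W, dy,
                           m$kh, m$kw)
      l$grads <- list(W = r$dw)
      if (m$bias) l$grads$b <- rowSums(matrix(dy, nrow = m$cout))
      r$dx
    },
    bn = bn_backward(l, dy),
    ln = ln_backward(l, dy),
    linear = {
      l$grads <- list(W = dy %*% t(l$cache))
      if (!is.null(l$params$b)) l$grads$b <- rowSums(dy)
      t(l$params$W) %*% dy
    },
    stop("unknown layer type ", l$type)
  )
}

# batch normalisation over (H, W, N) per channel ------------------------------

bn_forward <- function(l, x, training) {
  d <- fm_dims(x)
  r <- .bn_fwd_cpp(x, as.integer(d), l$params$gamma, l$params$beta,
                   l$running_mean, l$running_var, training, BN_EPS)
  if (training) {
    l$running_mean <- (1 - BN_MOMENTUM) * l$running_mean +
      BN_MOMENTUM * r$mu
    l$running_var <- (1 - BN_MOMENTUM) * l$running_var + BN_MOMENTUM * r$va
  }
  l$cache <- list(xhat = r$xhat, inv_sd = r$inv_sd, d = d,
                  training = training)
  r$y
}

bn_backward <- function(l, dy) {
  cc <- l$cache
  r <- .bn_bwd_cpp(cc$xhat, cc$inv_sd, l$params$gamma, dy,
                   as.integer(cc$d), cc$training)
  l$grads <- list(gamma = r$dgamma, beta = r$dbeta)
  r$dx
}

# layer normalisation over channels at each spatial position ------------------

ln_forward <- function(l, x) {
  d <- fm_dims(x)
  C <- d[1]
  m <- matrix(x, nrow = C)
  mu <- colMeans(m)
  va <- colMeans(m * m) - mu * mu
  inv_sd <- 1 / sqrt(va + BN_EPS)
  xhat <- (m - rep(mu, each = C)) * rep(inv_sd, each = C)
  y <- array(xhat * l$params$gamma + l$params$beta, dim = d)
  l$cache <- list(xhat = xhat, inv_sd = inv_sd, d = d)
  y
}

ln_backward <- function(l, dy) {
  cc <- l$cache
  C <- cc$d[1]
  mdy <- matrix(dy, nrow = C)
  l$grads <- list(gamma = rowSums(mdy * cc$xhat), beta = rowSums(mdy))
  dxhat <- mdy * l$params$gamma
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * cc$xhat)
  dx <- (dxhat - rep(mean_dxhat, each = C) -
           cc$xhat * rep(mean_dxhat_xhat, each = C)) *
    rep(cc$inv_sd, each = C)
  array(dx, dim = cc$d)
}

# parameter bookkeeping -------------------------------------------------------

layer_n_params <- function(l) sum(vapply(l$params, length, 0L))

# Recursively collect primitive layers from a nested module structure.
collect_layers <- function(mod) {
  if (inherits(mod, "lcm_layer")) return(list(mod))
  if (is.list(mod)) return(unlist(lapply(mod, collect_layers),
                                  recursive = FALSE))
  if (is.environment(mod) && !is.null(mod$children))
    return(collect_layers(mod$children))
  list()
}
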