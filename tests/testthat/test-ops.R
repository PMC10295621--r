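# Tensor primitives: forward semantics and hand-derived backward passes
# against central finite differences.

test_that("convolution kernels match direct computation and gradcheck", {
  set.seed(1)
  # 3x3 stride-1 conv vs naive R triple loop on a tiny map
  x <- rand_fm(2, 5, 4)
  l <- lcmunet:::new_conv(2L, 3L, 3L, 3L)
  y <- lcmunet:::layer_forward(l, x)
  Warr <- array(l$params$W, dim = c(2, 3, 3, 3))   # (cin, ki, kj, cout)
  naive <- array(0, dim = c(3, 5, 4, 1))
  for (co in 1:3) for (i in 1:5) for (j in 1:4) {
    acc <- 0
    for (ci in 1:2) for (ki in 1:3) for (kj in 1:3) {
      si <- i + ki - 2; sj <- j + kj - 2
      if (si >= 1 && si <= 5 && sj >= 1 && sj <= 4)
        acc <- acc + Warr[ci, ki, kj, co] * x[ci, si, sj, 1]
    }
    naive[co, i, j, 1] <- acc
  }
  expect_equal(y, naive, tolerance = 1e-12)

  # stride-2 output shape
  l2 <- lcmunet:::new_conv(2L, 4L, 3L, 3L, stride = 2L)
  expect_equal(dim(lcmunet:::layer_forward(l2, rand_fm(2, 8, 8))),
               c(4, 4, 4, 1))

  # gradient wrt input and weights
  l3 <- lcmunet:::new_conv(3L, 2L, 3L, 3L, stride = 2L, bias = TRUE)
  x3 <- rand_fm(3, 6, 6, 2)
  dy <- NULL
  val <- function() {
    y <- lcmunet:::layer_forward(l3, x3)
    if (is.null(dy)) dy <<- array(rnorm(length(y)), dim = dim(y))
    sum(y * dy)
  }
  invisible(val())
  dx <- lcmunet:::layer_backward(l3, dy)
  expect_true(fd_check(val, function() x3, function(v) x3 <<- v, dx))
  expect_true(fd_check(val, function() l3$params$W,
                       function(v) l3$params$W <<- v, l3$grads$W))
  expect_true(fd_check(val, function() l3$params$b,
                       function(v) l3$params$b <<- v, l3$grads$b))
})

test_that("depthwise kernels (square and asymmetric) pass gradcheck", {
  set.seed(2)
  for (kk in list(c(3L, 3L), c(1L, 3L), c(3L, 1L))) {
    l <- lcmunet:::new_dwconv(4L, kk[1], kk[2], bias = TRUE)
    x <- rand_fm(4, 6, 5, 2)
    dy <- NULL
    val <- function() {
      y <- lcmunet:::layer_forward(l, x)
      if (is.null(dy)) dy <<- array(rnorm(length(y)), dim = dim(y))
      sum(y * dy)
    }
    invisible(val())
    dx <- lcmunet:::layer_backward(l, dy)
    expect_true(fd_check(val, function() x, function(v) x <<- v, dx))
    expect_true(fd_check(val, function() l$params$W,
                         function(v) l$params$W <<- v, l$grads$W))
  }
  # depthwise delta kernel (centre 1) is the identity
  l <- lcmunet:::new_dwconv(3L, 3L, 3L)
  l$params$W[] <- 0
  l$params$W[, 2, 2] <- 1
  x <- rand_fm(3, 5, 5)
  expect_equal(lcmunet:::layer_forward(l, x), x)
})

test_that("normalisation layers normalise and pass gradcheck", {
  set.seed(3)
  for (mk in list(lcmunet:::new_bn, lcmunet:::new_ln)) {
    l <- mk(5L)
    x <- rand_fm(5, 4, 4, 3) * 2 + 1
    y <- lcmunet:::layer_forward(l, x, training = TRUE)
    expect_equal(mean(y), 0, tolerance = 1e-6)
    dy <- NULL
    val <- function() {
      y <- lcmunet:::layer_forward(l, x, training = TRUE)
      if (is.null(dy)) dy <<- array(rnorm(length(y)), dim = dim(y))
      sum(y * dy)
    }
    invisible(val())
    dx <- lcmunet:::layer_backward(l, dy)
    expect_true(fd_check(val, function() x, function(v) x <<- v, dx,
                         eps = 1e-5))
    expect_true(fd_check(val, function() l$params$gamma,
                         function(v) l$params$gamma <<- v, l$grads$gamma))
  }
  # batch norm eval mode uses running statistics deterministically
  l <- lcmunet:::new_bn(2L)
  x <- rand_fm(2, 4, 4)
  invisible(lcmunet:::layer_forward(l, x, training = TRUE))
  y1 <- lcmunet:::layer_forward(l, x, training = FALSE)
  y2 <- lcmunet:::layer_forward(l, x, training = FALSE)
  expect_identical(y1, y2)
})

test_that("pooling, upsampling, shift and channel padding are exact linear ops", {
  set.seed(4)
  # max pool picks maxima and routes gradient to the argmax
  x <- rand_fm(2, 4, 4)
  r <- lcmunet:::maxpool2_fwd(x)
  expect_equal(r$y[1, 1, 1, 1], max(x[1, 1:2, 1:2, 1]))
  expect_true(op_gradcheck(lcmunet:::maxpool2_fwd, lcmunet:::maxpool2_bwd,
                           rand_fm(3, 6, 6, 2)))
  expect_error(lcmunet:::maxpool2_fwd(rand_fm(1, 5, 4)), "even")

  # bilinear x2: constant maps stay constant; backward is the exact adjoint
  cst <- array(2.5, dim = c(1, 3, 3, 1))
  expect_equal(lcmunet:::bilinear_up2_fwd(cst)$y,
               array(2.5, dim = c(1, 6, 6, 1)))
  x <- rand_fm(2, 3, 4)
  dy <- rand_fm(2, 6, 8)
  fwd_y <- lcmunet:::bilinear_up2_fwd(x)$y
  dx <- lcmunet:::bilinear_up2_bwd(dim(x), dy)
  expect_equal(sum(fwd_y * dy), sum(x * dx), tolerance = 1e-10)

  # axial shift: zero shift is the identity; backward is the adjoint
  x <- rand_fm(10, 6, 6)
  expect_equal(lcmunet:::shift_axis_fwd(x, "w", 0L)$y, x)
  r <- lcmunet:::shift_axis_fwd(x, "h", 1L)
  dy <- rand_fm(10, 6, 6)
  dx <- lcmunet:::shift_axis_bwd(r$cache, dy)
  expect_equal(sum(r$y * dy), sum(x * dx), tolerance = 1e-10)

  # channel pad/truncate round trip
  p <- lcmunet:::pad_channels_fwd(rand_fm(3, 4, 4), 5L)
  expect_equal(dim(p$y)[1], 5)
  expect_true(all(p$y[4:5, , , ] == 0))
  dxp <- lcmunet:::pad_channels_bwd(p$cache, rand_fm(5, 4, 4))
  expect_equal(dim(dxp)[1], 3)
})

test_that("gelu and sigmoid derivatives match finite differences", {
  set.seed(5)
  for (pair in list(list(lcmunet:::gelu_fwd, lcmunet:::gelu_bwd),
                    list(lcmunet:::sigmoid_fwd, lcmunet:::sigmoid_bwd))) {
    expect_true(op_gradcheck(pair[[1]], pair[[2]], rand_fm(2, 3, 3, 2)))
  }
})
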