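# Finite-difference gradient checking utilities shared by the op and block
# tests. Tolerances combine a relative and an absolute floor because many
# true gradients are at the 1e-9 scale where central differences bottom out.

fd_check <- function(value_fun, get, set, analytic, n_probe = 6L,
                     eps = 1e-6, rtol = 1e-3, atol = 1e-6) {
  x <- get()
  idx <- sample.int(length(x), min(n_probe, length(x)))
  ok <- TRUE
  for (k in idx) {
    orig <- x[k]
    x[k] <- orig + eps; set(x); lp <- value_fun()
    x[k] <- orig - eps; set(x); lm <- value_fun()
    x[k] <- orig; set(x)
    fd <- (lp - lm) / (2 * eps)
    an <- analytic[k]
    if (abs(fd - an) > atol + rtol * (abs(fd) + abs(an))) {
      ok <- FALSE
      message(sprintf("fd %.6g vs analytic %.6g at index %d", fd, an, k))
    }
  }
  ok
}

# check input gradients of a pure op given fwd/bwd closures and a random
# downstream cotangent
op_gradcheck <- function(fwd, bwd, x, n_probe = 6L, eps = 1e-6) {
  r <- fwd(x)
  dy <- array(rnorm(length(r$y)), dim = dim(r$y))
  dx <- bwd(r$cache, dy)
  fd_check(function() sum(fwd(x)$y * dy),
           function() x,
           function(v) x <<- v,
           dx, n_probe = n_probe, eps = eps)
}

rand_fm <- function(c, h, w, n = 1L) {
  array(rnorm(c * h * w * n), dim = c(c, h, w, n))
}

tiny_dataset <- function(n = 4L, size = 32L, seed = 3L) {
  generate_dataset(gen_config(n_samples = n, image_size = c(size, size),
                              blur_sigma = 1, hair_occluders = 1L,
                              seed = seed))
}
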