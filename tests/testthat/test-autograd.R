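# Finite-difference checks of every differentiable layer, plus adjoint
# identities for the structural ops. These guard the hand-rolled backward
# passes that the whole training loop rests on.

gm <- asNamespace("ganmap")

fd_check <- function(forward_scalar, param, n_probe = 3, eps = 1e-6,
                     tol = 1e-5) {
  # analytic gradient must already be in param$grad
  set.seed(1)
  for (ii in sample(seq_along(param$value), min(n_probe, length(param$value)))) {
    v0 <- param$value[ii]
    param$value[ii] <- v0 + eps
    lp <- forward_scalar()
    param$value[ii] <- v0 - eps
    lm <- forward_scalar()
    param$value[ii] <- v0
    num <- (lp - lm) / (2 * eps)
    ana <- if (is.null(param$grad)) 0 else param$grad[ii]
    expect_equal(ana, num, tolerance = tol)
  }
}

test_that("conv3d forward/backward agree with finite differences", {
  set.seed(2)
  for (spec in list(list(k = 3L, stride = 1L, pad = 1L, dims = c(5, 4, 6)),
                    list(k = 3L, stride = 2L, pad = 1L, dims = c(6, 6, 6)),
                    list(k = 1L, stride = 1L, pad = 0L, dims = c(4, 4, 4)))) {
    cin <- 2L; cout <- 3L
    x <- gm$nn_param(array(rnorm(prod(spec$dims) * cin), c(spec$dims, cin)))
    w <- gm$nn_param(array(rnorm(spec$k^3 * cin * cout, sd = 0.3),
                           c(spec$k, spec$k, spec$k, cin, cout)))
    b <- gm$nn_param(rnorm(cout))
    run <- function() {
      sum(sin(gm$cpp_conv3d_forward(x$value, w$value, b$value,
                                    spec$stride, spec$pad)))
    }
    tp <- gm$tape_new()
    xn <- gm$ag_leaf(tp, x); wn <- gm$ag_leaf(tp, w); bn <- gm$ag_leaf(tp, b)
    out <- gm$ag_conv3d(tp, xn, wn, bn, spec$stride, spec$pad)
    # loss = sum(sin(out)) exercises a non-uniform output gradient
    loss <- gm$new_node(tp, sum(sin(out$value)), list(out))
    loss$backward <- function() gm$node_accum(out, loss$grad * cos(out$value))
    gm$zero_grads(list(x, w, b))
    gm$ag_backward(tp, loss)
    fd_check(run, x); fd_check(run, w); fd_check(run, b)
  }
})

test_that("instance norm, PReLU and the heads agree with finite differences", {
  set.seed(3)
  dims <- c(4, 4, 4, 3L)
  x <- gm$nn_param(array(rnorm(prod(dims)), dims))
  g <- gm$nn_param(runif(3, 0.5, 1.5))
  be <- gm$nn_param(rnorm(3, sd = 0.1))
  a <- gm$nn_param(runif(3, 0.1, 0.4))
  W <- gm$nn_param(matrix(rnorm(6, sd = 0.5), 2, 3))
  bb <- gm$nn_param(rnorm(2, sd = 0.1))
  run <- function() {
    ns <- prod(dims[1:3])
    xm <- matrix(x$value, ns, 3)
    mu <- colMeans(xm); va <- colMeans(sweep(xm, 2, mu)^2)
    xh <- sweep(sweep(xm, 2, mu), 2, 1 / sqrt(va + 1e-5), `*`)
    y <- sweep(sweep(xh, 2, g$value, `*`), 2, be$value, `+`)
    aa <- rep(a$value, each = ns)
    y <- ifelse(y > 0, y, aa * y)
    pooled <- colMeans(matrix(y, ns, 3))
    z <- drop(W$value %*% pooled) + bb$value
    z <- pmax(z, 0)
    sum(1 / (1 + exp(-z)))
  }
  tp <- gm$tape_new()
  xn <- gm$ag_leaf(tp, x)
  h <- gm$ag_instance_norm(tp, xn, g, be)
  h <- gm$ag_prelu(tp, h, a)
  h <- gm$ag_global_avgpool(tp, h)
  h <- gm$ag_linear(tp, h, W, bb)
  h <- gm$ag_relu(tp, h)
  out <- gm$ag_sigmoid(tp, h)
  loss <- gm$new_node(tp, sum(out$value), list(out))
  loss$backward <- function() gm$node_accum(out, rep(loss$grad, length(out$value)))
  gm$zero_grads(list(x, g, be, a, W, bb))
  gm$ag_backward(tp, loss)
  expect_equal(loss$value, run(), tolerance = 1e-12)
  for (p in list(x, g, be, a, W, bb)) fd_check(run, p)
})

test_that("maxpool and upsample satisfy their adjoint identities", {
  set.seed(4)
  x <- array(rnorm(6 * 6 * 6 * 2), c(6, 6, 6, 2))
  fw <- gm$cpp_maxpool3d_forward(x)
  # gradient routes only to argmax locations and sums to the output grad
  gout <- array(rnorm(length(fw$value)), dim(fw$value))
  dx <- gm$cpp_maxpool3d_backward(gout, fw$argmax, dim(x))
  expect_equal(sum(dx), sum(gout))
  expect_lte(sum(dx != 0), length(gout))

  # <R x, y> == <x, R* y> for the trilinear resize operator R
  xin <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  od <- c(8L, 10L, 6L, 2L)
  y <- array(rnorm(prod(od)), od)
  lhs <- sum(gm$cpp_resize_trilinear(xin, od) * y)
  rhs <- sum(xin * gm$cpp_resize_trilinear_adjoint(y, dim(xin)))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("upsample by 2 of a constant volume is constant", {
  x <- array(3.5, c(4, 4, 4, 1))
  up <- gm$cpp_resize_trilinear(x, c(8L, 8L, 8L, 1L))
  expect_true(all(abs(up - 3.5) < 1e-12))
})

test_that("smooth_l1 and log-loss nodes differentiate correctly", {
  set.seed(5)
  x <- gm$nn_param(array(rnorm(27, sd = 2), c(3, 3, 3)))
  target <- array(rnorm(27), c(3, 3, 3))
  run <- function() {
    d <- x$value - target
    mean(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5))
  }
  tp <- gm$tape_new()
  xn <- gm$ag_leaf(tp, x)
  loss <- gm$ag_smooth_l1(tp, xn, target)
  gm$zero_grads(list(x))
  gm$ag_backward(tp, loss)
  fd_check(run, x, n_probe = 6)

  p <- gm$nn_param(0.37)
  runp <- function() -log(p$value) + 2 * (-log(1 - p$value))
  tp2 <- gm$tape_new()
  pn <- gm$ag_leaf(tp2, p)
  l <- gm$ag_add(tp2, gm$ag_neg_log(tp2, pn),
                 gm$ag_scale(tp2, gm$ag_neg_log1m(tp2, pn), 2))
  gm$zero_grads(list(p))
  gm$ag_backward(tp2, l)
  expect_equal(l$value, runp(), tolerance = 1e-12)
  fd_check(runp, p, n_probe = 1)
})

test_that("NAdam reduces a convex quadratic and is deterministic", {
  run_once <- function() {
    p <- gm$nn_param(c(5, -3))
    opt <- gm$nadam_new(list(p), lr = 0.05)
    for (i in 1:800) {
      p$grad <- 2 * (as.numeric(p$value) - c(1, 2))
      gm$nadam_step(opt)
    }
    as.numeric(p$value)
  }
  v1 <- run_once(); v2 <- run_once()
  expect_identical(v1, v2)
  expect_equal(v1, c(1, 2), tolerance = 1e-2)
})
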