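# Minimal reverse-mode autodiff over dense arrays, sized for 32^3 tiles.
#
# A `tape` records nodes in creation order during a forward pass; backward
# walks the tape in reverse, each node's `backward` closure scattering its
# gradient into its parents. Trainable parameters are persistent
# environments (`nn_param`) whose `$grad` accumulates across the tiles of a
# batch (gradient accumulation stands in for large-batch training).

nn_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  class(e) <- "nn_param"
  e
}

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

tape_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

new_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (!is.null(tape)) tape_push(tape, nd)
  nd
}

node_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# leaf wrapping a parameter: backward deposits into the parameter env
ag_leaf <- function(tape, param) {
  nd <- new_node(tape, param$value)
  nd$backward <- function() {
    param$grad <- if (is.null(param$grad)) nd$grad else param$grad + nd$grad
  }
  nd
}

ag_const <- function(tape, value) new_node(tape, value)

ag_backward <- function(tape, root) {
  root$grad <- if (is.null(dim(root$value))) rep(1, length(root$value))
    else array(1, dim = dim(root$value))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward()
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# differentiable ops (inputs/outputs are nodes; arrays are (nx,ny,nz,C))
# ---------------------------------------------------------------------------

ag_conv3d <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  val <- cpp_conv3d_forward(x$value, w$value, b$value, stride, pad)
  nd <- new_node(tape, val, list(x, w, b))
  nd$backward <- function() {
    gr <- cpp_conv3d_backward(x$value, w$value, nd$grad, stride, pad)
    node_accum(x, gr$dx); node_accum(w, gr$dw); node_accum(b, gr$db)
  }
  nd
}

ag_instance_norm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  ns <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x$value, ns, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma$value, `*`), 2L, beta$value, `+`)
  nd <- new_node(tape, array(y, d), list(x, gamma, beta))
  nd$backward <- function() {
    gy <- matrix(nd$grad, ns, C)
    dgamma <- colSums(gy * xhat)
    dbeta <- colSums(gy)
    dxhat <- sweep(gy, 2L, gamma$value, `*`)
    # biased-variance instance-norm backward
    t1 <- dxhat
    t2 <- matrix(colMeans(dxhat), ns, C, byrow = TRUE)
    t3 <- xhat * matrix(colMeans(dxhat * xhat), ns, C, byrow = TRUE)
    dx <- sweep(t1 - t2 - t3, 2L, istd, `*`)
    node_accum(x, array(dx, d))
    node_accum(gamma, dgamma); node_accum(beta, dbeta)
  }
  nd
}

ag_prelu <- function(tape, x, slope) {
  d <- dim(x$value)
  C <- d[4]
  a <- rep(slope$value, each = prod(d[1:3]))
  pos <- x$value > 0
  y <- ifelse(pos, x$value, a * x$value)
  nd <- new_node(tape, array(y, d), list(x, slope))
  nd$backward <- function() {
    g <- nd$grad
    dx <- ifelse(pos, g, a * g)
    da <- colSums(matrix(g * x$value * !pos, prod(d[1:3]), C))
    node_accum(x, array(dx, d)); node_accum(slope, da)
  }
  nd
}

ag_maxpool <- function(tape, x) {
  fw <- cpp_maxpool3d_forward(x$value)
  nd <- new_node(tape, fw$value, list(x))
  nd$backward <- function() {
    node_accum(x, cpp_maxpool3d_backward(nd$grad, fw$argmax, dim(x$value)))
  }
  nd
}

ag_upsample <- function(tape, x, out_spatial) {
  in_dim <- dim(x$value)
  od <- as.integer(c(out_spatial, in_dim[4]))
  nd <- new_node(tape, cpp_resize_trilinear(x$value, od), list(x))
  nd$backward <- function() {
    node_accum(x, cpp_resize_trilinear_adjoint(nd$grad, in_dim))
  }
  nd
}

ag_concat <- function(tape, xs) {
  dims <- lapply(xs, function(n) dim(n$value))
  chans <- vapply(dims, `[`, integer(1), 4L)
  sp <- dims[[1]][1:3]
  val <- array(0, dim = c(sp, sum(chans)))
  off <- 0L
  for (i in seq_along(xs)) {
    val[, , , off + seq_len(chans[i])] <- xs[[i]]$value
    off <- off + chans[i]
  }
  nd <- new_node(tape, val, xs)
  nd$backward <- function() {
    off <- 0L
    for (i in seq_along(xs)) {
      node_accum(xs[[i]], nd$grad[, , , off + seq_len(chans[i]), drop = FALSE])
      off <- off + chans[i]
    }
  }
  nd
}

ag_global_avgpool <- function(tape, x) {
  d <- dim(x$value)
  ns <- prod(d[1:3])
  nd <- new_node(tape, colMeans(matrix(x$value, ns, d[4])), list(x))
  nd$backward <- function() {
    node_accum(x, array(rep(nd$grad / ns, each = ns), d))
  }
  nd
}

ag_linear <- function(tape, x, W, b) {
  nd <- new_node(tape, drop(W$value %*% x$value) + b$value, list(x, W, b))
  nd$backward <- function() {
    g <- nd$grad
    node_accum(x, drop(crossprod(W$value, g)))
    node_accum(W, outer(g, x$value))
    node_accum(b, g)
  }
  nd
}

ag_relu <- function(tape, x) {
  pos <- x$value > 0
  nd <- new_node(tape, x$value * pos, list(x))
  nd$backward <- function() node_accum(x, nd$grad * pos)
  nd
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  nd <- new_node(tape, s, list(x))
  nd$backward <- function() node_accum(x, nd$grad * s * (1 - s))
  nd
}

# mean smooth-L1 between a node and a constant target array
ag_smooth_l1 <- function(tape, x, target) {
  diff <- x$value - target
  ad <- abs(diff)
  quad <- ad < 1
  val <- mean(ifelse(quad, 0.5 * diff^2, ad - 0.5))
  nd <- new_node(tape, val, list(x))
  nd$backward <- function() {
    g <- ifelse(quad, diff, sign(diff)) / length(diff)
    node_accum(x, array(nd$grad * g, dim(diff)))
  }
  nd
}

# -log(clamp(p, eps, 1-eps)); gradient is zero in the clamped region
ag_neg_log <- function(tape, p, eps = 1e-7) {
  pc <- min(max(p$value, eps), 1 - eps)
  inside <- p$value > eps && p$value < 1 - eps
  nd <- new_node(tape, -log(pc), list(p))
  nd$backward <- function() {
    if (inside) node_accum(p, -nd$grad / pc)
  }
  nd
}

# -log(1 - clamp(p, eps, 1-eps))
ag_neg_log1m <- function(tape, p, eps = 1e-7) {
  pc <- min(max(p$value, eps), 1 - eps)
  inside <- p$value > eps && p$value < 1 - eps
  nd <- new_node(tape, -log(1 - pc), list(p))
  nd$backward <- function() {
    if (inside) node_accum(p, nd$grad / (1 - pc))
  }
  nd
}

ag_add <- function(tape, a, b) {
  nd <- new_node(tape, a$value + b$value, list(a, b))
  nd$backward <- function() { node_accum(a, nd$grad); node_accum(b, nd$grad) }
  nd
}

ag_scale <- function(tape, a, s) {
  nd <- new_node(tape, a$value * s, list(a))
  nd$backward <- function() node_accum(a, nd$grad * s)
  nd
}

#' Resize a 3D array to new dimensions by trilinear interpolation
#' (half-pixel coordinate convention with edge clamping)
#' @noRd
resize_trilinear <- function(data, out_dims) {
  d4 <- array(data, dim = c(dim(data), 1L))
  out <- cpp_resize_trilinear(d4, as.integer(c(out_dims, 1L)))
  array(out, dim = out_dims)
}

# ---------------------------------------------------------------------------
# NAdam optimizer (Nesterov-momentum Adam with momentum-decay schedule)
# ---------------------------------------------------------------------------

nadam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, psi = 0.004) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$psi <- psi
  st$t <- 0L
  st$mu_prod <- 1
  st$m <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  st$v <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nadam_step <- function(st) {
  st$t <- st$t + 1L
  t <- st$t
  mu_t <- st$beta1 * (1 - 0.5 * 0.96^(t * st$psi))
  mu_next <- st$beta1 * (1 - 0.5 * 0.96^((t + 1) * st$psi))
  mu_prod_t <- st$mu_prod * mu_t
  mu_prod_next <- mu_prod_t * mu_next
  st$mu_prod <- mu_prod_t
  bc2 <- 1 - st$beta2^t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    mhat <- mu_next * st$m[[i]] / (1 - mu_prod_next) +
      (1 - mu_t) * g / (1 - mu_prod_t)
    vhat <- st$v[[i]] / bc2
    p$value <- p$value - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  invisible(st)
}

nadam_state <- function(st) {
  list(t = st$t, mu_prod = st$mu_prod, m = st$m, v = st$v, lr = st$lr,
       beta1 = st$beta1, beta2 = st$beta2, eps = st$eps, psi = st$psi)
}

nadam_restore <- function(params, state) {
  st <- nadam_new(params, lr = state$lr, beta1 = state$beta1,
                  beta2 = state$beta2, eps = state$eps, psi = state$psi)
  st$t <- state$t; st$mu_prod <- state$mu_prod
  st$m <- state$m; st$v <- state$v
  st
}
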