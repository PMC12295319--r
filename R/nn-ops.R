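# Low-level differentiable operations on (H, W, C) arrays and vectors.
# All forward functions return the output plus whatever the matching backward
# pass needs; backward passes return gradients with the same shapes as their
# inputs. Everything is plain base-R matrix algebra: the networks built here
# are small enough (desk-scale backbones, 1x1 attention convolutions, dense
# heads) that im2col + %*% is fast and keeps every step inspectable.

#' Numerically stable softmax
#'
#' @param x Numeric vector of logits, or a matrix with one row of logits per
#'   observation.
#' @return Probabilities with the same shape as `x`; rows sum to 1.
#' @examples
#' softmax(c(0, 0))        # c(0.5, 0.5)
#' softmax(c(1000, 1000))  # stable at large magnitudes
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    z <- exp(x - apply(x, 1L, max))
    z / rowSums(z)
  } else {
    z <- exp(x - max(x))
    z / sum(z)
  }
}

# d(loss)/d(logits) given probabilities p = softmax(logits) and d(loss)/dp.
softmax_backward <- function(p, dp) {
  p * (dp - sum(dp * p))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Glorot-uniform initialisation: limit sqrt(6 / (fan_in + fan_out)).
glorot_uniform <- function(dim, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dim), -limit, limit), dim = dim)
}

# ---- 2-D convolution (valid padding) ------------------------------------

# im2col: unfold x (H, W, Cin) into a matrix with one row per output
# position (row-major in (ho, wo)) and one column per (kh, kw, cin) weight,
# column order matching R's flattening of a (kh, kw, Cin, Cout) kernel.
im2col <- function(x, kh, kw, stride) {
  d <- dim(x)
  ho <- (d[1] - kh) %/% stride + 1L
  wo <- (d[2] - kw) %/% stride + 1L
  cin <- d[3]
  cols <- matrix(0, ho * wo, kh * kw * cin)
  idx <- 0L
  for (ci in seq_len(cin)) {
    for (j in seq_len(kw)) {
      for (i in seq_len(kh)) {
        idx <- idx + 1L
        cols[, idx] <- as.vector(x[seq(i, by = stride, length.out = ho),
                                   seq(j, by = stride, length.out = wo), ci])
      }
    }
  }
  list(cols = cols, ho = ho, wo = wo)
}

# Forward valid-padding convolution. W: (kh, kw, Cin, Cout), b: length Cout.
conv2d_forward <- function(x, W, b, stride = 1L) {
  dw <- dim(W)
  if (dim(x)[3] != dw[3]) {
    stop("conv2d: input has ", dim(x)[3], " channels but kernel expects ", dw[3])
  }
  ic <- im2col(x, dw[1], dw[2], stride)
  wmat <- matrix(W, nrow = dw[1] * dw[2] * dw[3], ncol = dw[4])
  out <- ic$cols %*% wmat
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(ic$ho, ic$wo, dw[4])),
       cache = list(x = x, W = W, stride = stride, cols = ic$cols))
}

# Backward pass; dout has the shape of the forward output.
conv2d_backward <- function(cache, dout) {
  W <- cache$W
  dw <- dim(W)
  dd <- dim(dout)
  dout_mat <- matrix(dout, nrow = dd[1] * dd[2], ncol = dd[3])
  wmat <- matrix(W, nrow = dw[1] * dw[2] * dw[3], ncol = dw[4])
  dW <- array(crossprod(cache$cols, dout_mat), dim = dw)
  db <- colSums(dout_mat)
  # scatter the column gradients back onto the input grid
  dcols <- dout_mat %*% t(wmat)
  dx <- array(0, dim(cache$x))
  stride <- cache$stride
  ho <- dd[1]; wo <- dd[2]
  idx <- 0L
  for (ci in seq_len(dw[3])) {
    for (j in seq_len(dw[2])) {
      for (i in seq_len(dw[1])) {
        idx <- idx + 1L
        ri <- seq(i, by = stride, length.out = ho)
        cj <- seq(j, by = stride, length.out = wo)
        dx[ri, cj, ci] <- dx[ri, cj, ci] + matrix(dcols[, idx], ho, wo)
      }
    }
  }
  list(dW = dW, db = db, dx = dx)
}

# ---- Dense layer ---------------------------------------------------------

# z = W x + b with W (out, in).
dense_forward <- function(x, W, b) {
  list(out = as.vector(W %*% x) + b, cache = list(x = x, W = W))
}

dense_backward <- function(cache, dout) {
  list(dW = outer(dout, cache$x), db = dout,
       dx = as.vector(crossprod(cache$W, dout)))
}

# ---- Adam optimiser ------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

# One Adam step over a named list of parameter arrays. `mask` names the
# trainable parameters; others are left untouched.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      trainable = names(params)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps per-item generation independent of
# global RNG usage and of generation order.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Counter-based stream seed: fold (seed, class index, item index) into a
# 31-bit integer deterministically, in double arithmetic to avoid overflow.
stream_seed <- function(seed, class_idx = 0L, item_idx = 0L) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 +
    as.numeric(class_idx) * 69621 + as.numeric(item_idx) * 16807 + 1
  as.integer(s %% 2147483647)
}
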