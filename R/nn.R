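# Minimal feed-forward NN primitives for the haplotype imputation model.
# Layout conventions: conv activations are (channels, positions, batch)
# arrays; dense activations are (batch, units) matrices. All convolutions are
# stride-1, valid padding, implemented as im2col matrix products.

conv_init <- function(c_in, k, f, rngsd) {
  with_seed(rngsd, {
    sd <- sqrt(2 / (c_in * k))
    list(W = matrix(stats::rnorm(c_in * k * f, 0, sd), c_in * k, f),
         b = rep(0, f),
         gamma = rep(1, f), beta = rep(0, f),
         rmean = rep(0, f), rvar = rep(1, f))
  })
}

dense_init <- function(d_in, d_out, rngsd) {
  with_seed(rngsd, {
    sd <- sqrt(2 / d_in)
    list(W = matrix(stats::rnorm(d_in * d_out, 0, sd), d_in, d_out),
         b = rep(0, d_out))
  })
}

# im2col index for input (C, W) -> matrix rows (c, o) x cols p
im2col_idx <- function(C, W, k) {
  P <- W - k + 1L
  if (P < 1L) stop("window too short for kernel size ", k)
  idx <- integer(C * k * P)
  i <- 1L
  for (p in seq_len(P)) for (o in seq_len(k)) for (c in seq_len(C)) {
    idx[i] <- (p + o - 2L) * C + c; i <- i + 1L
  }
  idx
}

conv_forward <- function(layer, x, idx, k) {
  d <- dim(x); C <- d[1]; W <- d[2]; N <- d[3]
  P <- W - k + 1L
  x2 <- x; dim(x2) <- c(C * W, N)
  xc <- x2[idx, , drop = FALSE]          # (C*k*P, N)
  dim(xc) <- c(C * k, P * N)
  xc <- t(xc)                            # (P*N, C*k), p fastest within n
  out <- xc %*% layer$W                  # (P*N, F)
  out <- sweep(out, 2L, layer$b, "+")
  y <- t(out); dim(y) <- c(ncol(layer$W), P, N)
  list(y = y, xc = xc, P = P, N = N, C = C, W = W)
}

conv_backward <- function(layer, cache, dy, idx, k, need_dx = TRUE) {
  F <- dim(dy)[1]; P <- cache$P; N <- cache$N; C <- cache$C; W <- cache$W
  dout <- dy; dim(dout) <- c(F, P * N); dout <- t(dout)
  dW <- crossprod(cache$xc, dout)
  db <- colSums(dout)
  dx <- NULL
  if (need_dx) {
    dxc <- dout %*% t(layer$W)           # (P*N, C*k)
    A <- t(dxc); dim(A) <- c(C, k, P, N)
    dx <- array(0, c(C, W, N))
    for (o in seq_len(k))
      dx[, o:(o + P - 1L), ] <- dx[, o:(o + P - 1L), ] + A[, o, , ]
  }
  list(dW = dW, db = db, dx = dx)
}

bn_forward <- function(layer, x, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); F <- d[1]; m <- d[2] * d[3]
  x2 <- x; dim(x2) <- c(F, m)
  if (training) {
    mu <- rowMeans(x2)
    va <- rowMeans((x2 - mu)^2)
    layer$rmean <- (1 - momentum) * layer$rmean + momentum * mu
    layer$rvar <- (1 - momentum) * layer$rvar + momentum * va
  } else { mu <- layer$rmean; va <- layer$rvar }
  inv <- 1 / sqrt(va + eps)
  xhat <- (x2 - mu) * inv
  y <- xhat * layer$gamma + layer$beta
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, layer = layer, training = training,
       dims = d)
}

bn_backward <- function(cache, dy) {
  d <- cache$dims; F <- d[1]; m <- d[2] * d[3]
  dy2 <- dy; dim(dy2) <- c(F, m)
  g <- cache$layer$gamma
  dgamma <- rowSums(dy2 * cache$xhat)
  dbeta <- rowSums(dy2)
  if (cache$training) {
    dx <- (g * cache$inv / m) * (m * dy2 - dbeta - cache$xhat * dgamma)
  } else {
    dx <- dy2 * g * cache$inv
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(cache, dy) dy * cache$mask

pool_forward <- function(x, p) {
  d <- dim(x); F <- d[1]; P <- d[2]; N <- d[3]
  Q <- P %/% p
  if (Q < 1L) stop("feature map shorter than pool size")
  z <- x[, seq_len(Q * p), , drop = FALSE]
  dim(z) <- c(F, p, Q, N)
  best <- z[, 1L, , , drop = FALSE]; dim(best) <- c(F, Q, N)
  amax <- array(1L, c(F, Q, N))
  if (p > 1L) for (j in 2:p) {
    zj <- z[, j, , , drop = FALSE]; dim(zj) <- c(F, Q, N)
    upd <- zj > best
    best[upd] <- zj[upd]; amax[upd] <- j
  }
  list(y = best, amax = amax, p = p, P = P, dims = d)
}

pool_backward <- function(cache, dy) {
  d <- cache$dims; F <- d[1]; P <- cache$P; N <- d[3]
  p <- cache$p; Q <- P %/% p
  dz <- array(0, c(F, p, Q, N))
  for (j in seq_len(p)) {
    mask <- cache$amax == j
    slot <- array(0, c(F, Q, N)); slot[mask] <- dy[mask]
    dz[, j, , ] <- slot
  }
  dx <- array(0, d)
  dim(dz) <- c(F, p * Q, N)
  dx[, seq_len(p * Q), ] <- dz
  dx
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate) / (1 - rate), dim(x) %||% length(x))
  list(y = x * mask, mask = mask)
}
dropout_backward <- function(cache, dy)
  if (is.null(cache$mask)) dy else dy * cache$mask

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean categorical cross-entropy; labels are 1-based class indices
ce_loss <- function(probs, labels) {
  -mean(log(pmax(probs[cbind(seq_along(labels), labels)], 1e-12)))
}

adam_update <- function(param, grad, state, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# optimizer state mirroring a (possibly nested) list of gradient leaves
adam_like <- function(g) if (is.list(g)) lapply(g, adam_like) else
  list(m = g * 0, v = g * 0)

# apply Adam to every leaf of params present in grads
adam_apply <- function(params, grads, opt, lr, t) {
  if (!is.list(grads)) {
    u <- adam_update(params, grads, opt, lr, t)
    return(list(param = u$param, state = u$state))
  }
  for (nm in names(grads)) {
    u <- adam_apply(params[[nm]], grads[[nm]], opt[[nm]], lr, t)
    params[[nm]] <- u$param; opt[[nm]] <- u$state
  }
  list(param = params, state = opt)
}

#' Min-norm task weighting (MGDA-UB)
#'
#' Finds the point of the convex hull of the task gradients closest to the
#' origin: the weights \code{w} on the probability simplex minimizing
#' \code{||sum_t w_t g_t||^2}, by Frank-Wolfe iteration with the analytic
#' two-point line search. Used to scale per-task losses so a shared
#' representation descends towards a Pareto-stationary point.
#'
#' @param task_gradients list of numeric vectors (one flattened gradient per
#'   task, all the same length).
#' @param max_iter,tol Frank-Wolfe iteration controls.
#' @return Numeric weight vector on the simplex (sums to 1, non-negative).
#'   All-zero gradients give uniform weights.
#' @export
mgda_ub_weights <- function(task_gradients, max_iter = 2000L, tol = 1e-6) {
  Tn <- length(task_gradients)
  stopifnot(Tn >= 1L)
  if (Tn == 1L) return(1)
  G <- do.call(rbind, lapply(task_gradients, as.numeric))
  if (any(!is.finite(G))) stop("task gradients must be finite")
  M <- tcrossprod(G)
  if (all(abs(M) < 1e-30)) return(rep(1 / Tn, Tn))
  w <- rep(1 / Tn, Tn)
  scale <- max(abs(M))
  for (it in seq_len(max_iter)) {
    v <- as.numeric(M %*% w)
    tstar <- which.min(v)
    aMa <- sum(w * v)
    aMb <- v[tstar]
    if (aMa - aMb < tol * scale) break     # Frank-Wolfe duality gap
    bMb <- M[tstar, tstar]
    denom <- aMa - 2 * aMb + bMb
    gamma <- if (denom <= 0) as.numeric(aMb < aMa) else
      min(1, max(0, (aMa - aMb) / denom))
    w <- (1 - gamma) * w
    w[tstar] <- w[tstar] + gamma
  }
  w / sum(w)
}
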