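# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Every value is a base-R numeric matrix; a "node" is an
# environment holding the value, an accumulated gradient, its parents and
# a backward closure. Nodes created while a tape is active are recorded in
# creation order, which is a valid topological order for the backward pass.
#
# This engine exists so the graph/text model can be trained with exact
# gradients; its correctness is pinned by finite-difference tests.

the <- new.env(parent = emptyenv())
the$tape <- NULL

ad_tape_start <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  the$tape <- t
  invisible(t)
}

ad_tape_stop <- function() {
  the$tape <- NULL
  invisible(NULL)
}

ad_record <- function(node) {
  t <- the$tape
  if (is.null(t)) return(node)
  n <- t$n + 1L
  if (n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[n]] <- node
  t$n <- n
  node
}

ad_new <- function(v, parents = list(), bk = NULL, track = TRUE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$track <- track
  e$parents <- parents
  e$bk <- bk
  class(e) <- "ad_node"
  if (track && !is.null(bk)) ad_record(e)
  e
}

#' @noRd
ad_param <- function(v) ad_new(as.matrix(v), track = TRUE)

ad_const <- function(v) ad_new(as.matrix(v), track = FALSE)

is_ad <- function(x) inherits(x, "ad_node")

as_ad <- function(x) if (is_ad(x)) x else ad_const(x)

ad_value <- function(x) if (is_ad(x)) x$v else x

ad_acc <- function(p, g) {
  if (p$track) p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Run backward from `loss` (1x1 node) over the active tape.
ad_backward <- function(loss, tape = the$tape) {
  stopifnot(!is.null(tape))
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bk)) nd$bk(nd$grad)
  }
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- primitive operations ------------------------------------------------

ad_mm <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_new(a$v %*% b$v, bk = function(g) {
    ad_acc(a, g %*% t(b$v))
    ad_acc(b, crossprod(a$v, g))
  })
}

# a %*% t(b)
ad_mm_t <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_new(tcrossprod(a$v, b$v), bk = function(g) {
    ad_acc(a, g %*% b$v)
    ad_acc(b, crossprod(g, a$v))
  })
}

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_new(a$v + b$v, bk = function(g) {
    ad_acc(a, g)
    ad_acc(b, g)
  })
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_new(a$v - b$v, bk = function(g) {
    ad_acc(a, g)
    ad_acc(b, -g)
  })
}

# add a 1 x d row vector to every row of an n x d matrix
ad_add_rowvec <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  v <- sweep(a$v, 2L, as.vector(b$v), "+")
  ad_new(v, bk = function(g) {
    ad_acc(a, g)
    ad_acc(b, matrix(colSums(g), 1L))
  })
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_new(a$v * b$v, bk = function(g) {
    ad_acc(a, g * b$v)
    ad_acc(b, g * a$v)
  })
}

# multiply by a plain numeric scalar or same-shape mask (no grad through s)
ad_scale <- function(a, s) {
  a <- as_ad(a)
  ad_new(a$v * s, bk = function(g) ad_acc(a, g * s))
}

# multiply matrix node by 1x1 scalar node
ad_scale_node <- function(a, s) {
  a <- as_ad(a); s <- as_ad(s)
  ad_new(a$v * s$v[1L], bk = function(g) {
    ad_acc(a, g * s$v[1L])
    ad_acc(s, matrix(sum(g * a$v), 1L, 1L))
  })
}

# scale the rows of an n x d node by an n x 1 column node
ad_rowscale <- function(a, w) {
  a <- as_ad(a); w <- as_ad(w)
  wv <- as.vector(w$v)
  ad_new(a$v * wv, bk = function(g) {
    ad_acc(a, g * wv)
    ad_acc(w, matrix(rowSums(g * a$v), ncol = 1L))
  })
}

ad_tanh <- function(a) {
  a <- as_ad(a)
  v <- tanh(a$v)
  ad_new(v, bk = function(g) ad_acc(a, g * (1 - v^2)))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  v <- 1 / (1 + exp(-a$v))
  ad_new(v, bk = function(g) ad_acc(a, g * v * (1 - v)))
}

ad_relu <- function(a) {
  a <- as_ad(a)
  m <- (a$v > 0) * 1
  ad_new(a$v * m, bk = function(g) ad_acc(a, g * m))
}

# exact (erf-based) GELU: x * Phi(x)
ad_gelu <- function(a) {
  a <- as_ad(a)
  ph <- stats::pnorm(a$v)
  ad_new(a$v * ph, bk = function(g) {
    ad_acc(a, g * (ph + a$v * stats::dnorm(a$v)))
  })
}

ad_log <- function(a) {
  a <- as_ad(a)
  ad_new(log(a$v), bk = function(g) ad_acc(a, g / a$v))
}

# elementwise power with a constant exponent
ad_pow <- function(a, p) {
  a <- as_ad(a)
  ad_new(a$v^p, bk = function(g) ad_acc(a, g * p * a$v^(p - 1)))
}

# clamp from below; gradient is zero where clamped
ad_clamp_min <- function(a, lo) {
  a <- as_ad(a)
  m <- (a$v >= lo) * 1
  ad_new(pmax(a$v, lo), bk = function(g) ad_acc(a, g * m))
}

# row selection (embedding lookup); backward scatter-adds into the source
ad_rows <- function(a, idx) {
  a <- as_ad(a)
  idx <- as.integer(idx)
  ad_new(a$v[idx, , drop = FALSE], bk = function(g) {
    z <- matrix(0, nrow(a$v), ncol(a$v))
    rs <- rowsum(g, group = idx, reorder = FALSE)
    z[as.integer(rownames(rs)), ] <- rs
    ad_acc(a, z)
  })
}

# column slice
ad_cols <- function(a, idx) {
  a <- as_ad(a)
  idx <- as.integer(idx)
  ad_new(a$v[, idx, drop = FALSE], bk = function(g) {
    z <- matrix(0, nrow(a$v), ncol(a$v))
    z[, idx] <- g
    ad_acc(a, z)
  })
}

# sum the rows of an m x d node into n destination rows (scatter-add)
ad_scatter_rows <- function(a, idx, n) {
  a <- as_ad(a)
  idx <- as.integer(idx)
  v <- matrix(0, n, ncol(a$v))
  rs <- rowsum(a$v, group = idx, reorder = FALSE)
  v[as.integer(rownames(rs)), ] <- rs
  ad_new(v, bk = function(g) ad_acc(a, g[idx, , drop = FALSE]))
}

ad_concat_cols <- function(xs) {
  xs <- lapply(xs, as_ad)
  widths <- vapply(xs, function(x) ncol(x$v), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_new(do.call(cbind, lapply(xs, function(x) x$v)), bk = function(g) {
    for (i in seq_along(xs)) {
      ad_acc(xs[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_concat_rows <- function(xs) {
  xs <- lapply(xs, as_ad)
  hts <- vapply(xs, function(x) nrow(x$v), 1L)
  ends <- cumsum(hts)
  starts <- ends - hts + 1L
  ad_new(do.call(rbind, lapply(xs, function(x) x$v)), bk = function(g) {
    for (i in seq_along(xs)) {
      ad_acc(xs[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

# repeat a 1 x d row n times
ad_rep_row <- function(a, n) {
  a <- as_ad(a)
  ad_new(matrix(a$v, n, ncol(a$v), byrow = TRUE), bk = function(g) {
    ad_acc(a, matrix(colSums(g), 1L))
  })
}

# column means -> 1 x d
ad_mean_rows <- function(a) {
  a <- as_ad(a)
  n <- nrow(a$v)
  ad_new(matrix(colMeans(a$v), 1L), bk = function(g) {
    ad_acc(a, matrix(g, n, ncol(a$v), byrow = TRUE) / n)
  })
}

# per-column max over rows -> 1 x d (max pooling over positions)
ad_max_rows <- function(a) {
  a <- as_ad(a)
  am <- max.col(t(a$v), ties.method = "first")
  v <- matrix(a$v[cbind(am, seq_len(ncol(a$v)))], 1L)
  ad_new(v, bk = function(g) {
    z <- matrix(0, nrow(a$v), ncol(a$v))
    z[cbind(am, seq_len(ncol(a$v)))] <- as.vector(g)
    ad_acc(a, z)
  })
}

ad_sum <- function(a) {
  a <- as_ad(a)
  ad_new(matrix(sum(a$v), 1L, 1L), bk = function(g) {
    ad_acc(a, matrix(g[1L], nrow(a$v), ncol(a$v)))
  })
}

# rowSums(a * b) -> n x 1 (per-row inner products)
ad_dot_rows <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_new(matrix(rowSums(a$v * b$v), ncol = 1L), bk = function(g) {
    gv <- as.vector(g)
    ad_acc(a, b$v * gv)
    ad_acc(b, a$v * gv)
  })
}

# numerically stabilized row-wise softmax
ad_softmax_rows <- function(a) {
  a <- as_ad(a)
  z <- a$v - apply(a$v, 1L, max)
  e <- exp(z)
  v <- e / rowSums(e)
  ad_new(v, bk = function(g) {
    ad_acc(a, v * (g - rowSums(g * v)))
  })
}

# single element -> 1 x 1
ad_pick <- function(a, i, j) {
  a <- as_ad(a)
  i <- as.integer(i); j <- as.integer(j)
  ad_new(matrix(a$v[i, j], 1L, 1L), bk = function(g) {
    z <- matrix(0, nrow(a$v), ncol(a$v))
    z[i, j] <- g[1L]
    ad_acc(a, z)
  })
}

ad_add_n <- function(xs) {
  xs <- lapply(xs, as_ad)
  v <- xs[[1L]]$v
  if (length(xs) > 1L) for (i in 2:length(xs)) v <- v + xs[[i]]$v
  ad_new(v, bk = function(g) for (x in xs) ad_acc(x, g))
}

# ---- parameter initialization and optimizer ------------------------------

# Xavier/Glorot uniform: U(-l, l), l = gain * sqrt(6 / (fan_in + fan_out)).
xavier_uniform <- function(nin, nout, gain = 1) {
  l <- gain * sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p$v * 0, v = p$v * 0, t = 0L))
}

# Adam with decoupled weight decay; `skip_decay` names parameters (biases,
# embedding tables) excluded from decay.
adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, skip_decay = character()) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    st <- state[[nm]]
    st$t <- st$t + 1L
    g <- p$grad
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mh <- st$m / (1 - beta1^st$t)
    vh <- st$v / (1 - beta2^st$t)
    upd <- mh / (sqrt(vh) + eps)
    if (weight_decay > 0 && !(nm %in% skip_decay)) {
      upd <- upd + weight_decay * p$v
    }
    p$v <- p$v - lr * upd
    state[[nm]] <- st
  }
  state
}
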