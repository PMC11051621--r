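#' Configuration for the feature-fusion head
#'
#' @param method Fusion method 1, 2 or 3 (default 2, the shipped default).
#'   Method 1 runs the contextual embeddings through a BiLSTM before the
#'   convolution; method 2 feeds `[e_w, e_p]` straight into the
#'   convolution; method 3 broadcasts the pair representation and the drug
#'   positions' embeddings to every token before the convolution.
#' @param window Odd convolution window size (default 5).
#' @param channels Convolution output channels `d_c` (default 32).
#' @param dropout Dropout probability applied to the fused vector before
#'   the prediction layer during training (default 0.1).
#' @param d_lstm BiLSTM hidden size, method 1 only (default 32).
#' @param dedup_hdp If `TRUE`, method 3 concatenates the pair
#'   representation once instead of the printed duplication.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(method = 2L, window = 5L, channels = 32L,
                          dropout = 0.1, d_lstm = 32L, dedup_hdp = FALSE) {
  stopifnot(method %in% 1:3, window %% 2L == 1L, window >= 1L,
            channels >= 1L, dropout >= 0, dropout < 1)
  structure(
    list(method = as.integer(method), window = as.integer(window),
         channels = as.integer(channels), dropout = dropout,
         d_lstm = as.integer(d_lstm), dedup_hdp = isTRUE(dedup_hdp)),
    class = "fusion_config"
  )
}

# per-token input width of the convolution for each method
fusion_input_dim <- function(cfg, d_w, d_p2, dp_len) {
  switch(cfg$method,
    2L * cfg$d_lstm + d_p2,
    d_w + d_p2,
    d_w + (if (cfg$dedup_hdp) 1L else 2L) * dp_len + 3L * d_p2
  )
}

# length of the fused vector H
fusion_output_dim <- function(cfg, dp_len) {
  if (cfg$method == 3L) cfg$channels else cfg$channels + dp_len
}

#' Initialize fusion-head parameters
#'
#' @param cfg A [fusion_config()].
#' @param d_w Contextual embedding width.
#' @param d_p2 Width of a position-embedding row (`2 * d_p`).
#' @param dp_len Length of the pair representation.
#' @param n_classes Number of DDI classes (default 5).
#' @param seed Integer seed.
#' @return Named list of `ad_param` objects including the prediction layer.
#' @export
fusion_params <- function(cfg, d_w, d_p2, dp_len, n_classes = 5L, seed = 1L) {
  set.seed(seed)
  din <- fusion_input_dim(cfg, d_w, d_p2, dp_len)
  p <- list(
    W_conv = ad_param(xavier_uniform(cfg$window * din, cfg$channels)),
    b_conv = ad_param(matrix(0, 1L, cfg$channels)),
    W_pred = ad_param(xavier_uniform(fusion_output_dim(cfg, dp_len),
                                     n_classes)),
    b_pred = ad_param(matrix(0, 1L, n_classes))
  )
  if (cfg$method == 1L) {
    dl <- cfg$d_lstm
    fb <- matrix(0, 1L, 4L * dl)
    fb[1L, dl + (1:dl)] <- 1  # forget-gate bias
    p$W_lstm_f <- ad_param(xavier_uniform(d_w + dl, 4L * dl))
    p$b_lstm_f <- ad_param(fb)
    p$W_lstm_b <- ad_param(xavier_uniform(d_w + dl, 4L * dl))
    p$b_lstm_b <- ad_param(fb)
  }
  p
}

# windowed concatenation with zero padding: each row i of the result is the
# concatenation of the window rows centered on i
ad_window_concat <- function(x, window) {
  if (window == 1L) return(x)
  n <- nrow(x$v)
  din <- ncol(x$v)
  half <- (window - 1L) %/% 2L
  pad <- ad_const(matrix(0, half, din))
  padded <- ad_concat_rows(list(pad, x, pad))
  ad_concat_cols(lapply(0:(window - 1L), function(j) {
    ad_rows(padded, j + seq_len(n))
  }))
}

# convolution (as a windowed affine map) + GELU + max-pool over positions
conv_pool_ad <- function(et, W_conv, b_conv, window) {
  z <- ad_window_concat(et, window)
  c_ <- ad_gelu(ad_add_rowvec(ad_mm(z, W_conv), b_conv))
  ad_max_rows(c_)
}

# one LSTM direction; returns n x d_lstm node in original token order
lstm_dir_ad <- function(x, W, b, d_lstm, reverse = FALSE) {
  n <- nrow(x$v)
  h <- ad_const(matrix(0, 1L, d_lstm))
  cc <- ad_const(matrix(0, 1L, d_lstm))
  outs <- vector("list", n)
  order_ <- if (reverse) seq.int(n, 1L) else seq_len(n)
  for (i in order_) {
    xi <- ad_rows(x, i)
    z <- ad_add_rowvec(ad_mm(ad_concat_cols(list(h, xi)), W), b)
    ig <- ad_sigmoid(ad_cols(z, 1:d_lstm))
    fg <- ad_sigmoid(ad_cols(z, d_lstm + (1:d_lstm)))
    og <- ad_sigmoid(ad_cols(z, 2L * d_lstm + (1:d_lstm)))
    gg <- ad_tanh(ad_cols(z, 3L * d_lstm + (1:d_lstm)))
    cc <- ad_add(ad_mul(fg, cc), ad_mul(ig, gg))
    h <- ad_mul(og, ad_tanh(cc))
    outs[[i]] <- h
  }
  ad_concat_rows(outs)
}

# AD forward of the fusion head; e_w, e_p are n x * nodes, h_dp a 1 x L
# node; d1/d2 are the drug token index ranges (method 3 only).
fuse_ad <- function(e_w, e_p, h_dp, cfg, params, d1 = NULL, d2 = NULL) {
  if (nrow(e_w$v) < 1L) rlang::abort("cannot fuse an empty token sequence")
  if (cfg$method == 1L) {
    l <- lstm_dir_ad(e_w, params$W_lstm_f, params$b_lstm_f, cfg$d_lstm)
    r <- lstm_dir_ad(e_w, params$W_lstm_b, params$b_lstm_b, cfg$d_lstm,
                     reverse = TRUE)
    et <- ad_concat_cols(list(l, r, e_p))
    etext <- conv_pool_ad(et, params$W_conv, params$b_conv, cfg$window)
    return(ad_concat_cols(list(etext, h_dp)))
  }
  if (cfg$method == 2L) {
    et <- ad_concat_cols(list(e_w, e_p))
    etext <- conv_pool_ad(et, params$W_conv, params$b_conv, cfg$window)
    return(ad_concat_cols(list(etext, h_dp)))
  }
  n <- nrow(e_w$v)
  hdp_rep <- ad_rep_row(h_dp, n)
  ewdp <- if (cfg$dedup_hdp) {
    ad_concat_cols(list(e_w, hdp_rep))
  } else {
    ad_concat_cols(list(e_w, hdp_rep, hdp_rep))
  }
  epdp <- ad_concat_cols(list(
    e_p,
    ad_rep_row(ad_rows(e_p, d1[1L]), n),
    ad_rep_row(ad_rows(e_p, d2[1L]), n)
  ))
  e <- ad_concat_cols(list(ewdp, epdp))
  conv_pool_ad(e, params$W_conv, params$b_conv, cfg$window)
}

#' Fuse text, position and subgraph features into a fixed-size vector
#'
#' Numeric front end over the three fusion heads: windowed convolution with
#' GELU and max-pooling over token positions, preceded (method 1) by a
#' BiLSTM over the contextual embeddings, or augmented (method 3) by
#' broadcasting the pair representation and the two drug positions'
#' embeddings to every token. Methods 1 and 2 append the pair
#' representation to the pooled text vector; method 3's pooled vector is
#' the result itself.
#'
#' @param e_w Contextual embeddings (n x d_w).
#' @param e_p Position embeddings (n x 2 d_p).
#' @param h_dp Pair representation (numeric vector).
#' @param cfg A [fusion_config()].
#' @param params Parameters from [fusion_params()].
#' @param d1,d2 Drug token index ranges (method 3).
#' @return Numeric vector `H` whose length does not depend on sentence
#'   length.
#' @export
fuse <- function(e_w, e_p, h_dp, cfg, params, d1 = NULL, d2 = NULL) {
  out <- fuse_ad(ad_const(e_w), ad_const(e_p),
                 ad_const(matrix(h_dp, 1L)), cfg, params, d1, d2)
  as.vector(out$v)
}

#' Class scores and probabilities from a fused vector
#'
#' `s = H W_pred + b`; probabilities are the numerically stabilized softmax
#' of the scores.
#'
#' @param H Fused feature vector.
#' @param W_pred Weight matrix (length(H) x m) or `ad_param`.
#' @param b_pred Optional bias row.
#' @return List with `scores` and `prob` (both length m).
#' @export
predict_scores <- function(H, W_pred, b_pred = NULL) {
  if (any(!is.finite(H))) rlang::abort("non-finite fused vector")
  W <- ad_value(W_pred)
  s <- as.vector(matrix(H, 1L) %*% W)
  if (!is.null(b_pred)) s <- s + as.vector(ad_value(b_pred))
  z <- s - max(s)
  p <- exp(z) / sum(exp(z))
  list(scores = s, prob = p)
}
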