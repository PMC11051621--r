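#' Configuration for the subgraph message-passing network
#'
#' @param layers Number of message-passing layers T (default 3).
#' @param hidden_dim Per-layer state width (default 75).
#' @param num_bases Number of basis matrices B shared across relations.
#' @param zeta Attention pruning threshold in `[-1, 1)`; edges whose
#'   attention score does not exceed it are masked out (default 0).
#' @param attention_scale `"dim"` divides the attention logit by the input
#'   width d0 (as specified); `"sqrt_dim"` divides by sqrt(d0).
#' @return A list of class `subagcn_config`.
#' @export
subagcn_config <- function(layers = 3L, hidden_dim = 75L, num_bases = 4L,
                           zeta = 0, attention_scale = c("dim", "sqrt_dim")) {
  stopifnot(layers >= 1L, hidden_dim >= 1L, num_bases >= 1L,
            zeta >= -1, zeta < 1)
  structure(
    list(layers = as.integer(layers), hidden_dim = as.integer(hidden_dim),
         num_bases = as.integer(num_bases), zeta = zeta,
         attention_scale = match.arg(attention_scale)),
    class = "subagcn_config"
  )
}

# Double the stored edge set with inverse relations so messages flow both
# ways; inverse of relation r (1-based) is r + n_relations.
double_edges <- function(edges, n_relations) {
  if (nrow(edges) == 0L) {
    return(list(src = integer(), dst = integer(), rel = integer()))
  }
  list(
    src = c(edges$src, edges$dst),
    dst = c(edges$dst, edges$src),
    rel = c(edges$rel_idx, edges$rel_idx + n_relations)
  )
}

#' Initialize parameters for the subgraph network
#'
#' All weights are xavier-uniform under the given seed. Relation embeddings
#' cover the stored relations and one generated inverse per relation
#' (2 * n_relations rows).
#'
#' @param input_dim Width of the initial node states
#'   (`graph_dim + 2 * (k + 1)`).
#' @param n_relations Number of stored relation types.
#' @param cfg A [subagcn_config()].
#' @param seed Integer seed.
#' @return Named list of `ad_param` objects.
#' @export
subagcn_params <- function(input_dim, n_relations, cfg, seed = 1L) {
  stopifnot(cfg$num_bases <= 2L * n_relations)
  set.seed(seed)
  d0 <- as.integer(input_dim)
  dh <- cfg$hidden_dim
  r2 <- 2L * n_relations
  p <- list(
    rel_emb = ad_param(xavier_uniform(r2, d0)),
    W_I = ad_param(xavier_uniform(d0, d0)),
    W_J = ad_param(xavier_uniform(d0, d0))
  )
  dims <- c(d0, rep(dh, cfg$layers))
  for (t in seq_len(cfg$layers)) {
    din <- dims[t]
    for (b in seq_len(cfg$num_bases)) {
      p[[sprintf("V_%d_%d", t, b)]] <- ad_param(xavier_uniform(din, dh))
    }
    p[[sprintf("a_%d", t)]] <- ad_param(xavier_uniform(r2, cfg$num_bases))
    p[[sprintf("W_self_%d", t)]] <- ad_param(xavier_uniform(din, dh))
    p[[sprintf("W_g_%d", t)]] <- ad_param(xavier_uniform(din, 2L * dh))
    p[[sprintf("b_g_%d", t)]] <- ad_param(matrix(0, 1L, 2L * dh))
  }
  for (t in 0:cfg$layers) {
    dt <- dims[t + 1L]
    p[[sprintf("W_sub_%d", t)]] <- ad_param(xavier_uniform(dt, dt))
  }
  p
}

# Attention scores over a doubled edge set, from layer-0 states only
# (layer-independent attention). Returns list(alpha, tau) of AD nodes, or
# NULL when the subgraph has no edges.
subagcn_attention_ad <- function(h0, de, params, cfg) {
  if (length(de$src) == 0L) return(NULL)
  if (max(de$rel) > nrow(params$rel_emb$v)) {
    rlang::abort(sprintf("no relation embedding for relation index %d",
                         max(de$rel)))
  }
  d0 <- ncol(h0$v)
  denom <- if (cfg$attention_scale == "dim") d0 else sqrt(d0)
  hj <- ad_rows(ad_mm(h0, params$W_J), de$dst)
  hi <- ad_add(ad_rows(ad_mm(h0, params$W_I), de$src),
               ad_rows(params$rel_emb, de$rel))
  alpha <- ad_tanh(ad_scale(ad_dot_rows(hj, hi), 1 / denom))
  mask <- (alpha$v > cfg$zeta) * 1
  tau <- ad_scale(alpha, mask)
  list(alpha = alpha, tau = tau)
}

# One message-passing layer. Gates (gamma, beta) come from an affine map of
# the edge's target node state; relation weights are basis combinations;
# tau (fixed across layers) scales each gated message; node update is
# ReLU(h W_self + sum of incoming messages).
subagcn_layer_ad <- function(h, de, tau, params, cfg, t) {
  dh <- cfg$hidden_dim
  g <- ad_add_rowvec(ad_mm(h, params[[sprintf("W_g_%d", t)]]),
                     params[[sprintf("b_g_%d", t)]])
  gamma <- ad_cols(g, 1:dh)
  beta <- ad_cols(g, dh + (1:dh))
  pre <- ad_mm(h, params[[sprintf("W_self_%d", t)]])
  if (length(de$src) > 0L) {
    coefs <- ad_rows(params[[sprintf("a_%d", t)]], de$rel)
    msg <- ad_add_n(lapply(seq_len(cfg$num_bases), function(b) {
      hv <- ad_mm(h, params[[sprintf("V_%d_%d", t, b)]])
      ad_rowscale(ad_rows(hv, de$src), ad_cols(coefs, b))
    }))
    gated <- ad_add(ad_mul(ad_rows(gamma, de$dst), msg),
                    ad_rows(beta, de$dst))
    bmat <- ad_scatter_rows(ad_rowscale(gated, tau), de$dst, nrow(h$v))
    pre <- ad_add(pre, bmat)
  }
  ad_relu(pre)
}

# Full forward: initial states -> per-layer states -> layer-aggregated pair
# representation h_dp = concat over layers of [h_u; h_v; mean_i(h_i W_sub)].
subagcn_forward_ad <- function(h0, de, u_local, v_local, params, cfg) {
  att <- subagcn_attention_ad(h0, de, params, cfg)
  states <- vector("list", cfg$layers + 1L)
  states[[1L]] <- h0
  h <- h0
  for (t in seq_len(cfg$layers)) {
    h <- subagcn_layer_ad(h, de, if (is.null(att)) NULL else att$tau,
                          params, cfg, t)
    states[[t + 1L]] <- h
  }
  parts <- list()
  for (t in 0:cfg$layers) {
    st <- states[[t + 1L]]
    hg <- ad_mean_rows(ad_mm(st, params[[sprintf("W_sub_%d", t)]]))
    parts <- c(parts, list(ad_rows(st, u_local), ad_rows(st, v_local), hg))
  }
  list(h_dp = ad_concat_cols(parts), states = states, attention = att)
}

subgraph_local_endpoints <- function(sub) {
  u <- match(sub$pair[["u"]], sub$members$id)
  v <- match(sub$pair[["v"]], sub$members$id)
  c(u = u, v = v)
}

#' Edge attention scores for an enclosing subgraph
#'
#' Computes, for every stored edge and its generated inverse, the signal
#' strength score `alpha = tanh((h_j W_J) . (h_i W_I + r_ij) / d0)` from the
#' layer-0 node states, and the pruned weight `tau` (equal to `alpha` when
#' `alpha > zeta`, else 0).
#'
#' @param sub A labeled `ddi_subgraph` (see [label_nodes()]).
#' @param params Parameters from [subagcn_params()].
#' @param cfg A [subagcn_config()].
#' @param n_relations Number of stored relation types in the parent graph.
#' @return Tibble with `src`, `dst` (local member rows), `rel`, `alpha`,
#'   `tau`; zero rows if the subgraph has no edges.
#' @export
edge_attention <- function(sub, params, cfg, n_relations) {
  de <- double_edges(sub$edges, n_relations)
  att <- subagcn_attention_ad(ad_const(sub$init_states), de, params, cfg)
  if (is.null(att)) {
    return(tibble::tibble(src = integer(), dst = integer(), rel = integer(),
                          alpha = numeric(), tau = numeric()))
  }
  tibble::tibble(src = de$src, dst = de$dst, rel = de$rel,
                 alpha = as.vector(att$alpha$v), tau = as.vector(att$tau$v))
}

#' FiLM-style gates from node states
#'
#' One affine map of the target-node state produces `2 * d` outputs split
#' into a multiplicative gate `gamma` and an additive gate `beta` applied
#' to incoming messages.
#'
#' @param states Numeric matrix of node states (n x d_in).
#' @param W_g,b_g Affine map weights (d_in x 2 d_out) and bias (1 x 2 d_out).
#' @return List with matrices `gamma` and `beta` (n x d_out).
#' @export
film_gates <- function(states, W_g, b_g) {
  if (ncol(states) != nrow(W_g)) {
    rlang::abort("state width does not match gate weight rows")
  }
  g <- sweep(states %*% W_g, 2L, as.vector(b_g), "+")
  d <- ncol(g) / 2L
  list(gamma = g[, 1:d, drop = FALSE], beta = g[, d + (1:d), drop = FALSE])
}

#' Relation weight matrix from basis decomposition
#'
#' `W_r = sum_b a_rb V_b`: each relation's transform is a shared linear
#' combination of `B` basis matrices, limiting per-relation parameters.
#'
#' @param bases List of B equally shaped matrices.
#' @param coefs Numeric vector of length B (the relation's coefficient row).
#' @return The combined weight matrix.
#' @export
relation_weight <- function(bases, coefs) {
  if (length(coefs) != length(bases)) {
    rlang::abort("coefficient row length must equal the number of bases")
  }
  Reduce(`+`, Map(function(v, a) a * v, bases, as.list(coefs)))
}

#' One message-passing layer over a subgraph (numeric front end)
#'
#' Applies a single attention-gated relational layer to given node states:
#' `h'_v = ReLU(h_v W_self + sum_u tau_uv (gamma_v * (h_u W_r) + beta_v))`
#' with `W_r` built from the layer's basis decomposition and the gates from
#' [film_gates()] of the target state.
#'
#' @param states Numeric n x d_in matrix of node states.
#' @param edges List with integer vectors `src`, `dst`, `rel` (a doubled
#'   edge set as built internally; see [edge_attention()] output).
#' @param tau Numeric vector of pruned attention weights, one per edge.
#' @param params Parameters from [subagcn_params()].
#' @param cfg A [subagcn_config()].
#' @param layer Which layer's parameters to use (default 1).
#' @return Numeric n x hidden_dim matrix of updated states.
#' @export
propagate_layer <- function(states, edges, tau, params, cfg, layer = 1L) {
  de <- list(src = as.integer(edges$src), dst = as.integer(edges$dst),
             rel = as.integer(edges$rel))
  tau_node <- if (length(de$src) > 0L) {
    ad_const(matrix(tau, ncol = 1L))
  } else {
    NULL
  }
  subagcn_layer_ad(ad_const(states), de, tau_node, params, cfg, layer)$v
}

#' Drug-pair representation from an enclosing subgraph
#'
#' Runs the full attention-gated relational message passing over a labeled
#' subgraph and returns the layer-aggregated pair representation: the
#' concatenation over layers t = 0..T of the two endpoint states and the
#' subgraph readout `mean_i(h_i W_sub)`.
#'
#' @inheritParams edge_attention
#' @return List with `h_dp` (numeric row vector), `states` (list of
#'   per-layer state matrices), and `attention` (tibble as from
#'   [edge_attention()]).
#' @export
pair_representation <- function(sub, params, cfg, n_relations) {
  de <- double_edges(sub$edges, n_relations)
  ep <- subgraph_local_endpoints(sub)
  fw <- subagcn_forward_ad(ad_const(sub$init_states), de,
                           ep[["u"]], ep[["v"]], params, cfg)
  att <- if (is.null(fw$attention)) {
    tibble::tibble(src = integer(), dst = integer(), rel = integer(),
                   alpha = numeric(), tau = numeric())
  } else {
    tibble::tibble(src = de$src, dst = de$dst, rel = de$rel,
                   alpha = as.vector(fw$attention$alpha$v),
                   tau = as.vector(fw$attention$tau$v))
  }
  list(h_dp = fw$h_dp$v, states = lapply(fw$states, function(s) s$v),
       attention = att)
}

#' Length of the pair representation for given dimensions
#'
#' @param input_dim Layer-0 state width.
#' @param hidden_dim Hidden state width.
#' @param layers Number of layers T.
#' @return Integer: `3 * input_dim + layers * 3 * hidden_dim`.
#' @export
pair_representation_length <- function(input_dim, hidden_dim, layers) {
  as.integer(3L * input_dim + layers * 3L * hidden_dim)
}
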