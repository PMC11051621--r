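test_that("edge attention follows the tanh inner-product formula", {
  sub <- scalar_subgraph()
  cfg <- subagcn_config(layers = 1, hidden_dim = 1, num_bases = 1,
                        zeta = 0.1)

  # weights chosen so the inner product vanishes -> alpha = 0, tau = 0
  p0 <- scalar_attention_params(0)
  att0 <- edge_attention(sub, p0, cfg, n_relations = 1)
  expect_equal(att0$alpha, c(0, 0))
  expect_equal(att0$tau, c(0, 0))

  # 1-D hand case: h_i = h_j = 1, W_I = W_J = r = 1, d0 = 1 -> tanh(2)
  p1 <- scalar_attention_params(1)
  att1 <- edge_attention(sub, p1, cfg, n_relations = 1)
  expect_equal(att1$alpha, rep(tanh(2), 2), tolerance = 1e-12)

  # sqrt scaling option changes the divisor
  cfg2 <- subagcn_config(layers = 1, hidden_dim = 1, num_bases = 1,
                         zeta = -1, attention_scale = "sqrt_dim")
  sub4 <- sub
  sub4$init_states <- matrix(1, 2L, 4L)
  p4 <- list(rel_emb = ddiextract:::ad_param(matrix(1, 2, 4)),
             W_I = ddiextract:::ad_param(diag(4)),
             W_J = ddiextract:::ad_param(diag(4)))
  att4 <- edge_attention(sub4, p4, cfg2, n_relations = 1)
  expect_equal(att4$alpha[1], tanh(sum(rep(1, 4) * rep(2, 4)) / 2),
               tolerance = 1e-12)
})

test_that("attention stays in [-1, 1] and pruning is monotone in zeta", {
  set.seed(5)
  kg <- load_kg(random_edge_table(30, 0.15), quiet = TRUE)
  uv <- sample(kg$nodes$id, 2)
  sub <- extract_enclosing_subgraph(kg, uv[1], uv[2], 2)
  sub <- label_nodes(sub, init_node_embeddings(kg, graph_dim = 6, seed = 2))
  cfg <- subagcn_config(layers = 2, hidden_dim = 5, num_bases = 2)
  params <- subagcn_params(ncol(sub$init_states), length(kg$relations), cfg,
                           seed = 4)
  surviving <- c()
  for (z in c(-1, -0.5, 0, 0.3, 0.9)) {
    cfgz <- subagcn_config(layers = 2, hidden_dim = 5, num_bases = 2,
                           zeta = z)
    att <- edge_attention(sub, params, cfgz, length(kg$relations))
    expect_true(all(att$alpha >= -1 & att$alpha <= 1))
    expect_true(all(att$tau == 0 | att$tau > z))
    surviving <- c(surviving, sum(att$tau != 0))
  }
  # zeta = -1 disables pruning entirely; raising zeta never adds edges
  expect_equal(surviving[1], 2L * nrow(sub$edges))
  expect_true(all(diff(surviving) <= 0))
})

test_that("FiLM gates are an affine function of the target state", {
  # zero weights with bias pattern (1...1, 0...0) make gating the identity
  W_g <- matrix(0, 3, 4)
  b_g <- matrix(c(1, 1, 0, 0), 1)
  g <- film_gates(matrix(rnorm(6), 2, 3), W_g, b_g)
  expect_equal(g$gamma, matrix(1, 2, 2))
  expect_equal(g$beta, matrix(0, 2, 2))

  # 2x2 hand computation
  st <- matrix(c(1, 2), 1, 2)
  W <- matrix(c(0.5, -1, 2, 0, 1, 1, -0.5, 0.25), 2, 4)
  b <- matrix(c(0.1, 0.2, 0.3, 0.4), 1)
  gg <- film_gates(st, W, b)
  full <- st %*% W + matrix(b, 1, 4)
  expect_equal(gg$gamma, full[, 1:2, drop = FALSE])
  expect_equal(gg$beta, full[, 3:4, drop = FALSE])

  # equal states give equal gates
  two <- film_gates(rbind(st, st), W, b)
  expect_equal(two$gamma[1, ], two$gamma[2, ])

  expect_error(film_gates(matrix(0, 1, 4), W, b), "width")
})

test_that("basis decomposition reproduces relation weights", {
  # identity coefficients select each basis exactly
  V <- lapply(1:3, function(i) matrix(rnorm(4), 2, 2))
  expect_equal(relation_weight(V, c(1, 0, 0)), V[[1]])
  expect_equal(relation_weight(V, c(0, 0, 1)), V[[3]])

  # closed form: 0.5 I + 0.5 (2 I) = 1.5 I
  expect_equal(relation_weight(list(diag(2), 2 * diag(2)), c(0.5, 0.5)),
               1.5 * diag(2))

  # single basis: all relations share V_1 up to a scalar
  expect_equal(relation_weight(V[1], 2), 2 * V[[1]])
  expect_error(relation_weight(V, c(1, 0)), "length")
})

test_that("message passing matches a per-edge hand computation", {
  set.seed(9)
  cfg <- subagcn_config(layers = 1, hidden_dim = 3, num_bases = 2)
  params <- subagcn_params(4, 2, cfg, seed = 11)
  states <- matrix(rnorm(16), 4, 4)
  de <- list(src = c(1L, 2L, 3L), dst = c(2L, 3L, 1L), rel = c(1L, 3L, 4L))
  tau <- c(0.7, 0, -0.2)

  got <- propagate_layer(states, de, tau, params, cfg)
  want <- oracle_propagate(states, de, tau, params, cfg)
  expect_equal(got, want, tolerance = 1e-10)

  # isolated nodes: empty neighborhood reduces to ReLU(h W_self)
  none <- list(src = integer(), dst = integer(), rel = integer())
  iso <- propagate_layer(states, none, numeric(), params, cfg)
  expect_equal(iso, pmax(states %*% params$W_self_1$v, 0))

  # all tau = 0 is identical to the isolated-node case for every node
  allz <- propagate_layer(states, de, c(0, 0, 0), params, cfg)
  expect_equal(allz, iso)
})

test_that("pruning by edge deletion equals tau = 0 masking exactly", {
  set.seed(31)
  kg <- load_kg(random_edge_table(40, 0.12), quiet = TRUE)
  uv <- sample(kg$nodes$id, 2)
  sub <- extract_enclosing_subgraph(kg, uv[1], uv[2], 2)
  sub <- label_nodes(sub, init_node_embeddings(kg, graph_dim = 6, seed = 5))
  nrel <- length(kg$relations)
  cfg <- subagcn_config(layers = 2, hidden_dim = 5, num_bases = 3, zeta = 0)
  params <- subagcn_params(ncol(sub$init_states), nrel, cfg, seed = 13)

  full <- pair_representation(sub, params, cfg, nrel)

  # re-run on the doubled edge set with pruned edges physically removed
  de <- ddiextract:::double_edges(sub$edges, nrel)
  keep <- full$attention$tau != 0
  de_kept <- lapply(de, function(x) x[keep])
  ep <- ddiextract:::subgraph_local_endpoints(sub)
  fw <- ddiextract:::subagcn_forward_ad(
    ddiextract:::ad_const(sub$init_states), de_kept,
    ep[["u"]], ep[["v"]], params, cfg)
  expect_equal(as.vector(fw$h_dp$v), as.vector(full$h_dp))
})

test_that("identity basis coefficients recover per-relation weights", {
  set.seed(17)
  nrel <- 2L
  cfg <- subagcn_config(layers = 1, hidden_dim = 3,
                        num_bases = 2L * nrel)  # B = |R| (doubled)
  params <- subagcn_params(3, nrel, cfg, seed = 19)
  params$a_1$v <- diag(2L * nrel)
  states <- matrix(rnorm(9), 3, 3)
  de <- list(src = c(1L, 2L), dst = c(2L, 3L), rel = c(2L, 4L))
  tau <- c(0.5, 0.9)

  got <- propagate_layer(states, de, tau, params, cfg)

  # independent computation with the relation's own basis as its weight
  g <- film_gates(states, params$W_g_1$v, params$b_g_1$v)
  b_msg <- matrix(0, 3, 3)
  for (e in 1:2) {
    W_r <- params[[sprintf("V_1_%d", de$rel[e])]]$v
    m <- g$gamma[de$dst[e], ] * (states[de$src[e], ] %*% W_r) +
      g$beta[de$dst[e], ]
    b_msg[de$dst[e], ] <- b_msg[de$dst[e], ] + tau[e] * as.vector(m)
  }
  want <- pmax(states %*% params$W_self_1$v + b_msg, 0)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("readout is permutation invariant and dimension bookkeeping holds", {
  set.seed(23)
  kg <- load_kg(random_edge_table(40, 0.12), quiet = TRUE)
  uv <- sample(kg$nodes$id, 2)
  sub <- extract_enclosing_subgraph(kg, uv[1], uv[2], 3)
  emb <- init_node_embeddings(kg, graph_dim = 75, seed = 2)
  sub <- label_nodes(sub, emb)
  nrel <- length(kg$relations)
  cfg <- subagcn_config(layers = 3, hidden_dim = 75, num_bases = 2)
  params <- subagcn_params(ncol(sub$init_states), nrel, cfg, seed = 3)

  pr <- pair_representation(sub, params, cfg, nrel)
  # k = 3, graph_dim = 75: d0 = 83; T = 3 layers of width 75
  expect_equal(ncol(sub$init_states), 83L)
  expect_equal(length(pr$h_dp), pair_representation_length(83, 75, 3))
  expect_equal(length(pr$h_dp), 3 * 83 + 3 * 3 * 75)

  # permuting member order leaves h_dp bit-identical
  perm <- sample(nrow(sub$members))
  sub2 <- sub
  sub2$members <- sub$members[perm, ]
  sub2$init_states <- sub$init_states[perm, , drop = FALSE]
  sub2$labels <- sub$labels[perm, , drop = FALSE]
  inv <- match(seq_along(perm), perm)
  sub2$edges$src <- inv[sub$edges$src]
  sub2$edges$dst <- inv[sub$edges$dst]
  pr2 <- pair_representation(sub2, params, cfg, nrel)
  expect_identical(pr2$h_dp, pr$h_dp)

  # constant states: readout mean equals W_sub applied to the shared state
  h <- matrix(rnorm(5), 1)
  cst <- ddiextract:::ad_const(matrix(rep(h, 4), 4, byrow = TRUE))
  m <- ddiextract:::ad_mean_rows(
    ddiextract:::ad_mm(cst, ddiextract:::ad_const(diag(5) * 2)))
  expect_equal(as.vector(m$v), as.vector(h %*% (diag(5) * 2)))
})

test_that("the forward pass is deterministic under a fixed seed", {
  run <- function() {
    set.seed(77)
    kg <- load_kg(random_edge_table(30, 0.15), quiet = TRUE)
    uv <- sample(kg$nodes$id, 2)
    sub <- extract_enclosing_subgraph(kg, uv[1], uv[2], 2)
    sub <- label_nodes(sub, init_node_embeddings(kg, graph_dim = 6,
                                                 seed = 8))
    cfg <- subagcn_config(layers = 2, hidden_dim = 5, num_bases = 2)
    params <- subagcn_params(ncol(sub$init_states), length(kg$relations),
                             cfg, seed = 6)
    pair_representation(sub, params, cfg, length(kg$relations))$h_dp
  }
  expect_identical(run(), run())
})

test_that("autodiff gradients agree with finite differences", {
  w <- small_world(n = 8L, seed = 41L)
  cfg <- small_model_config()
  vocab <- build_vocab(w$instances$text)
  preps <- prepare_instances(w$instances, w$kg, vocab, cfg)
  params <- ddiextract:::ddi_init_params(cfg, w$kg, vocab)
  alpha <- rep(0.2, 5)

  loss_value <- function() {
    fw <- ddiextract:::ddi_forward_ad(preps[[1]], params, cfg)
    ddiextract:::focal_loss_ad(fw$scores, preps[[1]]$y, alpha, 2)$v[1]
  }

  check_param <- function(name, i, j) {
    ddiextract:::ad_zero_grad(params)
    ddiextract:::ad_tape_start()
    fw <- ddiextract:::ddi_forward_ad(preps[[1]], params, cfg)
    loss <- ddiextract:::focal_loss_ad(fw$scores, preps[[1]]$y, alpha, 2)
    ddiextract:::ad_backward(loss)
    ddiextract:::ad_tape_stop()
    g_auto <- params[[name]]$grad[i, j]
    eps <- 1e-5
    orig <- params[[name]]$v[i, j]
    params[[name]]$v[i, j] <- orig + eps
    up <- loss_value()
    params[[name]]$v[i, j] <- orig - eps
    dn <- loss_value()
    params[[name]]$v[i, j] <- orig
    g_fd <- (up - dn) / (2 * eps)
    expect_equal(g_auto, g_fd, tolerance = 1e-4)
  }

  check_param("V_1_1", 1, 1)
  check_param("W_conv", 3, 2)
  check_param("W_pred", 1, 1)
  check_param("rel_emb", 1, 1)
  check_param("tok_emb", preps[[1]]$ids[1], 2)
})
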