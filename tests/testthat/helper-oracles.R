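# Independent brute-force oracles used by the test suite. These deliberately
# avoid the package's own code paths (and igraph): plain queue-based BFS,
# explicit contingency tables, pairwise rank statistics.

# queue BFS distances from `start` over an undirected edge list
oracle_bfs <- function(node_ids, heads, tails, start) {
  dist <- stats::setNames(rep(Inf, length(node_ids)), node_ids)
  adj <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (i in seq_along(heads)) {
    adj[[heads[i]]] <- c(adj[[heads[i]]], tails[i])
    adj[[tails[i]]] <- c(adj[[tails[i]]], heads[i])
  }
  dist[start] <- 0
  queue <- start
  while (length(queue) > 0L) {
    cur <- queue[1L]
    queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (dist[nb] == Inf) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

# enclosing subgraph by definition: intersection of the k-hop neighborhoods
# plus the endpoints; induced edges with both endpoints inside
oracle_enclosing_subgraph <- function(edge_df, u, v, k) {
  node_ids <- sort(unique(c(edge_df$head, edge_df$tail)))
  du <- oracle_bfs(node_ids, edge_df$head, edge_df$tail, u)
  dv <- oracle_bfs(node_ids, edge_df$head, edge_df$tail, v)
  members <- sort(unique(c(node_ids[du[node_ids] <= k & dv[node_ids] <= k],
                           u, v)))
  keep <- edge_df$head %in% members & edge_df$tail %in% members
  list(members = members, edges = edge_df[keep, , drop = FALSE],
       dist_u = du[members], dist_v = dv[members])
}

# random Erdos-Renyi typed edge list over n nodes
random_edge_table <- function(n, p_edge = 0.08) {
  ids <- sprintf("N%03d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  sel <- stats::runif(ncol(pairs)) < p_edge
  if (!any(sel)) sel[sample.int(ncol(pairs), 1L)] <- TRUE
  tibble::tibble(
    head = ids[pairs[1L, sel]],
    head_type = "drug",
    relation = sample(c("r1", "r2"), sum(sel), replace = TRUE),
    tail = ids[pairs[2L, sel]],
    tail_type = "drug"
  )
}

# full evaluation by explicit counting, independent of ddi_evaluate()
oracle_eval <- function(gold, pred, scores, levels, scope_levels) {
  tp <- fp <- fn <- stats::setNames(numeric(length(levels)), levels)
  for (cl in levels) {
    tp[cl] <- sum(gold == cl & pred == cl)
    fp[cl] <- sum(gold != cl & pred == cl)
    fn[cl] <- sum(gold == cl & pred != cl)
  }
  p_i <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r_i <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  s <- scope_levels
  micro_p <- sum(tp[s]) / sum(tp[s] + fp[s])
  micro_r <- sum(tp[s]) / sum(tp[s] + fn[s])
  macro_p <- mean(p_i[s])
  macro_r <- mean(r_i[s])
  harm <- function(a, b) if (a + b > 0) 2 * a * b / (a + b) else 0
  aucs <- vapply(levels, function(cl) {
    oracle_auc(gold == cl, scores[, match(cl, levels)])
  }, 1)
  auprs <- vapply(levels, function(cl) {
    oracle_aupr(gold == cl, scores[, match(cl, levels)])
  }, 1)
  flat_truth <- unlist(lapply(s, function(cl) gold == cl))
  flat_score <- as.vector(scores[, match(s, levels)])
  list(
    tp = tp, fp = fp, fn = fn, precision = p_i, recall = r_i,
    micro = c(precision = micro_p, recall = micro_r,
              f1 = harm(micro_p, micro_r)),
    macro = c(precision = macro_p, recall = macro_r,
              f1 = harm(macro_p, macro_r)),
    auc = aucs, aupr = auprs,
    micro_auc = oracle_auc(flat_truth, flat_score),
    micro_aupr = oracle_aupr(flat_truth, flat_score),
    # classes without positives have undefined AUC/AUPR; the macro mean is
    # taken over the classes where the curve exists
    macro_auc = mean(aucs[match(s, levels)], na.rm = TRUE),
    macro_aupr = mean(auprs[match(s, levels)], na.rm = TRUE)
  )
}

# AUC as the probability a positive outranks a negative (ties count half),
# by explicit pairwise comparison
oracle_auc <- function(truth, score) {
  pos <- score[truth]
  neg <- score[!truth]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# AUPR by an explicit loop over distinct thresholds (trapezoid rule,
# starting at recall 0 / precision 1)
oracle_aupr <- function(truth, score) {
  n_pos <- sum(truth)
  if (n_pos == 0L) return(NA_real_)
  thr <- sort(unique(score), decreasing = TRUE)
  prec <- rec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    sel <- score >= thr[i]
    prec[i] <- sum(sel & truth) / sum(sel)
    rec[i] <- sum(sel & truth) / n_pos
  }
  prec <- c(1, prec)
  rec <- c(0, rec)
  sum(diff(rec) * (prec[-1L] + prec[-length(prec)]) / 2)
}

# plain-R single relational layer used as the propagation oracle:
# per-edge loop, explicit relation weight assembly
oracle_propagate <- function(states, edges, tau, params, cfg, layer = 1L) {
  dh <- cfg$hidden_dim
  n <- nrow(states)
  W_g <- params[[sprintf("W_g_%d", layer)]]$v
  b_g <- params[[sprintf("b_g_%d", layer)]]$v
  W_self <- params[[sprintf("W_self_%d", layer)]]$v
  a <- params[[sprintf("a_%d", layer)]]$v
  bases <- lapply(seq_len(cfg$num_bases), function(b) {
    params[[sprintf("V_%d_%d", layer, b)]]$v
  })
  g <- sweep(states %*% W_g, 2L, as.vector(b_g), "+")
  gamma <- g[, 1:dh, drop = FALSE]
  beta <- g[, dh + (1:dh), drop = FALSE]
  b_msg <- matrix(0, n, dh)
  for (e in seq_along(edges$src)) {
    W_r <- Reduce(`+`, Map(function(V, co) co * V, bases,
                           as.list(a[edges$rel[e], ])))
    msg <- gamma[edges$dst[e], ] * (states[edges$src[e], , drop = FALSE] %*%
                                      W_r) + beta[edges$dst[e], ]
    b_msg[edges$dst[e], ] <- b_msg[edges$dst[e], ] + tau[e] * as.vector(msg)
  }
  pmax(states %*% W_self + b_msg, 0)
}
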