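#' Full run configuration
#'
#' Collects every hyperparameter of the classifier. The defaults mirror the
#' reference experimental setting (maximum length 390 word pieces, position
#' embedding width 10, convolution window 5, dropout 0.1, weight decay
#' 0.01, hop 3, graph dimension 75, adaptive-moment optimizer at learning
#' rate 5e-5, batch size 32, 5 epochs, focal gamma 2). Desk-scale synthetic
#' experiments typically shrink the dimensions and raise the learning rate;
#' see the package vignette.
#'
#' @param max_length Maximum token count per sentence.
#' @param d_p Position-embedding width per drug channel.
#' @param d_w Contextual-embedding width of the tiny trainable encoder.
#' @param graph_dim Node-embedding width.
#' @param hop Subgraph hop count k.
#' @param layers,hidden_dim,num_bases,zeta,attention_scale Subgraph network
#'   settings; see [subagcn_config()].
#' @param fusion_method,window,channels,dropout,d_lstm Fusion head
#'   settings; see [fusion_config()].
#' @param lr,batch_size,epochs,weight_decay Optimizer settings.
#' @param gamma,focal_form,weighting Loss settings; see
#'   [multi_focal_loss()] and [class_weights()].
#' @param use_position,use_subgraph Ablation switches: when off, the
#'   corresponding feature block is replaced by zeros of the same shape.
#' @param eval_classes Averaging scope for reported metrics.
#' @param seed Integer seed for all randomness.
#' @return A list of class `ddi_config`.
#' @export
ddi_config <- function(max_length = 390L, d_p = 10L, d_w = 32L,
                       graph_dim = 75L, hop = 3L, layers = 3L,
                       hidden_dim = 75L, num_bases = 4L, zeta = 0,
                       attention_scale = "dim", fusion_method = 2L,
                       window = 5L, channels = 32L, dropout = 0.1,
                       d_lstm = 32L, lr = 5e-5, batch_size = 32L,
                       epochs = 5L, weight_decay = 0.01, gamma = 2,
                       focal_form = "true_class", weighting = "printed",
                       use_position = TRUE, use_subgraph = TRUE,
                       eval_classes = "positives_only", seed = 1L) {
  cfg <- list(
    max_length = as.integer(max_length), d_p = as.integer(d_p),
    d_w = as.integer(d_w), graph_dim = as.integer(graph_dim),
    hop = as.integer(hop),
    subagcn = subagcn_config(layers, hidden_dim, num_bases, zeta,
                             attention_scale),
    fusion = fusion_config(fusion_method, window, channels, dropout, d_lstm),
    lr = lr, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), weight_decay = weight_decay,
    gamma = gamma, focal_form = focal_form, weighting = weighting,
    use_position = isTRUE(use_position), use_subgraph = isTRUE(use_subgraph),
    eval_classes = eval_classes, seed = as.integer(seed)
  )
  class(cfg) <- "ddi_config"
  cfg
}

ddi_input_dim <- function(cfg) cfg$graph_dim + 2L * (cfg$hop + 1L)

ddi_hdp_length <- function(cfg) {
  pair_representation_length(ddi_input_dim(cfg), cfg$subagcn$hidden_dim,
                             cfg$subagcn$layers)
}

#' Prepare candidate instances for the model
#'
#' Tokenizes each anonymized sentence, computes drug-relative offsets, and
#' extracts + labels the pair's enclosing subgraph (cached per drug pair).
#'
#' @param instances Candidate tibble with `db1`, `db2`, `text`, `label`.
#' @param kg A `ddi_kg` containing all mapped drugs.
#' @param vocab Vocabulary for tokenization.
#' @param cfg A [ddi_config()].
#' @return List of per-instance prepared structures.
#' @export
prepare_instances <- function(instances, kg, vocab, cfg) {
  classes <- ddi_classes()
  n_rel <- length(kg$relations)
  cache <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(instances)), function(i) {
    toks <- tokenize(instances$text[i], vocab, cfg$max_length)
    n <- length(toks$tokens)
    o1 <- relative_offsets(n, toks$drug1, cfg$max_length)
    o2 <- relative_offsets(n, toks$drug2, cfg$max_length)
    key <- paste(instances$db1[i], instances$db2[i], sep = "|")
    sub <- cache[[key]]
    if (is.null(sub)) {
      sg <- extract_enclosing_subgraph(kg, instances$db1[i],
                                       instances$db2[i], cfg$hop)
      ep <- subgraph_local_endpoints(sg)
      sub <- list(member_idx = sg$members$node_idx,
                  p = distance_labels(sg),
                  de = double_edges(sg$edges, n_rel),
                  u_local = ep[["u"]], v_local = ep[["v"]])
      cache[[key]] <- sub
    }
    list(ids = toks$ids, n = n, o1 = o1, o2 = o2,
         d1 = toks$drug1, d2 = toks$drug2, sub = sub,
         y = match(instances$label[i], classes))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# initialize every trainable parameter of the model under cfg$seed
ddi_init_params <- function(cfg, kg, vocab) {
  d0 <- ddi_input_dim(cfg)
  n_rel <- length(kg$relations)
  set.seed(cfg$seed)
  node_emb <- ad_param(xavier_uniform(nrow(kg$nodes), cfg$graph_dim,
                                      gain = 2))
  gp <- subagcn_params(d0, n_rel, cfg$subagcn, seed = cfg$seed + 1L)
  enc <- tiny_encoder_params(length(vocab), cfg$d_w, cfg$max_length,
                             seed = cfg$seed + 2L)
  set.seed(cfg$seed + 3L)
  pos <- list(pos1 = ad_param(xavier_uniform(2L * cfg$max_length + 1L,
                                             cfg$d_p)),
              pos2 = ad_param(xavier_uniform(2L * cfg$max_length + 1L,
                                             cfg$d_p)))
  fus <- fusion_params(cfg$fusion, cfg$d_w, 2L * cfg$d_p,
                       ddi_hdp_length(cfg), n_classes = 5L,
                       seed = cfg$seed + 4L)
  c(list(node_emb = node_emb), gp, enc, pos, fus)
}

# AD forward for one prepared instance; returns list(scores node, H node)
ddi_forward_ad <- function(prep, params, cfg, training = FALSE) {
  e_w <- tiny_encoder_ad(prep$ids, params)
  e_p <- if (cfg$use_position) {
    ad_concat_cols(list(
      ad_rows(params$pos1, prep$o1 + cfg$max_length + 1L),
      ad_rows(params$pos2, prep$o2 + cfg$max_length + 1L)
    ))
  } else {
    ad_const(matrix(0, prep$n, 2L * cfg$d_p))
  }
  h_dp <- if (cfg$use_subgraph) {
    h0 <- ad_concat_cols(list(ad_rows(params$node_emb, prep$sub$member_idx),
                              ad_const(prep$sub$p)))
    subagcn_forward_ad(h0, prep$sub$de, prep$sub$u_local, prep$sub$v_local,
                       params, cfg$subagcn)$h_dp
  } else {
    ad_const(matrix(0, 1L, ddi_hdp_length(cfg)))
  }
  H <- fuse_ad(e_w, e_p, h_dp, cfg$fusion, params, prep$d1, prep$d2)
  if (training && cfg$fusion$dropout > 0) {
    keep <- 1 - cfg$fusion$dropout
    mask <- matrix((stats::runif(ncol(H$v)) < keep) / keep, 1L)
    H <- ad_scale(H, mask)
  }
  s <- ad_add_rowvec(ad_mm(H, params$W_pred), params$b_pred)
  list(scores = s, H = H)
}

ddi_predict_probs <- function(preps, params, cfg) {
  t(vapply(preps, function(prep) {
    s <- ddi_forward_ad(prep, params, cfg, training = FALSE)$scores$v
    z <- s - max(s)
    as.vector(exp(z) / sum(exp(z)))
  }, numeric(5L)))
}

#' Train the DDI classifier
#'
#' Mini-batch training with the adaptive-moment optimizer (decoupled weight
#' decay) and the multi-focal loss with count-derived class weights. With
#' `use_subgraph = FALSE` the pair representation is replaced by a zero
#' vector of the same length; with `use_position = FALSE` the position
#' embeddings are zeroed. No early stopping is applied unless
#' `stop_train_f1` is set, in which case training halts once the train
#' micro-F1 reaches that value.
#'
#' @param instances Candidate tibble (with `db1`/`db2` from
#'   [map_to_drugbank()] or the synthetic generator).
#' @param kg A `ddi_kg`.
#' @param cfg A [ddi_config()].
#' @param vocab Optional vocabulary (defaults to [build_vocab()] of the
#'   training texts).
#' @param epochs Overrides `cfg$epochs` when given.
#' @param stop_train_f1 Optional train micro-F1 at which to halt.
#' @param verbose Print one line per epoch.
#' @return A `ddi_fit`: parameters, config, vocabulary, the knowledge
#'   graph, class weights, and a per-epoch training `log` tibble
#'   (`epoch`, `loss`, `micro_f1`, `macro_f1`).
#' @export
ddi_train <- function(instances, kg, cfg, vocab = NULL, epochs = NULL,
                      stop_train_f1 = NULL, verbose = FALSE) {
  if (nrow(instances) == 0L) rlang::abort("empty training set")
  classes <- ddi_classes()
  epochs <- epochs %||% cfg$epochs
  vocab <- vocab %||% build_vocab(instances$text)
  preps <- prepare_instances(instances, kg, vocab, cfg)
  params <- ddi_init_params(cfg, kg, vocab)
  counts <- vapply(classes, function(cl) sum(instances$label == cl), 1L)
  alpha <- class_weights(counts, weighting = cfg$weighting)
  opt <- adam_state(params)
  skip_decay <- c("node_emb", "tok_emb", "seq_pos_emb", "pos1", "pos2",
                  grep("^b_", names(params), value = TRUE))

  n <- length(preps)
  log <- vector("list", epochs)
  set.seed(cfg$seed + 10L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      ad_zero_grad(params)
      for (i in idx) {
        ad_tape_start()
        fw <- ddi_forward_ad(preps[[i]], params, cfg, training = TRUE)
        loss <- focal_loss_ad(fw$scores, preps[[i]]$y, alpha, cfg$gamma,
                              cfg$focal_form)
        if (!is.finite(loss$v[1L])) {
          rlang::abort(sprintf("non-finite loss at instance %d", i))
        }
        ad_backward(loss)
        ad_tape_stop()
        ep_loss <- ep_loss + loss$v[1L]
      }
      nb <- length(idx)
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / nb
      opt <- adam_step(params, opt, lr = cfg$lr,
                       weight_decay = cfg$weight_decay,
                       skip_decay = skip_decay)
    }
    probs <- ddi_predict_probs(preps, params, cfg)
    pred <- classes[max.col(probs, ties.method = "first")]
    gold <- classes[vapply(preps, function(p) p$y, 1L)]
    ev <- suppressWarnings(
      ddi_evaluate(gold, pred, classes = cfg$eval_classes))
    log[[ep]] <- tibble::tibble(
      epoch = ep, loss = ep_loss / n,
      micro_f1 = ev$micro[["f1"]], macro_f1 = ev$macro[["f1"]]
    )
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, micro-F1 %.3f", ep,
                      ep_loss / n, ev$micro[["f1"]]))
    }
    if (!is.null(stop_train_f1) && ev$micro[["f1"]] >= stop_train_f1) {
      log <- log[seq_len(ep)]
      break
    }
  }
  structure(
    list(params = params, cfg = cfg, vocab = vocab, kg = kg, alpha = alpha,
         classes = classes, log = dplyr::bind_rows(log)),
    class = "ddi_fit"
  )
}

#' @export
print.ddi_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "<ddi_fit> %d epochs trained; final train loss %.4f, micro-F1 %.3f\n",
    nrow(x$log), last$loss, last$micro_f1))
  invisible(x)
}

#' Predict DDI classes for candidate instances
#'
#' Deterministic (dropout disabled). Instances must reference drugs present
#' in the fitted model's knowledge graph.
#'
#' @param object A `ddi_fit`.
#' @param instances Candidate tibble.
#' @param ... Unused.
#' @return Tibble with `.pred_class` and one probability column per class.
#' @export
predict.ddi_fit <- function(object, instances, ...) {
  preps <- prepare_instances(instances, object$kg, object$vocab, object$cfg)
  probs <- ddi_predict_probs(preps, object$params, object$cfg)
  colnames(probs) <- paste0(".prob_", object$classes)
  out <- tibble::as_tibble(probs)
  out$.pred_class <- object$classes[max.col(probs, ties.method = "first")]
  dplyr::relocate(out, ".pred_class")
}

#' Evaluate a fitted model on an instance set
#'
#' @param fit A `ddi_fit`.
#' @param instances Candidate tibble with gold `label`s.
#' @return A `ddi_eval` report (includes the confusion matrix).
#' @export
evaluate_run <- function(fit, instances) {
  pr <- stats::predict(fit, instances)
  scores <- as.matrix(pr[paste0(".prob_", fit$classes)])
  ddi_evaluate(instances$label, pr$.pred_class, scores,
               classes = fit$cfg$eval_classes, class_levels = fit$classes)
}

#' Training log of a fitted model
#'
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @return The per-epoch log tibble.
#' @export
tidy.ddi_fit <- function(x, ...) x$log

#' One-row summary of a fitted model
#'
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @return One-row tibble with epochs trained and final train metrics.
#' @export
glance.ddi_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log), final_loss = last$loss,
                 train_micro_f1 = last$micro_f1,
                 train_macro_f1 = last$macro_f1,
                 n_params = sum(vapply(x$params,
                                       function(p) length(p$v), 1)))
}

#' Plot the training trajectory
#'
#' @param object A `ddi_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and train micro-F1 by epoch.
#' @export
autoplot.ddi_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("loss", "micro_f1", "macro_f1"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores parameter values, the configuration, vocabulary
#' and class weights with a format version tag.
#'
#' @param fit A `ddi_fit`.
#' @param path Checkpoint file path.
#' @return `path` invisibly / the restored `ddi_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  obj <- list(version = 1L,
              values = lapply(fit$params, function(p) p$v),
              cfg = fit$cfg, vocab = fit$vocab, kg = fit$kg,
              alpha = fit$alpha, classes = fit$classes, log = fit$log)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, 1L)) rlang::abort("unknown checkpoint version")
  params <- lapply(obj$values, ad_param)
  structure(
    list(params = params, cfg = obj$cfg, vocab = obj$vocab, kg = obj$kg,
         alpha = obj$alpha, classes = obj$classes, log = obj$log),
    class = "ddi_fit"
  )
}

#' Document-level cross-validation folds
#'
#' Splits candidate instances into k folds by document (all instances of a
#' document share a fold), the splitting unit assumed for cross-validated
#' protocols.
#'
#' @param instances Candidate tibble with a `document_id` column.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment per instance row.
#' @export
cv_folds <- function(instances, k = 5L, seed = 1L) {
  docs <- unique(instances$document_id)
  set.seed(seed)
  fold_of_doc <- stats::setNames(sample(rep_len(seq_len(k), length(docs))),
                                 docs)
  unname(fold_of_doc[instances$document_id])
}
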