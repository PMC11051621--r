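# Label-specific 2-hop motif: both drugs of a pair share a neighbor of the
# given type through the given relation. The motif relations are disjoint
# from the background relations, so at noise 0 the subgraph around a pair
# identifies its label exactly.
synth_motifs <- function() {
  tibble::tibble(
    label = c("Mechanism", "Effect", "Advise", "Int"),
    relation = c("shares_metabolizing_enzyme", "perturbs_pathway",
                 "contraindicated_in", "interacts_with_target"),
    neighbor_type = c("protein", "pathway", "disease", "protein")
  )
}

synth_templates <- function() {
  list(
    Mechanism = c(
      "{D1} markedly increases the plasma concentration of {D2}.",
      "{D1} inhibits the hepatic metabolism of {D2} in most patients."
    ),
    Effect = c(
      "{D1} enhances the hypotensive effect of {D2}.",
      "Coadministration of {D1} potentiates the sedative action of {D2}."
    ),
    Advise = c(
      "{D1} should not be combined with {D2}.",
      "Caution is advised when {D1} is given together with {D2}."
    ),
    Int = c(
      "{D1} interacts with {D2}.",
      "An interaction between {D1} and {D2} has been reported."
    ),
    Negative = c(
      "{D1} and {D2} were each measured in plasma samples.",
      "Patients received {D1} while {D2} exposure was recorded separately."
    )
  )
}

# deterministic pronounceable surface names, pairwise distinct and never a
# substring of one another (fixed length, distinct syllable codes)
pronounceable_names <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vow, paste0))
  stopifnot(n <= length(syll)^2)
  codes <- sample.int(length(syll)^2, n) - 1L
  paste0(
    syll[codes %/% length(syll) + 1L],
    syll[codes %% length(syll) + 1L],
    sample(c("mab", "nib", "zol", "pril", "olol", "dine"), n, replace = TRUE)
  )
}

#' Configuration of the synthetic study world
#'
#' Defines the synthetic typed knowledge graph and annotated corpus used to
#' exercise every pipeline stage without downloads: entity counts, class
#' mix, where the label signal lives (`text_only`, `graph_only`, `both`),
#' the motif-planting rate and a label-noise rate.
#'
#' @param n_instances Number of candidate pairs / sentences (default 500).
#' @param n_drugs,n_proteins,n_pathways,n_diseases Entity counts.
#' @param class_probs Named class proportions in [ddi_classes()] order.
#' @param placement Which channel carries the label signal.
#' @param motif_rate Probability that a pair's motif is actually planted
#'   (default 1).
#' @param noise Probability that a planted motif relation (and, for text
#'   placements, the sentence template) is drawn from the wrong label.
#' @param n_background_edges Count of label-uninformative background edges.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_instances = 500L, n_drugs = 40L, n_proteins = 25L,
                         n_pathways = 15L, n_diseases = 12L,
                         class_probs = c(Negative = 0.4, Mechanism = 0.15,
                                         Effect = 0.15, Advise = 0.15,
                                         Int = 0.15),
                         placement = c("both", "text_only", "graph_only"),
                         motif_rate = 1, noise = 0,
                         n_background_edges = 120L, seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(all(names(class_probs) == ddi_classes()),
            abs(sum(class_probs) - 1) < 1e-8,
            motif_rate >= 0, motif_rate <= 1, noise >= 0, noise <= 1,
            n_instances >= 1L)
  if (choose(n_drugs, 2L) < n_instances) {
    rlang::abort("not enough drugs for the requested number of distinct pairs")
  }
  if (n_background_edges < n_drugs) {
    rlang::abort("n_background_edges must be at least n_drugs (every drug must be a graph node)")
  }
  structure(
    list(n_instances = as.integer(n_instances), n_drugs = as.integer(n_drugs),
         n_proteins = as.integer(n_proteins),
         n_pathways = as.integer(n_pathways),
         n_diseases = as.integer(n_diseases),
         class_probs = class_probs, placement = placement,
         motif_rate = motif_rate, noise = noise,
         n_background_edges = as.integer(n_background_edges),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic typed knowledge graph with planted label motifs
#'
#' Samples distinct drug pairs with labels from the configured class mix,
#' plants the label-specific shared-neighbor motif for each pair (subject
#' to `motif_rate` and `noise`, and only when the placement involves the
#' graph -- under `text_only` the motif label is drawn independently of the
#' gold label so the graph is label-uninformative), and adds random
#' background edges.
#'
#' @param cfg A [synth_config()].
#' @return List with `kg` (a `ddi_kg`), `pairs` (tibble: `instance`, `db1`,
#'   `db2`, `drug1_name`, `drug2_name`, `label`, `motif_label`,
#'   `motif_planted`), and `mapping` (tibble `name`, `drugbank_id`).
#' @export
generate_synthetic_kg <- function(cfg) {
  set.seed(cfg$seed)
  classes <- ddi_classes()
  motifs <- synth_motifs()
  need_type <- c(protein = cfg$n_proteins, pathway = cfg$n_pathways,
                 disease = cfg$n_diseases)
  for (i in seq_len(nrow(motifs))) {
    if (need_type[[motifs$neighbor_type[i]]] < 1L) {
      rlang::abort(sprintf(
        "motif for %s impossible: no %s entities configured",
        motifs$label[i], motifs$neighbor_type[i]))
    }
  }

  names_ <- pronounceable_names(cfg$n_drugs)
  dbids <- sprintf("SYND%04d", seq_len(cfg$n_drugs))
  proteins <- sprintf("SYNP%04d", seq_len(cfg$n_proteins))
  pathways <- sprintf("SYNW%04d", seq_len(cfg$n_pathways))
  diseases <- sprintf("SYNC%04d", seq_len(cfg$n_diseases))

  # distinct unordered drug pairs
  pair_codes <- sample.int(choose(cfg$n_drugs, 2L), cfg$n_instances)
  all_pairs <- utils::combn(cfg$n_drugs, 2L)
  ii <- all_pairs[1L, pair_codes]
  jj <- all_pairs[2L, pair_codes]
  labels <- sample(classes, cfg$n_instances, replace = TRUE,
                   prob = cfg$class_probs)
  motif_label <- if (cfg$placement == "text_only") {
    sample(classes, cfg$n_instances, replace = TRUE, prob = cfg$class_probs)
  } else {
    labels
  }
  planted <- stats::runif(cfg$n_instances) < cfg$motif_rate &
    motif_label != "Negative"

  edges <- list()
  nx <- 0L
  add_edge <- function(h, ht, r, t, tt) {
    nx <<- nx + 1L
    edges[[nx]] <<- c(h, ht, r, t, tt)
  }
  for (q in seq_len(cfg$n_instances)) {
    if (!planted[q]) next
    ml <- motif_label[q]
    if (stats::runif(1L) < cfg$noise) {
      ml <- sample(setdiff(motifs$label, ml), 1L)
    }
    mrow <- motifs[motifs$label == ml, ]
    w <- switch(mrow$neighbor_type,
                protein = sample(proteins, 1L),
                pathway = sample(pathways, 1L),
                disease = sample(diseases, 1L))
    add_edge(dbids[ii[q]], "drug", mrow$relation, w, mrow$neighbor_type)
    add_edge(dbids[jj[q]], "drug", mrow$relation, w, mrow$neighbor_type)
  }

  # background edges with label-uninformative relations: within the
  # configured budget, first one "targets" edge per drug (so every drug is
  # a graph node), then random unique edges up to the configured count
  bg <- paste(dbids[seq_len(min(cfg$n_drugs, cfg$n_background_edges))],
              "drug", "targets",
              sample(proteins, min(cfg$n_drugs, cfg$n_background_edges),
                     replace = TRUE),
              "protein", sep = "\t")
  guard <- 0L
  while (length(bg) < cfg$n_background_edges && guard < 100L) {
    guard <- guard + 1L
    need <- cfg$n_background_edges - length(bg)
    kind <- sample(3L, need, replace = TRUE)
    cand <- vapply(kind, function(kd) {
      switch(kd,
        paste(sample(dbids, 1L), "drug", "targets",
              sample(proteins, 1L), "protein", sep = "\t"),
        paste(sample(proteins, 1L), "protein", "participates_in",
              sample(pathways, 1L), "pathway", sep = "\t"),
        paste(sample(dbids, 1L), "drug", "associated_with",
              sample(diseases, 1L), "disease", sep = "\t"))
    }, character(1L))
    bg <- unique(c(bg, cand))
  }
  for (ln in bg) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    add_edge(f[1L], f[2L], f[3L], f[4L], f[5L])
  }

  em <- do.call(rbind, edges)
  edge_df <- tibble::tibble(head = em[, 1L], head_type = em[, 2L],
                            relation = em[, 3L], tail = em[, 4L],
                            tail_type = em[, 5L])
  kg <- load_kg(edge_df, quiet = TRUE)

  pairs <- tibble::tibble(
    instance = seq_len(cfg$n_instances),
    db1 = dbids[ii], db2 = dbids[jj],
    drug1_name = names_[ii], drug2_name = names_[jj],
    label = labels, motif_label = motif_label, motif_planted = planted
  )
  mapping <- tibble::tibble(name = names_, drugbank_id = dbids)
  list(kg = kg, pairs = pairs, mapping = mapping)
}

#' Render a synthetic annotated corpus for planted drug pairs
#'
#' Instantiates one sentence per pair from the label's template bank (for
#' `graph_only` placement the template label is drawn independently of the
#' gold label, so trigger phrases carry no signal; label `noise` swaps the
#' template label), writes the corpus in the SemEval XML dialect plus the
#' name-to-identifier mapping table, and returns the parsed sentences.
#'
#' @param cfg A [synth_config()].
#' @param world Output of [generate_synthetic_kg()].
#' @param dir Output directory (created if needed); `NULL` keeps everything
#'   in memory.
#' @return List with `sentences` (as from [parse_semeval()]), `xml_path`,
#'   `mapping_path` (both `NULL` when `dir` is).
#' @export
generate_synthetic_corpus <- function(cfg, world, dir = NULL) {
  set.seed(cfg$seed + 1000L)
  classes <- ddi_classes()
  templates <- synth_templates()
  pairs <- world$pairs

  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(q) {
    gold <- pairs$label[q]
    tlabel <- if (cfg$placement == "graph_only") {
      sample(classes, 1L)
    } else if (stats::runif(1L) < cfg$noise) {
      sample(setdiff(classes, gold), 1L)
    } else {
      gold
    }
    tmpl <- sample(templates[[tlabel]], 1L)
    n1 <- pairs$drug1_name[q]
    n2 <- pairs$drug2_name[q]
    p1 <- as.integer(regexpr("{D1}", tmpl, fixed = TRUE)) - 1L
    text1 <- sub("{D1}", n1, tmpl, fixed = TRUE)
    p2 <- as.integer(regexpr("{D2}", text1, fixed = TRUE)) - 1L
    text <- sub("{D2}", n2, text1, fixed = TRUE)
    sid <- sprintf("DDISYN.d%d.s%d", (q - 1L) %/% 25L, q - 1L)
    ents <- tibble::tibble(
      id = paste0(sid, ".e", 0:1),
      text = c(n1, n2),
      start = c(p1, p2),
      end = c(p1 + nchar(n1), p2 + nchar(n2)),
      type = "drug"
    )
    prs <- tibble::tibble(e1 = ents$id[1L], e2 = ents$id[2L], label = gold)
    tibble::tibble(document_id = sprintf("DDISYN.d%d", (q - 1L) %/% 25L),
                   sentence_id = sid, text = text,
                   entities = list(ents), pairs = list(prs))
  })
  class(rows) <- c("ddi_sentences", class(rows))

  xml_path <- mapping_path <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    xml_path <- file.path(dir, "synthetic_corpus.xml")
    mapping_path <- file.path(dir, "synthetic_mapping.tsv")
    write_semeval(rows, xml_path)
    utils::write.table(world$mapping, mapping_path, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  list(sentences = rows, xml_path = xml_path, mapping_path = mapping_path)
}
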