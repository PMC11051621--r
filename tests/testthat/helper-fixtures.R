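# Fixtures built in code: small corpora and graphs used across test files.

# one-sentence tibble in the shape parse_semeval() returns
make_sentence <- function(text, entity_names, labels = NULL, sid = "d0.s0",
                          did = "d0") {
  ents <- purrr::map_dfr(seq_along(entity_names), function(i) {
    nm <- entity_names[i]
    # locate the i-th non-overlapping occurrence among duplicated names
    occ <- gregexpr(nm, text, fixed = TRUE)[[1L]]
    prev <- sum(entity_names[seq_len(i - 1L)] == nm)
    start <- occ[prev + 1L] - 1L
    tibble::tibble(id = sprintf("%s.e%d", sid, i - 1L), text = nm,
                   start = start, end = start + nchar(nm), type = "drug")
  })
  prs <- if (is.null(labels)) {
    tibble::tibble(e1 = character(), e2 = character(), label = character())
  } else {
    labels
  }
  out <- tibble::tibble(document_id = did, sentence_id = sid, text = text,
                        entities = list(ents), pairs = list(prs))
  class(out) <- c("ddi_sentences", class(out))
  out
}

# the worked preprocessing example: three drug mentions, one Advise pair
worked_example_sentence <- function() {
  text <- paste0("If in certain cases, an antidepressant is considered ",
                 "necessary, it may be advisable to replace tamoxifen ",
                 "with anastrozole.")
  make_sentence(text, c("antidepressant", "tamoxifen", "anastrozole"),
                labels = tibble::tibble(e1 = "d0.s0.e0", e2 = "d0.s0.e1",
                                        label = "Advise"))
}

# the three filtering-rule example sentences
rule_example_sentences <- function() {
  s1 <- make_sentence(
    paste0("Repeated oral administration of coumaphos in sheep: ",
           "interactions of coumaphos with bishydroxycoumarin, ",
           "trichlorfon, and phenobarbital sodium."),
    c("coumaphos", "coumaphos", "bishydroxycoumarin", "trichlorfon",
      "phenobarbital"),
    sid = "r1.s0", did = "r1")
  s2 <- make_sentence(
    paste0("Other strong inhibitors of CYP3A4 (e.g., itraconazole, ",
           "clarithromycin, nefazodone, troleandomycin, ritonavir, ",
           "nelfinavir) would be expected to behave similarly."),
    c("itraconazole", "clarithromycin", "nefazodone", "troleandomycin",
      "ritonavir", "nelfinavir"),
    sid = "r2.s0", did = "r2")
  s3 <- make_sentence(
    paste0("The concurrent use of tetracycline and penthrane ",
           "(methoxyflurane) has been reported to result in fatal ",
           "renal toxicity."),
    c("tetracycline", "penthrane", "methoxyflurane"),
    sid = "r3.s0", did = "r3")
  dplyr::bind_rows(s1, s2, s3)
}

# tiny path graph DB1 - P1 - DB2 as a typed edge tibble
path_kg_table <- function() {
  tibble::tibble(
    head = c("DB1", "P1"),
    head_type = c("drug", "protein"),
    relation = c("targets", "targets"),
    tail = c("P1", "DB2"),
    tail_type = c("protein", "drug")
  )
}

# a labeled subgraph with hand-set scalar (1-D) states for algebra tests
scalar_subgraph <- function() {
  sub <- list(
    pair = c(u = "A", v = "B"),
    k = 1L,
    members = tibble::tibble(id = c("A", "B"), dist_u = c(0, 1),
                             dist_v = c(1, 0), node_idx = 1:2),
    edges = tibble::tibble(head = "A", relation = "r", tail = "B",
                           head_idx = 1L, rel_idx = 1L, tail_idx = 2L,
                           src = 1L, dst = 2L)
  )
  class(sub) <- "ddi_subgraph"
  sub$init_states <- matrix(1, 2L, 1L)
  sub
}

# hand-built parameter list for 1-D attention with W_I = W_J = r = 1
scalar_attention_params <- function(value = 1) {
  list(
    rel_emb = ddiextract:::ad_param(matrix(value, 2L, 1L)),
    W_I = ddiextract:::ad_param(matrix(value, 1L, 1L)),
    W_J = ddiextract:::ad_param(matrix(value, 1L, 1L))
  )
}

# a small synthetic training world shared by pipeline tests
small_world <- function(n = 60L, placement = "both", seed = 21L, noise = 0) {
  scfg <- synth_config(n_instances = n, placement = placement, noise = noise,
                       seed = seed)
  world <- generate_synthetic_kg(scfg)
  corp <- generate_synthetic_corpus(scfg, world, dir = NULL)
  inst <- map_to_drugbank(generate_candidates(corp$sentences), world$mapping)
  list(cfg = scfg, kg = world$kg, instances = inst)
}

# desk-scale model configuration used for synthetic training tests;
# any default can be overridden through ...
small_model_config <- function(...) {
  args <- list(max_length = 40L, d_p = 6L, d_w = 32L, graph_dim = 16L,
               hop = 2L, layers = 2L, hidden_dim = 16L, num_bases = 4L,
               channels = 24L, lr = 5e-3, batch_size = 32L, seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(ddi_config, args)
}
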