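#' Build a word-piece vocabulary from anonymized sentences
#'
#' The vocabulary contains every lowercased whole word seen in the texts,
#' every single character (plus its `##`-prefixed continuation form) as a
#' segmentation fallback, the atomic placeholders `DRUG1`/`DRUG2`, and
#' `[UNK]`.
#'
#' @param texts Character vector of (anonymized) sentences.
#' @return Character vector of vocabulary entries.
#' @export
build_vocab <- function(texts) {
  words <- unlist(lapply(texts, pretokenize_words))
  words <- setdiff(tolower(unique(words)), c("drug1", "drug2"))
  chars <- unique(unlist(strsplit(paste(tolower(texts), collapse = ""), "")))
  chars <- setdiff(chars, " ")
  unique(c("[UNK]", "DRUG1", "DRUG2", words, chars, paste0("##", chars)))
}

# whitespace split, punctuation broken out as separate word units
pretokenize_words <- function(text) {
  toks <- unlist(strsplit(text, "\\s+"))
  toks <- unlist(lapply(toks, function(w) {
    pieces <- unlist(strsplit(w, "(?=[[:punct:]])|(?<=[[:punct:]])",
                              perl = TRUE))
    pieces[nzchar(pieces)]
  }))
  toks[nzchar(toks)]
}

# greedy longest-match word-piece segmentation of one word
wordpiece_word <- function(word, vocab_set) {
  if (word %in% c("DRUG1", "DRUG2")) return(word)
  w <- tolower(word)
  pieces <- character()
  pos <- 1L
  n <- nchar(w)
  first <- TRUE
  while (pos <= n) {
    found <- NA_character_
    for (len in seq.int(n - pos + 1L, 1L)) {
      cand <- substr(w, pos, pos + len - 1L)
      key <- if (first) cand else paste0("##", cand)
      if (key %in% vocab_set) {
        found <- key
        pos <- pos + len
        break
      }
    }
    if (is.na(found)) return("[UNK]")
    pieces <- c(pieces, found)
    first <- FALSE
  }
  pieces
}

#' Word-piece tokenization of an anonymized candidate sentence
#'
#' Greedy longest-match segmentation against a vocabulary, with
#' `DRUG1`/`DRUG2` kept atomic. Sequences longer than `max_length` are
#' truncated token by token from whichever end lies farther from both drug
#' placeholders; truncating a drug token away is an error.
#'
#' @param text Anonymized sentence containing `DRUG1` and `DRUG2` exactly
#'   once each.
#' @param vocab Character vocabulary (see [build_vocab()]).
#' @param max_length Maximum token count (default 390).
#' @return A `ddi_tokens` list: `tokens`, `ids` (indices into `vocab`),
#'   `drug1`/`drug2` (token index ranges as `c(start, end)`), `vocab`.
#' @export
tokenize <- function(text, vocab, max_length = 390L) {
  if (stringr::str_count(text, stringr::fixed("DRUG1")) != 1L ||
      stringr::str_count(text, stringr::fixed("DRUG2")) != 1L) {
    rlang::abort("anonymized text must contain DRUG1 and DRUG2 exactly once")
  }
  vocab_set <- vocab
  words <- pretokenize_words(text)
  tokens <- unlist(lapply(words, wordpiece_word, vocab_set = vocab_set))
  d1 <- which(tokens == "DRUG1")
  d2 <- which(tokens == "DRUG2")

  while (length(tokens) > max_length) {
    n <- length(tokens)
    near <- range(c(d1, d2))
    dist_front <- near[1L] - 1L
    dist_back <- n - near[2L]
    if (dist_front == 0L && dist_back == 0L) {
      rlang::abort("cannot truncate without removing a drug mention")
    }
    if (dist_back >= dist_front) {
      tokens <- tokens[-n]
    } else {
      tokens <- tokens[-1L]
      d1 <- d1 - 1L
      d2 <- d2 - 1L
    }
  }
  structure(
    list(tokens = tokens,
         ids = match(tokens, vocab),
         drug1 = c(d1, d1), drug2 = c(d2, d2),
         vocab = vocab),
    class = "ddi_tokens"
  )
}

#' Signed drug-relative token offsets
#'
#' For each token, the signed distance (in token units) to the nearest
#' token of each drug placeholder's span: 0 inside the span, negative
#' before it, positive after it, clamped to `± max_length`.
#'
#' @param n Number of tokens.
#' @param span Integer `c(start, end)` token range of the drug.
#' @param max_length Clamp bound.
#' @return Integer vector of length `n`.
#' @export
relative_offsets <- function(n, span, max_length = 390L) {
  i <- seq_len(n)
  off <- ifelse(i < span[1L], i - span[1L],
                ifelse(i > span[2L], i - span[2L], 0L))
  pmax(pmin(off, max_length), -max_length)
}

#' Initialize the two position-embedding lookup tables
#'
#' Learned tables of size `(2 * max_length + 1) x d_p`, one per drug
#' channel; row `offset + max_length + 1` holds the embedding of a signed
#' offset.
#'
#' @param d_p Position embedding width (default 10).
#' @param max_length Maximum sequence length (default 390).
#' @param seed Integer seed.
#' @return List with matrices `table1`, `table2`.
#' @export
position_tables <- function(d_p = 10L, max_length = 390L, seed = 1L) {
  set.seed(seed)
  rows <- 2L * max_length + 1L
  list(table1 = xavier_uniform(rows, d_p),
       table2 = xavier_uniform(rows, d_p))
}

#' Drug-relative position embeddings for a token sequence
#'
#' Each token's row is the concatenation of its offset embedding with
#' respect to DRUG1 and to DRUG2.
#'
#' @param toks A `ddi_tokens` object.
#' @param tables List from [position_tables()].
#' @param max_length Clamp bound used for the offsets.
#' @return Numeric matrix `n x (2 * d_p)`.
#' @export
position_embeddings <- function(toks, tables, max_length = 390L) {
  n <- length(toks$tokens)
  o1 <- relative_offsets(n, toks$drug1, max_length)
  o2 <- relative_offsets(n, toks$drug2, max_length)
  cbind(tables$table1[o1 + max_length + 1L, , drop = FALSE],
        tables$table2[o2 + max_length + 1L, , drop = FALSE])
}

#' Initialize the tiny trainable text encoder
#'
#' A one-layer self-attention + feed-forward block over learned token and
#' token-position embeddings: small enough to train at desk scale, yet
#' context-sensitive (the attention mixing layer makes the output of a
#' token depend on the other tokens). A pretrained biomedical transformer
#' can be plugged in through the same contract (a function mapping token
#' ids to an `n x d_w` matrix); see [encoder_adapter()].
#'
#' @param vocab_size Vocabulary size.
#' @param d_w Embedding width (default 32).
#' @param max_length Maximum sequence length for the learned token-position
#'   table.
#' @param seed Integer seed.
#' @return Named list of `ad_param` objects.
#' @export
tiny_encoder_params <- function(vocab_size, d_w = 32L, max_length = 390L,
                                seed = 1L) {
  set.seed(seed)
  list(
    tok_emb = ad_param(xavier_uniform(vocab_size, d_w)),
    seq_pos_emb = ad_param(xavier_uniform(max_length, d_w)),
    W_q = ad_param(xavier_uniform(d_w, d_w)),
    W_k = ad_param(xavier_uniform(d_w, d_w)),
    W_v = ad_param(xavier_uniform(d_w, d_w)),
    W_ff = ad_param(xavier_uniform(d_w, d_w)),
    b_ff = ad_param(matrix(0, 1L, d_w))
  )
}

# AD forward of the tiny encoder: ids -> n x d_w contextual embeddings
tiny_encoder_ad <- function(ids, params) {
  n <- length(ids)
  if (n == 0L) rlang::abort("cannot encode an empty token sequence")
  d_w <- ncol(params$tok_emb$v)
  x <- ad_add(ad_rows(params$tok_emb, ids),
              ad_rows(params$seq_pos_emb, seq_len(n)))
  q <- ad_mm(x, params$W_q)
  k <- ad_mm(x, params$W_k)
  v <- ad_mm(x, params$W_v)
  a <- ad_softmax_rows(ad_scale(ad_mm_t(q, k), 1 / sqrt(d_w)))
  h <- ad_add(x, ad_mm(a, v))
  ad_gelu(ad_add_rowvec(ad_mm(h, params$W_ff), params$b_ff))
}

#' Encode a token sequence into contextual embeddings
#'
#' @param toks A `ddi_tokens` object.
#' @param encoder Either a parameter list from [tiny_encoder_params()] or a
#'   function `ids -> matrix` satisfying the encoder contract.
#' @return Numeric matrix `n x d_w`.
#' @export
encode <- function(toks, encoder) {
  if (is.function(encoder)) {
    m <- encoder(toks$ids)
    stopifnot(is.matrix(m), nrow(m) == length(toks$ids))
    return(m)
  }
  tiny_encoder_ad(toks$ids, encoder)$v
}

#' Adapter contract for a pretrained contextual encoder
#'
#' Wraps an externally computed embedding lookup (for example a pretrained
#' biomedical transformer exported as per-token vectors, typically
#' `d_w = 768`) as an encoder function usable wherever the tiny trainable
#' encoder is. The adapter is frozen: it carries no trainable parameters.
#'
#' @param embed_fn Function taking a vector of token ids and returning an
#'   `n x d_w` numeric matrix.
#' @param d_w Declared embedding width.
#' @return A function with class `ddi_encoder_adapter`.
#' @export
encoder_adapter <- function(embed_fn, d_w = 768L) {
  structure(function(ids) {
    m <- embed_fn(ids)
    if (ncol(m) != d_w) rlang::abort("adapter returned wrong embedding width")
    m
  }, class = c("ddi_encoder_adapter", "function"), d_w = d_w)
}
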