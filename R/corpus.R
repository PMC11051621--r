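#' DDI class labels, in their fixed order
#'
#' The class order used everywhere in the package: Negative first, then the
#' four positive interaction types.
#' @export
ddi_classes <- function() c("Negative", "Mechanism", "Effect", "Advise", "Int")

normalize_name <- function(x) {
  stringr::str_squish(tolower(x))
}

#' Parse a SemEval-2013 Task 9 corpus file
#'
#' Reads the DDIExtraction XML dialect: documents containing sentences,
#' each with drug-entity annotations (character offsets, 0-based inclusive
#' in the file; stored half-open 0-based internally) and labeled entity
#' pairs. Discontinuous offsets (semicolon-separated) keep their first span
#' with a warning.
#'
#' @param path Path to an XML file, or an `xml2` document.
#' @return A tibble with one row per sentence: `document_id`, `sentence_id`,
#'   `text`, and list-columns `entities` (tibble `id`, `text`, `start`,
#'   `end`, `type`) and `pairs` (tibble `e1`, `e2`, `label`).
#' @export
parse_semeval <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  docs <- xml2::xml_find_all(doc, "//document")
  out <- purrr::map_dfr(docs, function(d) {
    did <- xml2::xml_attr(d, "id")
    sents <- xml2::xml_find_all(d, "./sentence")
    purrr::map_dfr(sents, function(s) {
      sid <- xml2::xml_attr(s, "id")
      text <- xml2::xml_attr(s, "text")
      ents <- xml2::xml_find_all(s, "./entity")
      etb <- purrr::map_dfr(ents, function(e) {
        off <- xml2::xml_attr(e, "charOffset")
        if (grepl(";", off, fixed = TRUE)) {
          rlang::warn(sprintf(
            "entity %s has a discontinuous offset; keeping the first span",
            xml2::xml_attr(e, "id")))
          off <- strsplit(off, ";", fixed = TRUE)[[1L]][1L]
        }
        se <- as.integer(strsplit(off, "-", fixed = TRUE)[[1L]])
        tibble::tibble(
          id = xml2::xml_attr(e, "id"),
          text = xml2::xml_attr(e, "text"),
          start = se[1L],          # 0-based
          end = se[2L] + 1L,       # half-open
          type = xml2::xml_attr(e, "type")
        )
      })
      if (nrow(etb) > 0L) {
        if (anyDuplicated(etb$id) > 0L) {
          rlang::abort(sprintf("duplicate entity id in sentence %s", sid))
        }
        bad <- etb$end > nchar(text) | etb$start < 0L
        if (any(bad)) {
          rlang::abort(sprintf("entity %s offset outside sentence %s",
                               etb$id[which(bad)[1L]], sid))
        }
      }
      prs <- xml2::xml_find_all(s, "./pair")
      ptb <- purrr::map_dfr(prs, function(p) {
        ddi <- tolower(xml2::xml_attr(p, "ddi"))
        type <- xml2::xml_attr(p, "type")
        label <- if (identical(ddi, "true")) {
          switch(tolower(type),
                 mechanism = "Mechanism", effect = "Effect",
                 advise = "Advise", int = "Int",
                 rlang::abort(sprintf("unknown pair type '%s'", type)))
        } else {
          "Negative"
        }
        tibble::tibble(e1 = xml2::xml_attr(p, "e1"),
                       e2 = xml2::xml_attr(p, "e2"),
                       label = label)
      })
      if (nrow(ptb) > 0L) {
        unk <- setdiff(c(ptb$e1, ptb$e2), etb$id)
        if (length(unk) > 0L) {
          rlang::abort(sprintf("pair references unknown entity '%s' in %s",
                               unk[1L], sid))
        }
      }
      tibble::tibble(document_id = did, sentence_id = sid, text = text,
                     entities = list(etb), pairs = list(ptb))
    })
  })
  class(out) <- c("ddi_sentences", class(out))
  out
}

#' Serialize sentences back to SemEval XML
#'
#' Inverse of [parse_semeval()]; used for round-trip checks and by the
#' synthetic corpus generator.
#'
#' @param sentences A tibble as from [parse_semeval()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_semeval <- function(sentences, path) {
  root <- xml2::xml_new_root("corpus")
  for (did in unique(sentences$document_id)) {
    dnode <- xml2::xml_add_child(root, "document", id = did)
    rows <- sentences[sentences$document_id == did, ]
    for (i in seq_len(nrow(rows))) {
      snode <- xml2::xml_add_child(dnode, "sentence",
                                   id = rows$sentence_id[i],
                                   text = rows$text[i])
      ents <- rows$entities[[i]]
      for (j in seq_len(nrow(ents))) {
        xml2::xml_add_child(
          snode, "entity", id = ents$id[j],
          charOffset = sprintf("%d-%d", ents$start[j], ents$end[j] - 1L),
          type = ents$type[j], text = ents$text[j]
        )
      }
      prs <- rows$pairs[[i]]
      for (j in seq_len(nrow(prs))) {
        lab <- prs$label[j]
        xml2::xml_add_child(
          snode, "pair", id = sprintf("%s.p%d", rows$sentence_id[i], j - 1L),
          e1 = prs$e1[j], e2 = prs$e2[j],
          ddi = if (lab == "Negative") "false" else "true",
          type = if (lab == "Negative") NULL else tolower(lab)
        )
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

# Replace the two target mentions (given as half-open spans in the original
# text) by DRUG1 / DRUG2, in order of appearance. Returns the anonymized
# text and the spans of the placeholders in it.
anonymize_pair <- function(text, s1, e1, s2, e2) {
  stopifnot(e1 <= s2)  # caller orders mentions by position
  out <- paste0(
    substr(text, 1L, s1), "DRUG1",
    substr(text, e1 + 1L, s2), "DRUG2",
    substr(text, e2 + 1L, nchar(text))
  )
  d1s <- s1
  d1e <- s1 + 5L
  d2s <- s2 + (5L - (e1 - s1))
  d2e <- d2s + 5L
  list(text = out, d1_start = d1s, d1_end = d1e, d2_start = d2s, d2_end = d2e)
}

#' Generate candidate drug-pair instances from parsed sentences
#'
#' Every unordered pair of the n entities in a sentence yields one
#' candidate (`choose(n, 2)` per sentence), ordered by first-mention
#' position. The two target mentions are replaced by `DRUG1` and `DRUG2`
#' in order of appearance; all other drug mentions stay verbatim. Labels
#' come from the gold pair annotations, defaulting to `Negative`.
#' Overlapping target mentions keep the longer mention with a warning.
#'
#' @param sentences A tibble as from [parse_semeval()].
#' @return Tibble of candidate instances, one row per pair: sentence ids,
#'   surface names, original-text spans, anonymized `text` with placeholder
#'   spans, `label`, plus the sentence's full entity table (list-column
#'   `entities`) and original text (`text_orig`) used by the filtering
#'   rules.
#' @export
generate_candidates <- function(sentences) {
  purrr::map_dfr(seq_len(nrow(sentences)), function(i) {
    ents <- sentences$entities[[i]] |> dplyr::arrange(.data$start, .data$end)
    n <- nrow(ents)
    if (n < 2L) return(NULL)
    prs <- sentences$pairs[[i]]
    text <- sentences$text[i]
    combos <- utils::combn(n, 2L)
    purrr::map_dfr(seq_len(ncol(combos)), function(cix) {
      a <- combos[1L, cix]; b <- combos[2L, cix]
      ea <- ents[a, ]; eb <- ents[b, ]
      label <- "Negative"
      if (nrow(prs) > 0L) {
        hit <- (prs$e1 == ea$id & prs$e2 == eb$id) |
          (prs$e1 == eb$id & prs$e2 == ea$id)
        if (any(hit)) label <- prs$label[which(hit)[1L]]
      }
      s1 <- ea$start; e1 <- ea$end; s2 <- eb$start; e2 <- eb$end
      if (e1 > s2) {  # overlapping mentions: keep the longer one
        rlang::warn(sprintf(
          "overlapping mentions '%s'/'%s'; keeping the longer",
          ea$text, eb$text))
        if ((e1 - s1) >= (e2 - s2)) {
          s2 <- e1; e2 <- e1
        } else {
          s1 <- s2; e1 <- s2
        }
      }
      an <- anonymize_pair(text, s1, e1, s2, e2)
      original_text <- text
      tibble::tibble(
        document_id = sentences$document_id[i],
        sentence_id = sentences$sentence_id[i],
        e1 = ea$id, e2 = eb$id,
        drug1_name = ea$text, drug2_name = eb$text,
        e1_start = ea$start, e1_end = ea$end,
        e2_start = eb$start, e2_end = eb$end,
        text = an$text,
        d1_start = an$d1_start, d1_end = an$d1_end,
        d2_start = an$d2_start, d2_end = an$d2_end,
        label = label,
        text_orig = original_text,
        entities = list(ents)
      )
    })
  })
}

# is `short` an acronym/abbreviation of `long`? Crude initials heuristic.
is_abbreviation <- function(short, long) {
  s <- gsub("[^A-Za-z]", "", short)
  if (nchar(s) < 2L || nchar(s) > 8L || s != toupper(s)) return(FALSE)
  words <- strsplit(stringr::str_squish(long), "[ -]")[[1L]]
  if (length(words) < 2L) return(FALSE)
  initials <- toupper(paste0(substr(words, 1L, 1L), collapse = ""))
  identical(initials, s)
}

rule1_same_name <- function(inst) {
  n1 <- normalize_name(inst$drug1_name)
  n2 <- normalize_name(inst$drug2_name)
  n1 == n2 ||
    is_abbreviation(inst$drug1_name, inst$drug2_name) ||
    is_abbreviation(inst$drug2_name, inst$drug1_name)
}

# Coordinate structure: the text between the two mentions, after blanking
# out other drug mentions, contains at least one list separator and nothing
# beyond separators / connectives / parentheses.
rule2_coordinate <- function(inst) {
  gap_s <- inst$e1_end
  gap_e <- inst$e2_start
  if (gap_e < gap_s) return(FALSE)
  text <- inst$text_orig
  gap <- substr(text, gap_s + 1L, gap_e)
  ents <- inst$entities[[1L]]
  inside <- ents[ents$start >= gap_s & ents$end <= gap_e, ]
  for (j in seq_len(nrow(inside))) {
    rel_s <- inside$start[j] - gap_s
    rel_e <- inside$end[j] - gap_s
    substr(gap, rel_s + 1L, rel_e) <- strrep(" ", rel_e - rel_s)
  }
  has_sep <- grepl(",|;|\\band\\b|\\bor\\b|e\\.g\\.", gap, ignore.case = TRUE)
  only_sep <- grepl("^(\\s|,|;|\\(|\\)|and\\b|or\\b|e\\.g\\.,?|etc\\.?,?)*$",
                    gap, ignore.case = TRUE)
  has_sep && only_sep
}

# Special case/apposition: second mention parenthesized right after the
# first, or introduced by "such as" / "including" / "e.g.".
rule3_special_case <- function(inst) {
  gap_s <- inst$e1_end
  gap_e <- inst$e2_start
  if (gap_e < gap_s) return(FALSE)
  text <- inst$text_orig
  gap <- substr(text, gap_s + 1L, gap_e)
  after <- substr(text, inst$e2_end + 1L, inst$e2_end + 1L)
  paren <- grepl("^\\s*\\($", gap) && identical(after, ")")
  linked <- grepl("(such as|including|e\\.g\\.)[\\s,]*$", gap,
                  ignore.case = TRUE, perl = TRUE)
  paren || linked
}

#' Filter negative candidate instances
#'
#' Applies the three negative-filtering heuristics to `Negative`-labeled
#' instances (gold positives are never removed): Rule 1 removes pairs whose
#' mentions refer to the same drug name (or one abbreviates the other);
#' Rule 2 removes pairs sitting in one coordinate list; Rule 3 removes
#' pairs where one mention is a parenthesized or "such as"-introduced
#' special case of the other. Each rule can be toggled.
#'
#' @param instances Tibble from [generate_candidates()].
#' @param rules Named logical vector enabling `same_name`, `coordinate`,
#'   `special_case`.
#' @return The surviving instances; attribute `"removals"` holds a tibble
#'   of per-rule removal counts, and attribute `"removed"` the removed rows
#'   with a `rule` column.
#' @export
filter_negatives <- function(instances,
                             rules = c(same_name = TRUE, coordinate = TRUE,
                                       special_case = TRUE)) {
  if (nrow(instances) == 0L) {
    out <- instances
    attr(out, "removals") <- tibble::tibble(rule = character(), n = integer())
    return(out)
  }
  fired <- vapply(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, ]
    if (inst$label != "Negative") return(NA_character_)
    if (isTRUE(rules[["same_name"]]) && rule1_same_name(inst)) {
      return("same_name")
    }
    if (isTRUE(rules[["coordinate"]]) && rule2_coordinate(inst)) {
      return("coordinate")
    }
    if (isTRUE(rules[["special_case"]]) && rule3_special_case(inst)) {
      return("special_case")
    }
    NA_character_
  }, character(1L))
  keep <- is.na(fired)
  out <- instances[keep, ]
  removed <- instances[!keep, ]
  removed$rule <- fired[!keep]
  counts <- tibble::tibble(rule = c("same_name", "coordinate", "special_case"))
  counts$n <- vapply(counts$rule, function(r) sum(fired == r, na.rm = TRUE),
                     1L, USE.NAMES = FALSE)
  attr(out, "removals") <- counts
  attr(out, "removed") <- removed
  out
}

#' Map drug mentions to DrugBank identifiers
#'
#' Case-insensitive, whitespace-normalized lookup of both surface names in
#' a two-column mapping table; instances with either drug unmapped are
#' dropped and counted.
#'
#' @param instances Candidate-instance tibble.
#' @param mapping Path to a 2-column TSV (`name`, `drugbank_id`, no header)
#'   or a data frame with those two columns.
#' @return Instances with `db1`, `db2` columns; attribute `"n_unmapped"`
#'   counts dropped instances.
#' @export
map_to_drugbank <- function(instances, mapping) {
  if (is.character(mapping)) {
    mapping <- utils::read.delim(mapping, header = FALSE,
                                 col.names = c("name", "drugbank_id"),
                                 colClasses = "character")
  }
  mapping <- tibble::as_tibble(mapping)
  names(mapping)[1:2] <- c("name", "drugbank_id")
  mapping$key <- normalize_name(mapping$name)
  dup <- mapping |>
    dplyr::distinct(.data$key, .data$drugbank_id) |>
    dplyr::count(.data$key) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    rlang::abort(sprintf("conflicting DrugBank ids for name '%s'",
                         dup$key[1L]))
  }
  mapping <- dplyr::distinct(mapping, .data$key, .data$drugbank_id)
  lut <- stats::setNames(mapping$drugbank_id, mapping$key)
  db1 <- unname(lut[normalize_name(instances$drug1_name)])
  db2 <- unname(lut[normalize_name(instances$drug2_name)])
  keep <- !is.na(db1) & !is.na(db2)
  out <- instances[keep, ]
  out$db1 <- db1[keep]
  out$db2 <- db2[keep]
  attr(out, "n_unmapped") <- sum(!keep)
  out
}
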