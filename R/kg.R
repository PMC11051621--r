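#' Load a typed knowledge-graph edge list
#'
#' Reads a 5-column edge table (`head`, `head_type`, `relation`, `tail`,
#' `tail_type`) describing a typed biomedical knowledge graph of drugs,
#' proteins, pathways, diseases and the relations between them. Rows are
#' deduplicated, nodes are ordered lexicographically by identifier, and the
#' relation vocabulary is the sorted set of distinct relation labels.
#'
#' @param x Path to a tab-separated file (lines starting with `#` are
#'   ignored, no header) or a data frame with five columns in the order
#'   above.
#' @param quiet Suppress the node/edge/relation count message.
#'
#' @return A `ddi_kg` object: a list with
#'   \describe{
#'     \item{nodes}{tibble with `id`, `type`, and a contiguous `index`.}
#'     \item{edges}{tibble with `head`, `relation`, `tail` plus integer
#'       `head_idx`, `rel_idx`, `tail_idx`.}
#'     \item{relations}{character vector, the ordered relation vocabulary.}
#'   }
#' @export
load_kg <- function(x, quiet = FALSE) {
  if (is.character(x)) {
    lines <- readLines(x, encoding = "UTF-8")
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 5L)
    if (length(bad) > 0L) {
      rlang::abort(sprintf(
        "malformed edge row %d: expected 5 tab-separated fields, got %d",
        bad[1L], lengths(parts)[bad[1L]]
      ))
    }
    m <- do.call(rbind, parts)
    df <- tibble::tibble(
      head = m[, 1L], head_type = m[, 2L], relation = m[, 3L],
      tail = m[, 4L], tail_type = m[, 5L]
    )
  } else {
    df <- tibble::as_tibble(x)
    if (ncol(df) != 5L) {
      rlang::abort("edge table must have exactly 5 columns")
    }
    names(df) <- c("head", "head_type", "relation", "tail", "tail_type")
    df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
  }

  empt <- !stats::complete.cases(df) | df$head == "" | df$tail == "" |
    df$relation == ""
  if (any(empt)) {
    rlang::abort(sprintf("malformed edge row %d: empty identifier",
                         which(empt)[1L]))
  }
  df <- dplyr::distinct(df)

  nodes <- dplyr::bind_rows(
    tibble::tibble(id = df$head, type = df$head_type),
    tibble::tibble(id = df$tail, type = df$tail_type)
  ) |> dplyr::distinct()
  conflict <- nodes |> dplyr::count(.data$id) |> dplyr::filter(.data$n > 1L)
  if (nrow(conflict) > 0L) {
    rlang::abort(sprintf("node '%s' is declared with conflicting types",
                         conflict$id[1L]))
  }
  nodes <- nodes |>
    dplyr::arrange(.data$id) |>
    dplyr::mutate(index = dplyr::row_number())

  relations <- sort(unique(df$relation))
  idx <- stats::setNames(nodes$index, nodes$id)
  edges <- df |>
    dplyr::select("head", "relation", "tail") |>
    dplyr::mutate(
      head_idx = unname(idx[.data$head]),
      rel_idx = match(.data$relation, relations),
      tail_idx = unname(idx[.data$tail])
    )

  kg <- structure(
    list(nodes = nodes, edges = edges, relations = relations),
    class = "ddi_kg"
  )
  if (!quiet) {
    message(sprintf("knowledge graph: %d nodes, %d edges, %d relations",
                    nrow(nodes), nrow(edges), length(relations)))
  }
  kg
}

#' @export
print.ddi_kg <- function(x, ...) {
  cat(sprintf("<ddi_kg> %d nodes, %d edges, %d relations\n",
              nrow(x$nodes), nrow(x$edges), length(x$relations)))
  invisible(x)
}

kg_igraph <- function(kg) {
  igraph::graph_from_data_frame(
    data.frame(from = kg$edges$head, to = kg$edges$tail),
    directed = FALSE,
    vertices = data.frame(name = kg$nodes$id)
  )
}

#' Extract the k-hop enclosing subgraph of a drug pair
#'
#' The enclosing subgraph of a pair (u, v) is the subgraph induced on the
#' intersection of the k-hop neighborhoods of u and of v (distances taken
#' on the undirected view of the graph), with u and v always retained even
#' when the intersection rule alone would drop them. Each member node
#' carries its double-radius label: the pair of shortest-path distances to
#' u and to v.
#'
#' @param kg A `ddi_kg`.
#' @param u,v Node identifiers of the two drugs (must differ).
#' @param k Hop count (>= 1).
#'
#' @return A `ddi_subgraph`: list with `pair`, `k`, `members` (tibble of
#'   `id`, `dist_u`, `dist_v`, `node_idx` into the parent graph; distances
#'   are `NA` when a retained endpoint is unreachable), and `edges` (the
#'   induced edge tibble with local `src`/`dst` row indices into `members`).
#'   Members are ordered by (dist_u, dist_v, id) for reproducibility.
#' @export
extract_enclosing_subgraph <- function(kg, u, v, k) {
  stopifnot(inherits(kg, "ddi_kg"), k >= 1)
  if (identical(u, v)) rlang::abort("degenerate pair: u and v are identical")
  for (d in c(u, v)) {
    if (!d %in% kg$nodes$id) {
      rlang::abort(sprintf("drug '%s' is not a node of the knowledge graph", d))
    }
  }
  g <- kg_igraph(kg)
  dmat <- igraph::distances(g, v = c(u, v), mode = "all")
  du <- dmat[1L, kg$nodes$id]
  dv <- dmat[2L, kg$nodes$id]

  keep <- (du <= k & dv <= k) | kg$nodes$id %in% c(u, v)
  members <- kg$nodes[keep, ] |>
    dplyr::transmute(
      id = .data$id,
      dist_u = unname(ifelse(is.finite(du[keep]), du[keep], NA_real_)),
      dist_v = unname(ifelse(is.finite(dv[keep]), dv[keep], NA_real_)),
      node_idx = .data$index
    ) |>
    dplyr::arrange(.data$dist_u, .data$dist_v, .data$id)

  local <- stats::setNames(seq_len(nrow(members)), members$id)
  edges <- kg$edges |>
    dplyr::filter(.data$head %in% members$id, .data$tail %in% members$id) |>
    dplyr::mutate(
      src = unname(local[.data$head]),
      dst = unname(local[.data$tail])
    )

  structure(
    list(pair = c(u = u, v = v), k = as.integer(k),
         members = members, edges = edges),
    class = "ddi_subgraph"
  )
}

#' @export
print.ddi_subgraph <- function(x, ...) {
  cat(sprintf("<ddi_subgraph> pair (%s, %s), k = %d: %d nodes, %d edges\n",
              x$pair[["u"]], x$pair[["v"]], x$k,
              nrow(x$members), nrow(x$edges)))
  invisible(x)
}

#' Double-radius one-hot labels for subgraph members
#'
#' Each member's distances to the two target drugs are clamped to `[0, k]`
#' (an unreachable retained endpoint falls into bucket `k`) and one-hot
#' encoded, giving a label of length `2 * (k + 1)` independent of graph
#' size.
#'
#' @param sub A `ddi_subgraph`.
#' @return Numeric matrix, one row per member.
#' @export
distance_labels <- function(sub) {
  k <- sub$k
  enc <- function(d) {
    d <- ifelse(is.na(d), k, pmin(d, k))
    m <- matrix(0, length(d), k + 1L)
    m[cbind(seq_along(d), d + 1L)] <- 1
    m
  }
  cbind(enc(sub$members$dist_u), enc(sub$members$dist_v))
}

#' Attach initial node states to an enclosing subgraph
#'
#' The initial state of member i is the concatenation of its node embedding
#' (length `graph_dim`) with its double-radius one-hot label (length
#' `2 * (k + 1)`).
#'
#' @param sub A `ddi_subgraph`.
#' @param node_embeddings Numeric matrix with one row per knowledge-graph
#'   node and rownames equal to node identifiers, or a named list of
#'   vectors.
#' @return `sub` with elements `labels` (matrix) and `init_states` (matrix
#'   of width `graph_dim + 2 * (k + 1)`).
#' @export
label_nodes <- function(sub, node_embeddings) {
  if (is.list(node_embeddings)) {
    node_embeddings <- do.call(rbind, node_embeddings)
  }
  miss <- setdiff(sub$members$id, rownames(node_embeddings))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("no embedding for subgraph node '%s'", miss[1L]))
  }
  emb <- node_embeddings[sub$members$id, , drop = FALSE]
  widths <- ncol(emb)
  if (is.null(widths) || widths < 1L) {
    rlang::abort("node embeddings must have at least one column")
  }
  sub$labels <- distance_labels(sub)
  sub$init_states <- cbind(emb, sub$labels)
  sub
}

#' Xavier-uniform node embeddings for a knowledge graph
#'
#' Initializes one embedding row per node with the xavier-uniform scheme
#' (gain 2) under a fixed seed, the initialization used for drug node
#' embeddings throughout the package.
#'
#' @param kg A `ddi_kg`.
#' @param graph_dim Embedding width (default 75).
#' @param seed Integer seed.
#' @param gain Xavier gain (default 2).
#' @return Matrix with rownames = node ids.
#' @export
init_node_embeddings <- function(kg, graph_dim = 75, seed = 1L, gain = 2) {
  set.seed(seed)
  m <- xavier_uniform(nrow(kg$nodes), graph_dim, gain = gain)
  rownames(m) <- kg$nodes$id
  m
}
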