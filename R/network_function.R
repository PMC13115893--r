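# Downstream gene-level analysis: CpG-to-gene mapping, effector-status
# classification, hypergeometric over-representation with FDR control, and
# composite degree/betweenness hub scoring of an interaction network.

#' Construct an interaction network from an edge table
#'
#' @param edges data.frame with columns `node_a`, `node_b`,
#'   `combined_score` (integer, STRING convention 0-1000); undirected, no
#'   self-loops.
#' @param nodes Optional character vector of node ids (defaults to the
#'   union of edge endpoints; extra entries are kept as isolated nodes).
#' @return An object of class `interaction_network`.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  need <- c("node_a", "node_b", "combined_score")
  if (!all(need %in% names(edges))) {
    stop_oam("'edges' must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(edges) > 0 && any(edges$node_a == edges$node_b)) {
    stop_oam("self-loops are not allowed")
  }
  endpoints <- unique(c(edges$node_a, edges$node_b))
  nodes <- if (is.null(nodes)) sort(endpoints) else sort(unique(c(nodes, endpoints)))
  structure(list(edges = edges, nodes = nodes), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Map panel CpGs to gene symbols
#'
#' Returns the deduplicated, sorted union of gene symbols linked to the
#' panel probes; probes without any gene link are reported separately.
#'
#' @param panel Character vector of probe ids.
#' @param annotation A [cpg_annotation()] covering every panel probe.
#' @return List: `genes` (sorted unique symbols), `unmapped` (probes with
#'   no gene link).
#' @export
map_cpg_to_genes <- function(panel, annotation) {
  stopifnot(inherits(annotation, "cpg_annotation"))
  panel <- unique(as.character(panel))
  absent <- setdiff(panel, annotation$probes$cpg_id)
  if (length(absent) > 0) {
    stop_oam("probes absent from annotation: %s",
             paste(utils::head(absent, 5), collapse = ", "))
  }
  ln <- annotation$links[annotation$links$cpg_id %in% panel, , drop = FALSE]
  list(genes = sort(unique(ln$gene)),
       unmapped = sort(setdiff(panel, ln$cpg_id)))
}

#' Classify mapped genes by effector-evidence status
#'
#' Splits a gene list into three disjoint groups: previously validated
#' effector genes, genes reported in curated databases or related studies,
#' and remaining novel candidates. A gene present in both reference lists
#' counts as validated (precedence).
#'
#' @param genes Character vector of mapped genes.
#' @param validated Reference list of validated effector genes.
#' @param database_reported Reference list of database-reported genes.
#' @return List: `n_validated`, `n_database`, `n_novel`, plus the three
#'   gene vectors (`validated_genes`, `database_genes`, `novel_genes`).
#' @export
classify_effector_status <- function(genes, validated, database_reported) {
  genes <- unique(as.character(genes))
  v <- intersect(genes, validated)
  rest <- setdiff(genes, v)
  d <- intersect(rest, database_reported)
  n <- setdiff(rest, d)
  list(n_validated = length(v), n_database = length(d), n_novel = length(n),
       validated_genes = sort(v), database_genes = sort(d),
       novel_genes = sort(n))
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a query gene list against each named
#' gene set, with Benjamini-Hochberg adjustment across all tested sets
#' (the same routine used by the differential-methylation screen). Sets
#' are intersected with the background universe before testing.
#'
#' @param query Character vector of query genes (must lie in
#'   `background`).
#' @param sets Named list of character vectors (`gene_set_collection`).
#' @param background Character vector: the gene universe.
#' @return data.frame sorted by `adj_p`: `set_name`, `overlap_count`,
#'   `set_size`, `query_size`, `background_size`, `p_value`, `adj_p`.
#' @export
hypergeometric_ora <- function(query, sets, background) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop_oam("empty background universe")
  query <- unique(as.character(query))
  if (!all(query %in% background)) {
    stop_oam("query genes outside the background universe: %s",
             paste(utils::head(setdiff(query, background), 5), collapse = ", "))
  }
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), length(background) - length(s),
                       length(query), lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = length(s),
               query_size = length(query),
               background_size = length(background), p_value = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$adj_p <- benjamini_hochberg(tab$p_value)
  tab[order(tab$adj_p, tab$p_value, tab$set_name), , drop = FALSE]
}

#' Load a STRING-like edge list
#'
#' Reads a tab-separated file with two endpoint columns and an integer
#' combined-score column, keeps edges with `combined_score >= min_score`
#' (inclusive threshold), drops self-loops, and merges duplicate
#' undirected edges keeping the maximum score.
#'
#' @param path Edge-list TSV (header: `node_a`, `node_b`,
#'   `combined_score`).
#' @param min_score Minimum combined score retained (default 500).
#' @return An [interaction_network()].
#' @export
load_edge_list <- function(path, min_score = 500L) {
  lines <- readLines(path)
  if (length(lines) < 1) stop_oam("empty edge-list file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("node_a", "node_b", "combined_score")
  if (!all(need %in% header)) {
    stop_oam("edge list must have columns %s", paste(need, collapse = ", "))
  }
  ia <- match("node_a", header); ib <- match("node_b", header)
  is_ <- match("combined_score", header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    sc <- suppressWarnings(as.numeric(p[is_]))
    if (length(p) < length(header) || is.na(sc) || sc != floor(sc)) {
      stop_oam("malformed edge-list row at line %d", i + 1L)
    }
  }
  df <- data.frame(
    node_a = vapply(parts, `[[`, character(1), ia),
    node_b = vapply(parts, `[[`, character(1), ib),
    combined_score = as.integer(vapply(parts, `[[`, character(1), is_)),
    stringsAsFactors = FALSE
  )
  df <- df[df$node_a != df$node_b, , drop = FALSE]
  df <- df[df$combined_score >= min_score, , drop = FALSE]
  if (nrow(df) > 0) {
    a <- pmin(df$node_a, df$node_b)
    b <- pmax(df$node_a, df$node_b)
    df$node_a <- a; df$node_b <- b
    key <- paste(a, b, sep = "\r")
    df <- df[order(key, -df$combined_score), , drop = FALSE]
    df <- df[!duplicated(paste(df$node_a, df$node_b, sep = "\r")), , drop = FALSE]
    rownames(df) <- NULL
  }
  interaction_network(df)
}

#' Write an interaction network as an edge-list TSV
#'
#' @param network An [interaction_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  g
}

#' Composite centrality hub scoring
#'
#' Computes normalized degree centrality (`degree / (n - 1)`) and
#' normalized betweenness centrality for every node, min-max standardizes
#' each metric over nodes (constant metrics standardize to 0), combines
#' them as `composite = w_degree * degree_std + w_between * between_std`,
#' and returns the top-scoring nodes (descending composite, node-id
#' tie-break).
#'
#' @param network An [interaction_network()].
#' @param w_degree,w_between Non-negative weights summing to 1.
#' @param top_k Number of top nodes returned (default 20; capped at the
#'   node count).
#' @return data.frame of class `node_score`: `node`, `degree_c`,
#'   `betweenness_c`, `degree_std`, `betweenness_std`, `composite`, for the
#'   top `top_k` nodes.
#' @export
composite_node_score <- function(network, w_degree = 0.5, w_between = 0.5,
                                 top_k = 20L) {
  stopifnot(inherits(network, "interaction_network"))
  assert_number(w_degree, "w_degree", 0, 1)
  assert_number(w_between, "w_between", 0, 1)
  if (abs(w_degree + w_between - 1) > 1e-9) {
    stop_oam("centrality weights must sum to 1")
  }
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  deg_c <- if (n > 1) deg / (n - 1) else deg * 0
  bet_c <- if (n > 2) {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  } else stats::setNames(rep(0, n), igraph::V(g)$name)
  minmax <- function(v) {
    r <- range(v)
    if (r[2] - r[1] < .Machine$double.eps) return(v * 0)
    (v - r[1]) / (r[2] - r[1])
  }
  deg_s <- minmax(deg_c)
  bet_s <- minmax(bet_c)
  comp <- w_degree * deg_s + w_between * bet_s
  out <- data.frame(node = igraph::V(g)$name, degree_c = unname(deg_c),
                    betweenness_c = unname(bet_c), degree_std = unname(deg_s),
                    betweenness_std = unname(bet_s), composite = unname(comp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$composite, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out <- utils::head(out, min(assert_count(top_k, "top_k"), nrow(out)))
  class(out) <- c("node_score", "data.frame")
  out
}
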