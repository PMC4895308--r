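# Signed directed graph core: construction, shortest-path parity counting,
# and the conflict-adjusted distance.

#' Map interaction effect terms to edge signs
#'
#' Activation-like relations (`activation`, `expression`) become `+1`,
#' inhibition-like relations (`inhibition`, `repression`) become `-1`.
#' Pre-signed values (`"+1"`, `"1"`, `"-1"`, or numeric `1`/`-1`) pass
#' through unchanged.
#'
#' @param effect character or numeric vector of effect annotations.
#' @return integer vector of `+1`/`-1` signs.
#' @examples
#' effect_to_sign(c("activation", "repression", "+1"))
#' @export
effect_to_sign <- function(effect) {
  if (is.numeric(effect)) {
    bad <- !effect %in% c(-1, 1)
    if (any(bad)) {
      stop("invalid edge sign(s): ", paste(unique(effect[bad]), collapse = ", "),
           " (must be +1 or -1)")
    }
    return(as.integer(effect))
  }
  key <- tolower(trimws(as.character(effect)))
  map <- c(activation = 1L, expression = 1L, inhibition = -1L, repression = -1L,
           "+1" = 1L, "1" = 1L, "-1" = -1L)
  sign <- unname(map[key])
  bad <- is.na(sign)
  if (any(bad)) {
    stop("unknown effect term(s): ", paste(unique(effect[bad]), collapse = ", "))
  }
  sign
}

#' Build a signed directed graph
#'
#' Constructs a `signed_digraph` from an edge table. Nodes are opaque,
#' case-sensitive gene identifiers. Each edge carries a sign: `+1` for
#' activation-like relations, `-1` for inhibition-like. Duplicate identical
#' records are collapsed to a single edge; parallel edges between the same
#' ordered pair with *opposite* signs are both retained (conflicting curated
#' assertions are preserved, not resolved at build time).
#'
#' @param edges a data.frame with columns `source`, `target` and either
#'   `sign` (`+1`/`-1`) or `effect` (terms understood by
#'   [effect_to_sign()]); alternatively a list of length-3 records
#'   `(source, target, sign)`.
#' @param nodes optional character vector of additional node identifiers,
#'   e.g. genes present in a pathway without any signed relation. Isolated
#'   nodes matter downstream: disease genes mapping onto them are discarded
#'   during restriction.
#' @return an object of class `signed_digraph` with elements `nodes`
#'   (character vector) and `edges` (data.frame `source`, `target`, `sign`).
#' @examples
#' g <- build_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
#'                             sign = c(1, -1)))
#' g
#' @seealso [shortest_path_parity()], [conflict_distance()]
#' @export
build_graph <- function(edges, nodes = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) {
    rec <- lapply(seq_along(edges), function(i) {
      e <- edges[[i]]
      if (length(e) != 3L) {
        stop("malformed edge record at position ", i,
             ": expected (source, target, sign), got ",
             paste(as.character(e), collapse = ", "))
      }
      data.frame(source = as.character(e[[1]]), target = as.character(e[[2]]),
                 sign = suppressWarnings(as.numeric(e[[3]])),
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rec)
  }
  if (!is.data.frame(edges)) stop("`edges` must be a data.frame or list of records")
  if (nrow(edges) == 0L && is.null(nodes)) stop("empty edge table and no nodes given")
  if (!all(c("source", "target") %in% names(edges))) {
    stop("edge table must have columns `source` and `target`")
  }
  if (!"sign" %in% names(edges)) {
    if (!"effect" %in% names(edges)) {
      stop("edge table must have a `sign` or `effect` column")
    }
    edges$sign <- effect_to_sign(edges$effect)
  }
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)
  sgn <- edges$sign
  bad <- which(is.na(src) | is.na(tgt) | !nzchar(src) | !nzchar(tgt) |
                 is.na(sgn) | !sgn %in% c(-1, 1))
  if (length(bad)) {
    i <- bad[1L]
    stop("malformed edge record ", i, ": (",
         src[i], ", ", tgt[i], ", ", sgn[i], ")")
  }
  ed <- unique(data.frame(source = src, target = tgt, sign = as.integer(sgn),
                          stringsAsFactors = FALSE))
  rownames(ed) <- NULL
  node_ids <- unique(c(as.character(nodes), ed$source, ed$target))
  # index-based adjacency for the parity BFS
  from <- match(ed$source, node_ids)
  to <- match(ed$target, node_ids)
  adj_to <- vector("list", length(node_ids))
  adj_sign <- vector("list", length(node_ids))
  ord <- split(seq_len(nrow(ed)), factor(from, levels = seq_along(node_ids)))
  for (i in seq_along(node_ids)) {
    idx <- ord[[i]]
    adj_to[[i]] <- to[idx]
    adj_sign[[i]] <- ed$sign[idx]
  }
  structure(list(nodes = node_ids, edges = ed,
                 adj_to = adj_to, adj_sign = adj_sign),
            class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  n_neg <- sum(x$edges$sign < 0)
  cat("signed_digraph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " signed edges (", nrow(x$edges) - n_neg, " activation-like, ",
      n_neg, " inhibition-like)\n", sep = "")
  invisible(x)
}

#' Node identifiers of a signed digraph
#' @param graph a `signed_digraph`.
#' @return character vector of node ids.
#' @export
graph_nodes <- function(graph) {
  stopifnot(inherits(graph, "signed_digraph"))
  graph$nodes
}

#' Total degree (in + out) of every node
#' @param graph a `signed_digraph`.
#' @return named integer vector over all nodes; isolated nodes have degree 0.
#' @export
graph_degree <- function(graph) {
  stopifnot(inherits(graph, "signed_digraph"))
  d <- table(factor(c(graph$edges$source, graph$edges$target),
                    levels = graph$nodes))
  stats::setNames(as.integer(d), graph$nodes)
}

#' Convert a signed digraph to an igraph object
#'
#' Used for operations where sign and (optionally) direction are
#' deliberately discarded, e.g. the PDD baseline's plain hop distances.
#'
#' @param graph a `signed_digraph`.
#' @return an igraph graph with a `sign` edge attribute.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "signed_digraph"))
  igraph::graph_from_data_frame(graph$edges,
                                vertices = data.frame(name = graph$nodes),
                                directed = TRUE)
}

.node_index <- function(graph, id, what = "node") {
  i <- match(id, graph$nodes)
  if (is.na(i)) stop("unknown ", what, " id: ", id)
  i
}

# Layered BFS dynamic programming over (node, parity) states.
# From `source_idx`, computes for every node the unweighted shortest-path
# hop distance plus the number of shortest paths with an even (n_even) and
# odd (n_odd) count of inhibition edges. Parallel signed edges count as
# distinct steps. Counts are doubles; exact up to 2^53 paths.
.parity_bfs <- function(graph, source_idx) {
  n <- length(graph$nodes)
  dist <- rep(Inf, n)
  n_even <- numeric(n)
  n_odd <- numeric(n)
  dist[source_idx] <- 0
  n_even[source_idx] <- 1
  frontier <- source_idx
  d <- 0
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      to <- graph$adj_to[[u]]
      sg <- graph$adj_sign[[u]]
      for (j in seq_along(to)) {
        v <- to[j]
        if (is.infinite(dist[v])) {
          dist[v] <- d + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == d + 1) {
          if (sg[j] > 0L) {
            n_even[v] <- n_even[v] + n_even[u]
            n_odd[v] <- n_odd[v] + n_odd[u]
          } else {
            n_even[v] <- n_even[v] + n_odd[u]
            n_odd[v] <- n_odd[v] + n_even[u]
          }
        }
      }
    }
    frontier <- unique(nxt)
    d <- d + 1
  }
  list(hop = dist, n_activation = n_even, n_inhibition = n_odd)
}

#' Shortest-path census by inhibition parity
#'
#' Finds all directed shortest paths from `source` to `target` and splits
#' them into activation-like paths (an even number of inhibition edges,
#' zero included) and inhibition-like paths (an odd number). Counting is
#' done by layered breadth-first dynamic programming over (node, parity)
#' states, so dense conflict regions never require explicit enumeration;
#' the result is identical to enumerating every minimal-length path.
#'
#' A node trivially reaches itself: `hop = 0` with one activation-like
#' path. An unreachable target yields `hop = Inf` with zero counts.
#'
#' @param graph a `signed_digraph`.
#' @param source,target node identifiers present in the graph.
#' @return a list of class `path_parity` with elements `hop` (non-negative
#'   integer or `Inf`), `n_activation` and `n_inhibition` (path counts).
#' @examples
#' g <- build_graph(data.frame(source = c("A", "X"), target = c("X", "B"),
#'                             sign = c(1, -1)))
#' shortest_path_parity(g, "A", "B")  # hop 2, one inhibition-like path
#' @export
shortest_path_parity <- function(graph, source, target) {
  stopifnot(inherits(graph, "signed_digraph"))
  s <- .node_index(graph, source, "source node")
  t <- .node_index(graph, target, "target node")
  res <- .parity_bfs(graph, s)
  structure(list(hop = res$hop[t],
                 n_activation = res$n_activation[t],
                 n_inhibition = res$n_inhibition[t]),
            class = "path_parity")
}

#' @export
print.path_parity <- function(x, ...) {
  cat("path_parity: hop ", x$hop, ", ", x$n_activation,
      " activation-like, ", x$n_inhibition, " inhibition-like\n", sep = "")
  invisible(x)
}

# Vectorised conflict-adjusted distance over parallel hop / count vectors.
.conflict_distance_values <- function(hop, n_activation, n_inhibition) {
  dc <- rep(Inf, length(hop))
  finite <- is.finite(hop) & n_activation != n_inhibition
  dc[finite] <- (n_activation[finite] + n_inhibition[finite]) /
    (n_activation[finite] - n_inhibition[finite]) * hop[finite]
  dc
}

#' Conflict-adjusted distance between a drug target and a disease gene
#'
#' Combines a shortest-path parity census into a single signed distance
#'
#' \deqn{d_c = \frac{n_a + n_i}{n_a - n_i}\,|d|}
#'
#' where \eqn{n_a} and \eqn{n_i} are the activation-like and
#' inhibition-like shortest-path counts and \eqn{|d|} the hop distance.
#' The sign says whether the net shortest-path effect is activating
#' (positive) or inhibiting (negative); the magnitude grows beyond the hop
#' distance as the two parity classes approach a tie, signalling an
#' unreliable net effect. When the classes tie exactly, or the pair is
#' unreachable, the distance is the infinity sentinel `Inf` (unsigned;
#' every downstream kernel maps it to exactly 0).
#'
#' A target sitting directly on its disease gene (`hop = 0`) gets
#' \eqn{d_c = 0}, treated as activation-like with positive sign (see
#' [dc_sign()]).
#'
#' @param parity a `path_parity` as returned by [shortest_path_parity()],
#'   or a list with elements `hop`, `n_activation`, `n_inhibition`.
#' @return a single numeric: signed finite distance, or `Inf`.
#' @examples
#' conflict_distance(list(hop = 3, n_activation = 2, n_inhibition = 0)) # +3
#' conflict_distance(list(hop = 2, n_activation = 8, n_inhibition = 1)) # 18/7
#' conflict_distance(list(hop = 5, n_activation = 4, n_inhibition = 4)) # Inf
#' @export
conflict_distance <- function(parity) {
  stopifnot(is.list(parity),
            all(c("hop", "n_activation", "n_inhibition") %in% names(parity)))
  hop <- parity$hop
  na <- parity$n_activation
  ni <- parity$n_inhibition
  if (is.finite(hop) && hop > 0 && na + ni < 1) {
    stop("invalid parity: finite hop with zero paths")
  }
  if (any(na < 0) || any(ni < 0)) stop("invalid parity: negative path count")
  .conflict_distance_values(hop, na, ni)
}

#' Sign convention for conflict-adjusted distances
#'
#' `+1` for non-negative distances (including the `d_c = 0` case of a
#' target that is itself a disease gene) and `-1` for negative ones. The
#' infinity sentinel maps to `+1`, which is inconsequential: its kernel
#' value is exactly 0.
#'
#' @param d_c numeric vector of conflict-adjusted distances.
#' @return integer vector of `+1`/`-1`.
#' @export
dc_sign <- function(d_c) {
  ifelse(d_c >= 0, 1L, -1L)
}

#' Read a signed edge table
#'
#' Accepts a headered TSV with columns `source`, `target`, `effect`
#' (effect terms or pre-signed values, see [effect_to_sign()]) or a
#' headerless SIF-like 3-column variant interpreted positionally.
#'
#' @param path path to the file.
#' @return data.frame with columns `source`, `target`, `sign`, ready for
#'   [build_graph()].
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stop("edge table not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    all(c("source", "target") %in% tolower(strsplit(first, "\t")[[1]]))
  tab <- utils::read.delim(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!has_header) {
    if (ncol(tab) < 3L) stop("headerless edge table needs 3 columns: ", path)
    names(tab)[1:3] <- c("source", "target", "effect")
  }
  names(tab) <- tolower(names(tab))
  if (!all(c("source", "target") %in% names(tab))) {
    stop("edge table missing source/target columns: ", path)
  }
  eff_col <- if ("effect" %in% names(tab)) "effect" else if ("sign" %in% names(tab)) "sign" else
    stop("edge table missing effect/sign column: ", path)
  data.frame(source = tab$source, target = tab$target,
             sign = effect_to_sign(tab[[eff_col]]),
             stringsAsFactors = FALSE)
}
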