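# Independent oracles and fixture builders shared across test files.

# Random Erdos-Renyi signed digraph over n nodes; guarantees at least one
# edge so build_graph always succeeds.
random_signed_graph <- function(n, p = 0.25, inhibition = 0.4) {
  ids <- paste0("n", seq_len(n))
  pairs <- expand.grid(s = seq_len(n), t = seq_len(n))
  pairs <- pairs[pairs$s != pairs$t, ]
  sel <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  if (nrow(sel) == 0L) sel <- pairs[sample.int(nrow(pairs), 1L), , drop = FALSE]
  sign <- ifelse(runif(nrow(sel)) < inhibition, -1L, 1L)
  build_graph(data.frame(source = ids[sel$s], target = ids[sel$t],
                         sign = sign, stringsAsFactors = FALSE),
              nodes = ids)
}

# Exhaustive shortest-path parity census: plain BFS for the hop distance,
# then depth-first enumeration of every walk of exactly that length (any
# such walk reaching the target is a shortest path), tallying inhibition
# parity. Works straight off the edge table; shares no code with the
# package's layered DP.
enum_parity <- function(graph, source, target) {
  edges <- graph$edges
  dist <- stats::setNames(rep(Inf, length(graph$nodes)), graph$nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (v in unique(edges$target[edges$source == u])) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  hop <- unname(dist[target])
  if (is.infinite(hop)) {
    return(list(hop = Inf, n_activation = 0, n_inhibition = 0))
  }
  counts <- c(even = 0, odd = 0)
  walk <- function(u, depth, negs) {
    if (depth == hop) {
      if (u == target) {
        idx <- if (negs %% 2 == 0) "even" else "odd"
        counts[idx] <<- counts[idx] + 1
      }
      return(invisible(NULL))
    }
    e <- edges[edges$source == u, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      walk(e$target[i], depth + 1, negs + (e$sign[i] < 0))
    }
  }
  walk(source, 0, 0)
  list(hop = hop, n_activation = unname(counts["even"]),
       n_inhibition = unname(counts["odd"]))
}

# Inhibitory single-target drug facing one up-regulated gene at d_c = +1
# and one down-regulated gene at d_c = -3; both sign terms are +1 and the
# hand-computed score at alpha = 3 is (0.9 + 0.5) / 2 = 0.7.
antagonist_fixture <- function() {
  graph <- build_graph(data.frame(
    source = c("t", "t", "x", "y"),
    target = c("gu", "x", "y", "gd"),
    sign = c(1L, -1L, 1L, 1L)))
  list(graph = graph,
       drug = data.frame(gene = "t", effect = -1L,
                         stringsAsFactors = FALSE),
       disease = data.frame(gene = c("gu", "gd"), state = c(-1L, 1L),
                            stringsAsFactors = FALSE))
}

# Small random scoring fixture: graph + one drug + one disease, all
# genes guaranteed to be graph nodes.
random_scoring_fixture <- function(n = 8, p = 0.3, n_targets = 2,
                                   n_genes = 2) {
  g <- random_signed_graph(n, p)
  nodes <- graph_nodes(g)
  list(graph = g,
       drug = data.frame(gene = sample(nodes, n_targets),
                         effect = sample(c(-1L, 1L), n_targets,
                                         replace = TRUE),
                         stringsAsFactors = FALSE),
       disease = data.frame(gene = sample(nodes, n_genes),
                            state = sample(c(-1L, 1L), n_genes,
                                           replace = TRUE),
                            stringsAsFactors = FALSE))
}

# A minimal KGML document exercising gene entries, a multi-gene entry, a
# compound entry, a group entry and a mix of recognised and unrecognised
# relation subtypes.
kgml_fixture <- function() {
  paste0('<?xml version="1.0"?>\n',
         '<pathway name="path:syn001" org="syn" number="001">\n',
         '  <entry id="1" name="hsa:111" type="gene"/>\n',
         '  <entry id="2" name="hsa:222" type="gene"/>\n',
         '  <entry id="3" name="hsa:333 hsa:444" type="gene"/>\n',
         '  <entry id="4" name="cpd:C00001" type="compound"/>\n',
         '  <entry id="5" name="undefined" type="group">\n',
         '    <component id="1"/>\n',
         '    <component id="2"/>\n',
         '  </entry>\n',
         '  <entry id="6" name="hsa:555" type="gene"/>\n',
         '  <relation entry1="1" entry2="2" type="PPrel">\n',
         '    <subtype name="activation" value="--&gt;"/>\n',
         '  </relation>\n',
         '  <relation entry1="1" entry2="2" type="PPrel">\n',
         '    <subtype name="phosphorylation" value="+p"/>\n',
         '  </relation>\n',
         '  <relation entry1="2" entry2="3" type="GErel">\n',
         '    <subtype name="expression" value="--&gt;"/>\n',
         '  </relation>\n',
         '  <relation entry1="1" entry2="4" type="PCrel">\n',
         '    <subtype name="inhibition" value="--|"/>\n',
         '  </relation>\n',
         '  <relation entry1="6" entry2="5" type="PPrel">\n',
         '    <subtype name="repression" value="--|"/>\n',
         '  </relation>\n',
         '</pathway>\n')
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
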