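# PDOD scoring: sign-weighted bell-kernel aggregation of conflict-adjusted
# distances, plus the directionless PDD baseline.

#' Bell-shaped distance kernel
#'
#' \deqn{k(d_c) = \frac{1}{1 + |d_c/\alpha|^2}}
#'
#' A Cauchy-shaped bump that is exactly 1 at distance 0, falls to 0.5 at
#' the half-width `alpha`, and decays quadratically beyond it — encoding
#' the assumption that a target's influence on a gene fades rapidly past a
#' characteristic network distance. The infinity sentinel (unreachable
#' pairs or exact activation/inhibition path ties) evaluates to exactly 0,
#' never `NaN`.
#'
#' @param d_c numeric vector of conflict-adjusted distances (may contain
#'   `Inf`).
#' @param alpha positive half-width; default 3.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' bell_kernel(c(0, 3, Inf))        # 1.0, 0.5, 0.0
#' @export
bell_kernel <- function(d_c, alpha = 3) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a single positive number")
  }
  k <- numeric(length(d_c))
  finite <- is.finite(d_c)
  k[finite] <- 1 / (1 + (abs(d_c[finite]) / alpha)^2)
  k
}

#' Sign term of a (target, disease gene) pair
#'
#' The product of the drug-target effect type, the sign of the
#' conflict-adjusted distance, and the disease gene's altered state:
#' `+1` means the drug opposes the gene's alteration through this target
#' (therapeutic direction), `-1` means it reinforces it.
#'
#' @param i_effect drug-target effect type: `+1` activation-like, `-1`
#'   inhibition-like.
#' @param d_c_sign sign of the conflict-adjusted distance per [dc_sign()]
#'   (`+1` at `d_c = 0`).
#' @param gene_state `+1` down-regulated, `-1` up-regulated.
#' @return integer vector of `+1`/`-1`.
#' @examples
#' sgn_term(-1, +1, -1)  # inhibitor of a net activator of an up gene: +1
#' @export
sgn_term <- function(i_effect, d_c_sign, gene_state) {
  ok <- function(v) all(v %in% c(-1, 1))
  if (!ok(i_effect) || !ok(d_c_sign) || !ok(gene_state)) {
    stop("all sign factors must be +1 or -1")
  }
  as.integer(i_effect * d_c_sign * gene_state)
}

.check_scoring_inputs <- function(drug, disease) {
  if (!is.data.frame(drug) || nrow(drug) == 0L ||
      !all(c("gene", "effect") %in% names(drug))) {
    stop("`drug` must be a non-empty data.frame with columns gene, effect ",
         "(drugs without typed in-network targets are excluded upstream)")
  }
  if (!is.data.frame(disease) || nrow(disease) == 0L ||
      !all(c("gene", "state") %in% names(disease))) {
    stop("`disease` must be a non-empty data.frame with columns gene, state")
  }
}

#' PDOD score of a drug against a disease
#'
#' \deqn{\mathrm{score}(R,G) = \frac{1}{n_g n_r}\sum_{i=1}^{n_r}
#'   \sum_{j=1}^{n_g} \mathrm{sgn}(r_i, g_j)\,
#'   \frac{1}{1 + |d_c(r_i, g_j)/\alpha|^2}}
#'
#' For every typed drug target and disease gene the conflict-adjusted
#' shortest-path distance is computed on the signed directed graph, its
#' kernel value weighted by the sign term ([sgn_term()]), and the double
#' sum normalised by the number of targets `n_r` times the number of
#' disease genes `n_g`. Unreachable or conflict-tied pairs contribute
#' exactly 0; the normalisation by `n_r` penalises drugs carrying many
#' off-targets. Scores lie in `[-1, 1]`; positive scores mark drugs whose
#' net propagated effect opposes the disease's gene-state alterations.
#'
#' Both `drug` and `disease` are expected to have passed through
#' [restrict_to_graph()]: `n_r` counts the typed targets remaining in the
#' network.
#'
#' @param drug data.frame with one row per typed target: columns `gene`,
#'   `effect` (+1/-1).
#' @param disease data.frame with one row per disease gene: columns
#'   `gene`, `state` (+1 down-regulated, -1 up-regulated).
#' @param graph a `signed_digraph`.
#' @param alpha bell-kernel half-width, default 3.
#' @return a single numeric score in `[-1, 1]`.
#' @export
pdod_score <- function(drug, disease, graph, alpha = 3) {
  .check_scoring_inputs(drug, disease)
  stopifnot(inherits(graph, "signed_digraph"))
  gene_idx <- vapply(disease$gene, .node_index, integer(1), graph = graph,
                     what = "disease gene")
  contrib <- numeric(0)
  for (i in seq_len(nrow(drug))) {
    res <- .parity_bfs(graph, .node_index(graph, drug$gene[i], "drug target"))
    dc <- .conflict_distance_values(res$hop[gene_idx],
                                    res$n_activation[gene_idx],
                                    res$n_inhibition[gene_idx])
    contrib <- c(contrib,
                 sgn_term(drug$effect[i], dc_sign(dc), disease$state) *
                   bell_kernel(dc, alpha))
  }
  sum(contrib) / (nrow(drug) * nrow(disease))
}

# Plain hop distances with effect type and (optionally) direction removed.
.baseline_hops <- function(graph, targets, genes,
                           mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  ig <- as_igraph(graph)
  igraph::distances(ig, v = targets, to = genes,
                    mode = if (mode == "undirected") "all" else "out")
}

#' PDD baseline score (no directional information)
#'
#' The same kernel aggregation as [pdod_score()] with every piece of
#' directional information removed: the sign term is identically `+1`,
#' and the distance is the plain hop distance on the unsigned network —
#' by default on its undirected projection (both effect type and effect
#' direction discarded), optionally directed-but-unsigned. Scores lie in
#' `[0, 1]` and are invariant to edge signs, drug effect types and gene
#' states; the contrast with PDOD isolates the value of directionality.
#'
#' @inheritParams pdod_score
#' @param mode `"undirected"` (default) or `"directed"` hop distances.
#' @return a single numeric score in `[0, 1]`.
#' @export
pdd_score <- function(drug, disease, graph, alpha = 3,
                      mode = c("undirected", "directed")) {
  .check_scoring_inputs(drug, disease)
  stopifnot(inherits(graph, "signed_digraph"))
  mode <- match.arg(mode)
  bad <- setdiff(c(drug$gene, disease$gene), graph$nodes)
  if (length(bad)) stop("unknown node id: ", bad[1])
  h <- .baseline_hops(graph, drug$gene, disease$gene, mode)
  # transpose: genes vary fastest, matching score_all()'s summation order
  sum(bell_kernel(as.vector(t(h)), alpha)) / (nrow(drug) * nrow(disease))
}

# Per (drug, disease, target, gene) decomposition shared by score_all()
# and alpha_sweep(): everything that does not depend on alpha. Parity BFS
# runs once per unique target gene; undirected hops once per target set.
.pair_terms <- function(drugs, diseases, graph,
                        pdd_mode = c("undirected", "directed")) {
  pdd_mode <- match.arg(pdd_mode)
  stopifnot(inherits(graph, "signed_digraph"))
  bad <- setdiff(c(drugs$gene, diseases$gene), graph$nodes)
  if (length(bad)) stop("unknown node id: ", bad[1])

  genes <- unique(diseases$gene)
  gene_idx <- match(genes, graph$nodes)
  targets <- unique(drugs$gene)

  dc_tab <- matrix(Inf, nrow = length(targets), ncol = length(genes),
                   dimnames = list(targets, genes))
  for (t in seq_along(targets)) {
    res <- .parity_bfs(graph, match(targets[t], graph$nodes))
    dc_tab[t, ] <- .conflict_distance_values(res$hop[gene_idx],
                                             res$n_activation[gene_idx],
                                             res$n_inhibition[gene_idx])
  }
  hop_tab <- if (length(targets) && length(genes)) {
    .baseline_hops(graph, targets, genes, pdd_mode)
  } else {
    matrix(numeric(0), length(targets), length(genes))
  }
  dimnames(hop_tab) <- list(targets, genes)

  dis_split <- split(seq_len(nrow(diseases)), diseases$disease_id)
  drug_split <- split(seq_len(nrow(drugs)), drugs$drug_id)
  rows <- list()
  for (did in names(dis_split)) {
    dg <- diseases[dis_split[[did]], , drop = FALSE]
    for (rid in names(drug_split)) {
      dr <- drugs[drug_split[[rid]], , drop = FALSE]
      # gene index varies fastest so the summation order matches the
      # target-outer / gene-inner loop of pdod_score() bit for bit
      grid <- expand.grid(gj = seq_len(nrow(dg)), ti = seq_len(nrow(dr)),
                          KEEP.OUT.ATTRS = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = rid,
        disease_id = did,
        target = dr$gene[grid$ti],
        gene = dg$gene[grid$gj],
        effect = dr$effect[grid$ti],
        state = dg$state[grid$gj],
        d_c = dc_tab[cbind(dr$gene[grid$ti], dg$gene[grid$gj])],
        hop_plain = hop_tab[cbind(dr$gene[grid$ti], dg$gene[grid$gj])],
        n_r = nrow(dr),
        n_g = nrow(dg),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(drug_id = character(0), disease_id = character(0),
                      target = character(0), gene = character(0),
                      effect = integer(0), state = integer(0),
                      d_c = numeric(0), hop_plain = numeric(0),
                      n_r = integer(0), n_g = integer(0)))
  }
  do.call(rbind, rows)
}

.scores_from_terms <- function(terms, alpha) {
  terms$sgn <- sgn_term(terms$effect, dc_sign(terms$d_c), terms$state)
  terms$kernel <- bell_kernel(terms$d_c, alpha)
  norm <- terms$n_r * terms$n_g
  terms$contribution <- terms$sgn * terms$kernel / norm
  pdd_kernel <- bell_kernel(terms$hop_plain, alpha)
  key <- interaction(terms$drug_id, terms$disease_id, drop = TRUE, sep = "\r")
  # sum the raw sgn x kernel terms per pair, divide once: bit-identical to
  # an independent pdod_score() call on the same inputs
  pdod <- tapply(terms$sgn * terms$kernel, key, sum) / tapply(norm, key, `[`, 1)
  pdd <- tapply(pdd_kernel, key, sum) / tapply(norm, key, `[`, 1)
  ids <- do.call(rbind, strsplit(names(pdod), "\r", fixed = TRUE))
  list(scores = data.frame(drug_id = ids[, 1], disease_id = ids[, 2],
                           pdod = as.numeric(pdod), pdd = as.numeric(pdd),
                           stringsAsFactors = FALSE),
       detail = terms)
}

#' Score every drug against every disease
#'
#' Computes the full drug-by-disease PDOD and PDD score matrix. The
#' conflict-adjusted distance for each (target gene, disease gene) pair is
#' computed once and shared across all drugs targeting that gene, so the
#' result is identical — bitwise — to scoring each pair independently.
#'
#' @param drugs data.frame of typed drug-target interactions (`drug_id`,
#'   optionally `drug_name`, `gene`, `effect`), already restricted to the
#'   graph.
#' @param diseases data.frame of disease genes (`disease_id`, `gene`,
#'   `state`), already restricted.
#' @param graph a `signed_digraph`.
#' @param alpha bell-kernel half-width, default 3.
#' @param pdd_mode hop-distance convention for the PDD baseline.
#' @param detail keep the per-pair decomposition (target, disease gene,
#'   `d_c`, sign term, kernel value, contribution)?
#' @return object of class `pdod_scores`: list with `scores` (data.frame
#'   `drug_id`, `drug_name`, `disease_id`, `pdod`, `pdd`), `alpha`,
#'   `pdd_mode`, and `detail` (data.frame or `NULL`).
#' @export
score_all <- function(drugs, diseases, graph, alpha = 3,
                      pdd_mode = c("undirected", "directed"),
                      detail = FALSE) {
  pdd_mode <- match.arg(pdd_mode)
  if (!is.data.frame(drugs) || !is.data.frame(diseases)) {
    stop("`drugs` and `diseases` must be data.frames")
  }
  terms <- .pair_terms(drugs, diseases, graph, pdd_mode)
  if (nrow(terms) == 0L) {
    scores <- data.frame(drug_id = character(0), disease_id = character(0),
                         pdod = numeric(0), pdd = numeric(0),
                         stringsAsFactors = FALSE)
    return(structure(list(scores = scores, alpha = alpha,
                          pdd_mode = pdd_mode, detail = NULL),
                     class = "pdod_scores"))
  }
  res <- .scores_from_terms(terms, alpha)
  scores <- res$scores
  if ("drug_name" %in% names(drugs)) {
    nm <- unique(drugs[c("drug_id", "drug_name")])
    scores$drug_name <- nm$drug_name[match(scores$drug_id, nm$drug_id)]
    scores <- scores[c("drug_id", "drug_name", "disease_id", "pdod", "pdd")]
  }
  structure(list(scores = scores, alpha = alpha, pdd_mode = pdd_mode,
                 detail = if (detail) res$detail else NULL),
            class = "pdod_scores")
}

#' @export
print.pdod_scores <- function(x, ...) {
  cat("pdod_scores: ", length(unique(x$scores$drug_id)), " drugs x ",
      length(unique(x$scores$disease_id)), " diseases (alpha = ", x$alpha,
      ", pdd = ", x$pdd_mode, ")\n", sep = "")
  utils::str(x$scores, give.attr = FALSE)
  invisible(x)
}

#' Write per-disease ranked score tables
#'
#' One headered TSV per disease (`scores_<disease>.tsv`) with columns
#' `drug_id`, `drug_name`, `pdod_score`, `pdd_score`, `rank` (dense rank
#' by descending PDOD score; ties share the smaller rank). Scores are
#' written with six decimal places. If the score object carries per-pair
#' detail, a companion `detail_<disease>.tsv` is written.
#'
#' @param x a `pdod_scores` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_scores <- function(x, dir) {
  stopifnot(inherits(x, "pdod_scores"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (did in unique(x$scores$disease_id)) {
    tab <- x$scores[x$scores$disease_id == did, , drop = FALSE]
    ord <- order(-tab$pdod, tab$drug_id)
    tab <- tab[ord, , drop = FALSE]
    out <- data.frame(
      drug_id = tab$drug_id,
      drug_name = if ("drug_name" %in% names(tab)) tab$drug_name else tab$drug_id,
      pdod_score = sprintf("%.6f", tab$pdod),
      pdd_score = sprintf("%.6f", tab$pdd),
      rank = rank(-tab$pdod, ties.method = "min"),
      stringsAsFactors = FALSE)
    p <- file.path(dir, paste0("scores_", .safe_id(did), ".tsv"))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(x$detail)) {
      det <- x$detail[x$detail$disease_id == did,
                      c("drug_id", "target", "gene", "d_c", "sgn",
                        "kernel", "contribution")]
      names(det)[3] <- "disease_gene"
      pd <- file.path(dir, paste0("detail_", .safe_id(did), ".tsv"))
      utils::write.table(det, pd, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, pd)
    }
  }
  invisible(paths)
}

.safe_id <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
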