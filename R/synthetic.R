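# Synthetic study generator: a random signed regulatory network, a disease
# gene set with altered states, and a drug panel with planted ground truth
# (therapeutic / aggravating / neutral), all a pure function of the seed.

#' Configuration for a synthetic study
#'
#' Defaults describe the standard benchmark fixture: a 200-gene directed
#' Erdos-Renyi network with mean out-degree about 4 (edge probability
#' 0.02), 30% inhibition edges, one disease of 10 genes, and a 50-drug
#' panel of which 30% are planted therapeutic, with the remainder split
#' between aggravating and neutral drugs. Planted targets sit 1-3 hops
#' from a disease gene.
#'
#' @param n_genes number of genes (nodes).
#' @param edge_probability independent probability of each directed edge.
#' @param inhibition_fraction probability an edge is inhibition-signed.
#' @param n_drugs size of the drug panel.
#' @param targets_per_drug length-2 integer range of targets per drug.
#' @param n_disease_genes disease gene set size.
#' @param planted_therapeutic_fraction fraction of drugs planted as
#'   therapeutic; the rest split evenly aggravating / neutral.
#' @param planted_hop_range length-2 range of hop distances at which
#'   planted (therapeutic/aggravating) targets must reach a disease gene.
#' @param seed integer seed; the whole fixture is a pure function of it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200, edge_probability = 0.02,
                             inhibition_fraction = 0.3, n_drugs = 50,
                             targets_per_drug = c(1L, 3L),
                             n_disease_genes = 10,
                             planted_therapeutic_fraction = 0.3,
                             planted_hop_range = c(1L, 3L), seed = 1L) {
  stopifnot(n_genes >= 2, n_drugs >= 2, n_disease_genes >= 1,
            edge_probability > 0, edge_probability < 1,
            inhibition_fraction >= 0, inhibition_fraction <= 1,
            length(targets_per_drug) == 2, all(targets_per_drug >= 1),
            targets_per_drug[1] <= targets_per_drug[2],
            planted_therapeutic_fraction > 0,
            planted_therapeutic_fraction < 1,
            length(planted_hop_range) == 2, all(planted_hop_range >= 1),
            planted_hop_range[1] <= planted_hop_range[2],
            is.numeric(seed), length(seed) == 1, seed == round(seed),
            abs(seed) < 2^31 - 3)
  structure(list(n_genes = as.integer(n_genes),
                 edge_probability = edge_probability,
                 inhibition_fraction = inhibition_fraction,
                 n_drugs = as.integer(n_drugs),
                 targets_per_drug = as.integer(targets_per_drug),
                 n_disease_genes = as.integer(n_disease_genes),
                 planted_therapeutic_fraction = planted_therapeutic_fraction,
                 planted_hop_range = as.integer(planted_hop_range),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a random signed directed network
#'
#' Directed Erdos-Renyi model: every ordered gene pair (no self-loops)
#' carries an edge independently with `edge_probability`; each edge is
#' inhibition-signed (-1) with `inhibition_fraction`, activation-signed
#' (+1) otherwise. Seeded from `config$seed`: identical configs give
#' identical graphs. Gene ids are `g001`, `g002`, ...
#'
#' @param config a [synthetic_config()].
#' @return a `signed_digraph` whose node set always includes all
#'   `n_genes` genes (nodes left edgeless by the draw stay as isolated
#'   nodes).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%03d", seq_len(n))
  pairs <- expand.grid(source = seq_len(n), target = seq_len(n),
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  present <- stats::runif(nrow(pairs)) < config$edge_probability
  sel <- pairs[present, ]
  sign <- ifelse(stats::runif(nrow(sel)) < config$inhibition_fraction, -1L, 1L)
  build_graph(data.frame(source = ids[sel$source], target = ids[sel$target],
                         sign = sign, stringsAsFactors = FALSE),
              nodes = ids)
}

#' Generate a synthetic disease gene set
#'
#' Samples `n_disease_genes` genes with in-degree at least one (so planted
#' drug targets can reach them) and assigns each an up- or down-regulated
#' state uniformly at random. Seeded from `config$seed + 1`.
#'
#' @param graph a `signed_digraph`, typically from [generate_network()].
#' @param config a [synthetic_config()].
#' @param disease_id identifier for the generated disease.
#' @return data.frame `disease_id`, `gene`, `state` (+1 down, -1 up).
#' @export
generate_disease <- function(graph, config, disease_id = "SYNTH1") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  indeg <- table(factor(graph$edges$target, levels = graph$nodes))
  candidates <- graph$nodes[indeg > 0]
  if (length(candidates) < config$n_disease_genes) {
    stop("graph too sparse: only ", length(candidates),
         " genes have incoming edges; increase edge_probability or n_genes")
  }
  genes <- sample(candidates, config$n_disease_genes)
  data.frame(disease_id = disease_id, gene = genes,
             state = sample(c(-1L, 1L), config$n_disease_genes,
                            replace = TRUE),
             stringsAsFactors = FALSE)
}

# Per-node summary against the disease gene set: base contribution (sum of
# dc_sign * state * kernel over disease genes, i.e. the per-target PDOD
# numerator for an activation-like interaction), nearest informative hop,
# and directed reachability of any disease gene.
.plant_census <- function(graph, disease, alpha = 3) {
  gene_idx <- match(disease$gene, graph$nodes)
  n <- length(graph$nodes)
  base <- numeric(n)
  near_hop <- rep(Inf, n)
  reaches <- logical(n)
  for (i in seq_len(n)) {
    res <- .parity_bfs(graph, i)
    hops <- res$hop[gene_idx]
    dc <- .conflict_distance_values(hops, res$n_activation[gene_idx],
                                    res$n_inhibition[gene_idx])
    base[i] <- sum(dc_sign(dc) * disease$state * bell_kernel(dc, alpha))
    informative <- is.finite(dc)
    if (any(informative)) near_hop[i] <- min(hops[informative])
    reaches[i] <- any(is.finite(hops))
  }
  list(base = base, near_hop = near_hop, reaches = reaches)
}

#' Plant a drug panel with known ground truth
#'
#' Builds three drug classes against a disease gene set:
#' \describe{
#'   \item{therapeutic}{every target's effect type is chosen so that its
#'     summed sign-weighted kernel contribution over the disease genes is
#'     positive, with at least one informative (finite \eqn{d_c}) disease
#'     gene within `planted_hop_range`;}
#'   \item{aggravating}{targets drawn from the same pool with the effect
#'     type flipped, so contributions are negative at identical network
#'     distances — indistinguishable from therapeutic drugs once
#'     directional information is discarded;}
#'   \item{neutral}{targets that reach no disease gene at all, scoring
#'     exactly 0.}
#' }
#' Plant validity is verified post hoc with the production
#' [pdod_score()] — not assumed from construction, since background edges
#' can create conflicting parallel shortest paths; a drug whose planted
#' sign is spoiled is redrawn. Seeded from `config$seed + 2`.
#'
#' @param graph a `signed_digraph`.
#' @param disease data.frame from [generate_disease()].
#' @param config a [synthetic_config()].
#' @return list with `drugs` (data.frame `drug_id`, `drug_name`, `gene`,
#'   `effect`), `answers` (data.frame `disease_id`, `drug_id`: the
#'   therapeutic class), and `classes` (named character vector drug_id ->
#'   class).
#' @export
plant_drugs <- function(graph, disease, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  census <- .plant_census(graph, disease)
  hop_ok <- census$near_hop >= config$planted_hop_range[1] &
    census$near_hop <= config$planted_hop_range[2]
  connected_pool <- which(hop_ok & census$base != 0)
  # neutral targets must still exist in the written edge table, so
  # fully isolated nodes are not eligible
  deg <- graph_degree(graph)
  neutral_pool <- which(!census$reaches & deg > 0 &
                          !graph$nodes %in% disease$gene)

  n_th <- max(1L, round(config$planted_therapeutic_fraction * config$n_drugs))
  n_rest <- config$n_drugs - n_th
  n_ag <- ceiling(n_rest / 2)
  n_ne <- n_rest - n_ag
  if (!length(connected_pool)) {
    stop("graph too sparse to plant drugs: no gene reaches a disease gene ",
         "within hops [", config$planted_hop_range[1], ", ",
         config$planted_hop_range[2], "]; increase edge_probability, ",
         "n_genes or widen planted_hop_range")
  }
  if (n_ne > 0L && !length(neutral_pool)) {
    stop("cannot plant neutral drugs: every gene reaches a disease gene; ",
         "decrease edge_probability or increase n_genes")
  }

  classes <- rep(c("therapeutic", "aggravating", "neutral"),
                 c(n_th, n_ag, n_ne))
  rows <- list()
  labels <- character(0)
  for (k in seq_along(classes)) {
    cls <- classes[k]
    id <- sprintf("D%03d", k)
    pool <- if (cls == "neutral") neutral_pool else connected_pool
    lo <- config$targets_per_drug[1]
    hi <- config$targets_per_drug[2]
    want <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    n_t <- min(want, length(pool))
    for (attempt in 1:25) {
      tgt <- pool[sample.int(length(pool), n_t)]
      effect <- switch(cls,
                       therapeutic = ifelse(census$base[tgt] > 0, 1L, -1L),
                       aggravating = ifelse(census$base[tgt] > 0, -1L, 1L),
                       neutral = sample(c(-1L, 1L), n_t, replace = TRUE))
      drug <- data.frame(gene = graph$nodes[tgt], effect = effect,
                         stringsAsFactors = FALSE)
      s <- pdod_score(drug, disease, graph)
      ok <- switch(cls, therapeutic = s > 0, aggravating = s < 0,
                   neutral = s == 0)
      if (ok) break
      if (attempt == 25) {
        stop("failed to plant a ", cls, " drug after 25 draws; ",
             "the graph/disease combination is too conflicted — ",
             "try another seed or a denser graph")
      }
    }
    drug$drug_id <- id
    drug$drug_name <- paste0("synthetic-", cls, "-", k)
    rows[[k]] <- drug[c("drug_id", "drug_name", "gene", "effect")]
    labels[id] <- cls
  }
  drugs <- do.call(rbind, rows)
  rownames(drugs) <- NULL
  answers <- data.frame(disease_id = unique(disease$disease_id),
                        drug_id = names(labels)[labels == "therapeutic"],
                        stringsAsFactors = FALSE)
  list(drugs = drugs, answers = answers, classes = labels)
}

#' Generate a complete synthetic study
#'
#' Network, disease gene set, planted drug panel and answer set, all
#' reproducible from `config$seed` (sub-steps draw from streams seeded
#' `seed`, `seed + 1`, `seed + 2` in that order). Optionally writes the
#' fixture to disk in the exact TSV dialects the parsers consume
#' (`network.tsv`, `dti.tsv`, `disease.tsv`, `answers.tsv`) plus a
#' `manifest.json` recording the configuration.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory; created if missing.
#' @return list with `graph`, `drugs`, `disease`, `answers`, `classes`,
#'   `config`, and (if written) `files`.
#' @export
simulate_study <- function(config = synthetic_config(), dir = NULL) {
  graph <- generate_network(config)
  disease <- generate_disease(graph, config)
  planted <- plant_drugs(graph, disease, config)
  out <- list(graph = graph, drugs = planted$drugs, disease = disease,
              answers = planted$answers, classes = planted$classes,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) {
      p <- file.path(dir, f)
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    net <- data.frame(source = graph$edges$source,
                      target = graph$edges$target,
                      effect = ifelse(graph$edges$sign > 0,
                                      "activation", "inhibition"))
    dti <- data.frame(drug_id = planted$drugs$drug_id,
                      drug_name = planted$drugs$drug_name,
                      gene = planted$drugs$gene,
                      action = ifelse(planted$drugs$effect > 0,
                                      "activator", "inhibitor"))
    dis <- data.frame(disease_id = disease$disease_id, gene = disease$gene,
                      state = ifelse(disease$state > 0, "down", "up"))
    files <- c(network = wt(net, "network.tsv"),
               dti = wt(dti, "dti.tsv"),
               disease = wt(dis, "disease.tsv"),
               answers = wt(planted$answers, "answers.tsv"))
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(list(generator = "pdod::simulate_study",
                              config = unclass(config),
                              classes = as.list(planted$classes)),
                         manifest, auto_unbox = TRUE, pretty = TRUE)
    out$files <- c(files, manifest = manifest)
  }
  out
}
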