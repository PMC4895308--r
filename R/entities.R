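# Drug, disease and action-vocabulary data model plus table parsers.
#
# Drugs are represented as a long data.frame (one row per typed drug-target
# interaction: drug_id, drug_name, gene, effect) and diseases likewise
# (disease_id, gene, state). state follows the scoring convention:
# +1 = down-regulated in patients, -1 = up-regulated.

#' Drug-target action-term vocabulary
#'
#' The default vocabulary maps DrugBank-style action terms onto the two
#' effect classes used in scoring. Activation-like: activation, agonist,
#' activator, simulator (with the common spelling "stimulator" accepted as
#' a synonym), partial agonist. Inhibition-like: inhibition, inhibitor,
#' antagonist, negative modulator, inverse agonist, suppressor,
#' inhibitor (competitive), partial antagonist, reducer, blocker.
#'
#' @param activation_like,inhibition_like character vectors of action
#'   terms; must be disjoint after case-folding and trimming.
#' @return list of class `action_vocabulary`.
#' @export
action_vocabulary <- function(
    activation_like = c("activation", "agonist", "activator", "simulator",
                        "stimulator", "partial agonist"),
    inhibition_like = c("inhibition", "inhibitor", "antagonist",
                        "negative modulator", "inverse agonist",
                        "suppressor", "inhibitor (competitive)",
                        "partial antagonist", "reducer", "blocker")) {
  act <- unique(tolower(trimws(activation_like)))
  inh <- unique(tolower(trimws(inhibition_like)))
  overlap <- intersect(act, inh)
  if (length(overlap)) {
    stop("action vocabulary classes overlap: ", paste(overlap, collapse = ", "))
  }
  structure(list(activation_like = act, inhibition_like = inh),
            class = "action_vocabulary")
}

#' Classify a drug-target action term
#'
#' Case-insensitive, whitespace-trimmed lookup in an [action_vocabulary()].
#' Terms in neither class return `NA` ("unknown"); unknown is a value, not
#' an error, and rows carrying it are dropped by [load_dti_table()].
#'
#' @param term character vector of action terms.
#' @param vocab an `action_vocabulary`.
#' @return integer vector: `+1` activation-like, `-1` inhibition-like,
#'   `NA` unknown.
#' @examples
#' classify_action(c("Antagonist", "partial agonist", "binder"))
#' @export
classify_action <- function(term, vocab = action_vocabulary()) {
  stopifnot(inherits(vocab, "action_vocabulary"))
  key <- tolower(trimws(as.character(term)))
  out <- rep(NA_integer_, length(key))
  out[key %in% vocab$activation_like] <- 1L
  out[key %in% vocab$inhibition_like] <- -1L
  out
}

.require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop("table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Load a drug-target interaction table
#'
#' Reads a headered TSV with columns `drug_id`, `drug_name`, `gene`,
#' `action`, classifies every action term through the vocabulary, drops
#' rows with unknown actions (count reported via `message()` and the
#' `dropped_unknown` attribute) and excludes drugs left without any typed
#' interaction.
#'
#' @param path path to the TSV.
#' @param vocab an [action_vocabulary()].
#' @param quiet suppress the dropped-row message.
#' @return data.frame `drug_id`, `drug_name`, `gene`, `effect` (+1/-1),
#'   with attribute `dropped_unknown`.
#' @export
load_dti_table <- function(path, vocab = action_vocabulary(), quiet = FALSE) {
  if (!file.exists(path)) stop("DTI table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty DTI table: ", path)
  .require_columns(tab, c("drug_id", "drug_name", "gene", "action"), path)
  tab$effect <- classify_action(tab$action, vocab)
  dropped <- sum(is.na(tab$effect))
  if (dropped && !quiet) {
    message("load_dti_table: dropped ", dropped,
            " row(s) with unknown action terms")
  }
  tab <- tab[!is.na(tab$effect),
             c("drug_id", "drug_name", "gene", "effect")]
  tab <- unique(tab)
  rownames(tab) <- NULL
  attr(tab, "dropped_unknown") <- dropped
  tab
}

#' Load a disease gene table
#'
#' Headered TSV with columns `disease_id`, `gene`, `state` where state is
#' `up` or `down` (the direction of dysregulation in patients). States are
#' encoded for scoring as +1 = down-regulated, -1 = up-regulated: a
#' positive score then rewards drugs that push genes *against* their
#' disease alteration.
#'
#' @param path path to the TSV.
#' @return data.frame `disease_id`, `gene`, `state` (+1/-1).
#' @export
read_disease_table <- function(path) {
  if (!file.exists(path)) stop("disease table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty disease table: ", path)
  .require_columns(tab, c("disease_id", "gene", "state"), path)
  st <- tolower(trimws(tab$state))
  bad <- !st %in% c("up", "down")
  if (any(bad)) {
    stop("invalid disease gene state(s): ",
         paste(unique(tab$state[bad]), collapse = ", "),
         " (expected up/down)")
  }
  out <- data.frame(disease_id = tab$disease_id, gene = tab$gene,
                    state = ifelse(st == "down", 1L, -1L),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  dup <- duplicated(out[c("disease_id", "gene")])
  if (any(dup)) {
    stop("conflicting states for gene(s): ",
         paste(unique(out$gene[dup]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Load a therapeutic answer set table
#'
#' Headered TSV with columns `disease_id`, `drug_id` listing known
#' therapeutic drug-disease associations (the positives for AUC ranking).
#'
#' @param path path to the TSV.
#' @return data.frame `disease_id`, `drug_id`.
#' @export
read_answer_table <- function(path) {
  if (!file.exists(path)) stop("answer table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty answer table: ", path)
  .require_columns(tab, c("disease_id", "drug_id"), path)
  unique(tab[c("disease_id", "drug_id")])
}

#' Restrict drugs and diseases to a network
#'
#' Mirrors the filtering applied before scoring: drug targets absent from
#' the network are removed and drugs losing all targets are excluded;
#' disease genes absent from the network or sitting on isolated nodes
#' (total degree zero) are removed and diseases losing all genes are
#' excluded. Idempotent.
#'
#' @param drugs data.frame as from [load_dti_table()].
#' @param diseases data.frame as from [read_disease_table()].
#' @param graph a `signed_digraph`.
#' @return list with elements `drugs`, `diseases` (filtered data.frames)
#'   and `report` (named removal counts: `targets_removed`,
#'   `drugs_removed`, `genes_removed_absent`, `genes_removed_isolated`,
#'   `diseases_removed`).
#' @export
restrict_to_graph <- function(drugs, diseases, graph) {
  stopifnot(inherits(graph, "signed_digraph"))
  deg <- graph_degree(graph)
  nodes <- graph$nodes

  keep_t <- drugs$gene %in% nodes
  drugs2 <- drugs[keep_t, , drop = FALSE]
  drug_ids_before <- unique(drugs$drug_id)
  drug_ids_after <- unique(drugs2$drug_id)

  absent <- !diseases$gene %in% nodes
  isolated <- !absent & deg[diseases$gene] == 0L
  diseases2 <- diseases[!(absent | isolated), , drop = FALSE]
  dis_ids_before <- unique(diseases$disease_id)
  dis_ids_after <- unique(diseases2$disease_id)

  rownames(drugs2) <- NULL
  rownames(diseases2) <- NULL
  list(
    drugs = drugs2,
    diseases = diseases2,
    report = list(
      targets_removed = sum(!keep_t),
      drugs_removed = length(setdiff(drug_ids_before, drug_ids_after)),
      genes_removed_absent = sum(absent),
      genes_removed_isolated = sum(isolated, na.rm = TRUE),
      diseases_removed = length(setdiff(dis_ids_before, dis_ids_after))
    )
  )
}
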