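# KGML (KEGG Markup Language) ingestion restricted to gene entries and
# relations with an unambiguous effect direction.

#' Parse a KGML pathway file into signed edge records
#'
#' Extracts directed, sign-interpretable relations from a KGML document.
#' Only `entry` elements of type `gene` contribute nodes; `group` entries
#' are expanded to the genes of their member components. Of the relation
#' subtypes, only `activation`, `inhibition`, `expression` and
#' `repression` carry an obvious effect direction and yield edges; others
#' (binding/association, phosphorylation, ...) are skipped and counted.
#' Entries naming several genes fan out combinatorially: every source gene
#' is connected to every target gene. A relation annotated with more than
#' one recognised subtype emits one edge per subtype, so a simultaneous
#' activation + inhibition annotation is preserved as a parallel
#' opposite-sign edge pair rather than silently resolved.
#'
#' @param x path to a KGML file, or a KGML document as a string.
#' @return data.frame with columns `source`, `target`, `effect` (the
#'   subtype term), and attributes `skipped_subtypes` / `skipped_nongene`
#'   counting discarded relation annotations. An empty data.frame (zero
#'   rows) is valid output for a pathway without usable relations. Feed
#'   through [build_graph()] to obtain the signed graph.
#' @export
parse_kgml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e) {
    stop("malformed KGML input: ", conditionMessage(e))
  })
  entries <- xml2::xml_find_all(doc, ".//entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  entry_name <- xml2::xml_attr(entries, "name")

  genes_of <- stats::setNames(vector("list", length(entry_id)), entry_id)
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "gene")) {
      genes_of[[entry_id[i]]] <- strsplit(trimws(entry_name[i]), "\\s+")[[1]]
    }
  }
  # groups/complexes: union of member gene entries
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "group")) {
      comp <- xml2::xml_attr(
        xml2::xml_find_all(entries[[i]], "./component"), "id")
      genes_of[[entry_id[i]]] <-
        unique(unlist(genes_of[comp], use.names = FALSE))
    }
  }

  recognised <- c("activation", "inhibition", "expression", "repression")
  relations <- xml2::xml_find_all(doc, ".//relation")
  out <- list()
  skipped_subtypes <- 0L
  skipped_nongene <- 0L
  for (rel in relations) {
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"), "name")
    keep <- intersect(subtypes, recognised)
    skipped_subtypes <- skipped_subtypes + length(setdiff(subtypes, recognised))
    if (!length(keep)) next
    src <- genes_of[[xml2::xml_attr(rel, "entry1")]]
    tgt <- genes_of[[xml2::xml_attr(rel, "entry2")]]
    if (!length(src) || !length(tgt)) {
      skipped_nongene <- skipped_nongene + length(keep)
      next
    }
    for (st in keep) {
      out[[length(out) + 1L]] <-
        expand.grid(source = src, target = tgt, effect = st,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    }
  }
  edges <- if (length(out)) {
    unique(do.call(rbind, out))
  } else {
    data.frame(source = character(0), target = character(0),
               effect = character(0), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  attr(edges, "skipped_subtypes") <- skipped_subtypes
  attr(edges, "skipped_nongene") <- skipped_nongene
  edges
}
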