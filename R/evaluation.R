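# Ranking evaluation: AUC of known-therapeutic drugs versus the rest.

#' Rank-sum AUC of answer drugs
#'
#' The Mann-Whitney statistic: the probability that a randomly chosen
#' answer (known-therapeutic) drug receives a higher score than a randomly
#' chosen non-answer drug, with ties counted one half (midrank
#' averaging). Ties matter here because unreachable drugs all score
#' exactly zero.
#'
#' @param scores named numeric vector of per-drug scores (names = drug
#'   ids), or an unnamed vector aligned with `is_answer`.
#' @param answers character vector of answer drug ids, or a logical vector
#'   aligned with `scores`. Answer ids absent from `scores` are dropped
#'   with a message.
#' @return AUC in `[0, 1]`.
#' @examples
#' rank_auc(c(a = 0.9, b = 0.1, c = 0.2), "a")  # 1
#' @export
rank_auc <- function(scores, answers) {
  if (is.logical(answers)) {
    stopifnot(length(answers) == length(scores))
    is_ans <- answers
  } else {
    if (is.null(names(scores))) stop("`scores` must be named by drug id")
    known <- answers %in% names(scores)
    if (any(!known)) {
      message("rank_auc: dropping ", sum(!known),
              " answer id(s) absent from the scored drugs")
    }
    is_ans <- names(scores) %in% answers[known]
  }
  n1 <- sum(is_ans)
  n0 <- sum(!is_ans)
  if (n1 == 0L || n0 == 0L) {
    stop("degenerate answer set: need at least one answer and one ",
         "non-answer drug")
  }
  r <- rank(scores)
  (sum(r[is_ans]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-disease AUC report for a score matrix
#'
#' @param x a `pdod_scores` object from [score_all()].
#' @param answers data.frame (`disease_id`, `drug_id`) of known
#'   therapeutic associations.
#' @param methods which score columns to evaluate.
#' @param on_degenerate `"error"` or `"skip"` (warn and drop the disease)
#'   when a disease has no usable answer or non-answer drugs.
#' @return data.frame `disease_id`, `method`, `alpha`, `auc`, `n_answers`,
#'   `n_drugs`.
#' @export
auc_report <- function(x, answers, methods = c("pdod", "pdd"),
                       on_degenerate = c("error", "skip")) {
  stopifnot(inherits(x, "pdod_scores"))
  on_degenerate <- match.arg(on_degenerate)
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (did in unique(x$scores$disease_id)) {
    tab <- x$scores[x$scores$disease_id == did, , drop = FALSE]
    ans <- answers$drug_id[answers$disease_id == did]
    for (m in methods) {
      sc <- stats::setNames(tab[[m]], tab$drug_id)
      a <- tryCatch(rank_auc(sc, ans), error = function(e) e)
      if (inherits(a, "error")) {
        if (on_degenerate == "error") stop(conditionMessage(a))
        warning("skipping disease ", did, " (", m, "): ",
                conditionMessage(a))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        disease_id = did, method = m, alpha = x$alpha, auc = a,
        n_answers = sum(tab$drug_id %in% ans), n_drugs = nrow(tab),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(disease_id = character(0), method = character(0),
                      alpha = numeric(0), auc = numeric(0),
                      n_answers = integer(0), n_drugs = integer(0)))
  }
  do.call(rbind, out)
}

#' AUC across a grid of kernel half-widths
#'
#' Recomputes PDOD (and optionally PDD) scores and the per-disease AUC for
#' every value of `alpha`. Distances are computed once: only the kernel is
#' re-evaluated per alpha, so the sweep costs little more than a single
#' scoring run.
#'
#' @inheritParams score_all
#' @param answers data.frame (`disease_id`, `drug_id`).
#' @param alphas non-empty vector of positive half-widths.
#' @param methods score columns to evaluate.
#' @return data.frame `disease_id`, `method`, `alpha`, `auc`, `n_answers`,
#'   `n_drugs`, one row per (disease, method, alpha).
#' @export
alpha_sweep <- function(drugs, diseases, graph, answers,
                        alphas = c(1, 2, 3, 5), methods = c("pdod", "pdd"),
                        pdd_mode = c("undirected", "directed")) {
  if (!length(alphas)) stop("`alphas` must be non-empty")
  pdd_mode <- match.arg(pdd_mode)
  methods <- match.arg(methods, several.ok = TRUE)
  if (nrow(diseases) == 0L || nrow(drugs) == 0L) {
    return(data.frame(disease_id = character(0), method = character(0),
                      alpha = numeric(0), auc = numeric(0),
                      n_answers = integer(0), n_drugs = integer(0)))
  }
  terms <- .pair_terms(drugs, diseases, graph, pdd_mode)
  out <- list()
  for (a in alphas) {
    res <- .scores_from_terms(terms, a)
    x <- structure(list(scores = res$scores, alpha = a, pdd_mode = pdd_mode,
                        detail = NULL), class = "pdod_scores")
    out[[length(out) + 1L]] <-
      auc_report(x, answers, methods, on_degenerate = "skip")
  }
  do.call(rbind, out)
}
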