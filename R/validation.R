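# Leave-one-species-out benchmarking and the voting-vs-single-best-hit
# comparison.

#' Score assignments against truth labels
#'
#' A query is scored only when it carries truth labels. It counts as
#' correct when its assigned KO is among its true KOs. Precision is
#' `correct / assigned-and-truth-labeled` (undefined when nothing was
#' assigned); coverage is `assigned-and-truth-labeled / truth-labeled`.
#'
#' @param assignments a `ko_assignments` data.frame.
#' @param truth named list mapping query id to a character vector of
#'   true K numbers (or a two-column data.frame `query_id`, `ko`).
#' @return A list with `counts` (`truth_annotated`, `assigned`,
#'   `assigned_and_truth`, `correct`), `precision` and `coverage`.
#' @export
score_assignments <- function(assignments, truth) {
  if (is.data.frame(truth))
    truth <- split(truth$ko, truth$query_id)
  scored <- assignments[assignments$query_id %in% names(truth), ,
                        drop = FALSE]
  assigned_all <- sum(assignments$status == "assigned")
  asg <- scored[scored$status == "assigned", , drop = FALSE]
  correct <- if (nrow(asg) == 0) 0L else
    sum(mapply(function(q, k) k %in% truth[[q]],
               asg$query_id, asg$ko))
  counts <- c(truth_annotated = nrow(scored),
              assigned = assigned_all,
              assigned_and_truth = nrow(asg),
              correct = as.integer(correct))
  precision <- if (nrow(asg) > 0) correct / nrow(asg) else {
    warning("no truth-labeled query was assigned; precision undefined")
    NaN
  }
  coverage <- if (nrow(scored) > 0) nrow(asg) / nrow(scored) else NaN
  list(counts = counts, precision = precision, coverage = coverage)
}

#' Leave-one-species-out validation
#'
#' Removes one annotated species from the template set, re-annotates
#' its KO-labeled proteins by voting over the remaining templates, and
#' scores the result against the held-out species' own labels.
#'
#' @param templates list of [template_db()] objects.
#' @param held_out species code of the template to hold out.
#' @param threshold inclusive E-value ceiling (default `1e-5`).
#' @param min_votes minimum winning vote count (default 2).
#' @return A `validation_report` list: `held_out_species`, `counts`,
#'   `precision`, `coverage`, and the raw `assignments`.
#' @export
leave_one_out <- function(templates, held_out, threshold = 1e-5,
                          min_votes = 2L) {
  templates <- as_template_list(templates)
  if (!held_out %in% names(templates))
    stop("held-out species '", held_out, "' not among the templates")
  rest <- templates[names(templates) != held_out]
  if (length(rest) < 2 || length(rest) < min_votes)
    stop("need at least max(2, min_votes) remaining templates, have ",
         length(rest))
  ho <- templates[[held_out]]
  labeled <- names(ho$ko_labels)[lengths(ho$ko_labels) > 0]
  queries <- ho$records[ho$records$id %in% labeled, , drop = FALSE]
  class(queries) <- c("seq_set", "data.frame")
  attr(queries, "moltype") <- "protein"
  asg <- annotate_all(queries, rest, threshold, min_votes)
  sc <- score_assignments(asg, ho$ko_labels[labeled])
  structure(list(held_out_species = held_out, counts = sc$counts,
                 precision = sc$precision, coverage = sc$coverage,
                 assignments = asg),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Leave-one-out validation, held out:", x$held_out_species, "\n")
  cat(sprintf("  truth-labeled queries: %d\n  assigned: %d  correct: %d\n",
              x$counts[["truth_annotated"]],
              x$counts[["assigned_and_truth"]], x$counts[["correct"]]))
  cat(sprintf("  precision: %.4f\n  coverage:  %.4f\n",
              x$precision, x$coverage))
  invisible(x)
}

#' Write a validation report as TSV plus readable text
#'
#' @param report a [leave_one_out()] result.
#' @param prefix output path prefix.
#' @return The written paths, invisibly.
#' @export
write_validation_report <- function(report, prefix) {
  tsv <- paste0(prefix, ".validation.tsv")
  df <- data.frame(held_out = report$held_out_species,
                   truth_annotated = report$counts[["truth_annotated"]],
                   assigned = report$counts[["assigned"]],
                   assigned_and_truth = report$counts[["assigned_and_truth"]],
                   correct = report$counts[["correct"]],
                   precision = sprintf("%.6f", report$precision),
                   coverage = sprintf("%.6f", report$coverage))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  txt <- paste0(prefix, ".validation.txt")
  con <- file(txt, "w")
  sink(con); print(report); sink(); close(con)
  invisible(c(tsv, txt))
}

#' Compare voting against a single-best-hit baseline
#'
#' Runs (a) the voting pipeline over all templates and (b) the plain
#' best-BLAST-hit strategy against one designated template (the
#' baseline every homology-transfer annotator starts from). For the
#' baseline, a query adopts the lexicographically smallest K number of
#' its best hit's subject. Reports annotated-sequence, distinct-KO and
#' (when an index is given) pathway counts per method, plus precision
#' when truth labels are supplied.
#'
#' @inheritParams annotate_all
#' @param baseline_species species code of the single-template baseline
#'   (default: first template).
#' @param truth optional truth labels as in [score_assignments()].
#' @param index optional [build_ko_index()] for pathway counts.
#' @return A `method_comparison` data.frame with one row per method.
#' @export
compare_assigners <- function(queries, templates, threshold = 1e-5,
                              min_votes = 2L, baseline_species = NULL,
                              truth = NULL, index = NULL) {
  templates <- as_template_list(templates)
  if (length(templates) < 2) stop("need at least 2 templates")
  baseline_species <- baseline_species %||% names(templates)[1]
  if (!baseline_species %in% names(templates))
    stop("baseline species '", baseline_species, "' not among templates")

  voting <- annotate_all(queries, templates, threshold, min_votes)
  single <- single_best_hit_assign(queries, templates[[baseline_species]],
                                   threshold)
  row_for <- function(name, asg) {
    ann <- asg[asg$status == "assigned", , drop = FALSE]
    pw <- if (!is.null(index)) {
      keep <- ann$ko %in% names(index$pathways)
      length(unique(unlist(index$pathways[ann$ko[keep]],
                           use.names = FALSE)))
    } else NA_integer_
    prec <- if (!is.null(truth)) {
      suppressWarnings(score_assignments(asg, truth)$precision)
    } else NA_real_
    data.frame(method = name, annotated_sequences = nrow(ann),
               distinct_ko_terms = length(unique(ann$ko)),
               pathway_count = pw, precision = prec,
               stringsAsFactors = FALSE)
  }
  out <- rbind(row_for("voting", voting),
               row_for(paste0("single_best_hit:", baseline_species),
                       single))
  attr(out, "assignments") <- list(voting = voting, single = single)
  class(out) <- c("method_comparison", "data.frame")
  out
}

# Plain best-hit annotation against one template: the query takes the
# (lexicographically smallest) K number of its best hit's subject.
single_best_hit_assign <- function(queries, template, threshold = 1e-5) {
  if (nrow(queries) == 0) return(empty_assignments())
  best <- best_hit_search(queries, template, threshold)
  rows <- lapply(queries$id, function(q) {
    i <- match(q, best$query_id)
    ko <- NA_character_
    if (!is.na(i)) {
      labels <- template$ko_labels[[best$subject_id[i]]]
      if (length(labels) > 0) ko <- sort(labels)[1]
    }
    data.frame(query_id = q,
               status = if (is.na(ko)) "unassigned" else "assigned",
               ko = ko, vote_count = if (is.na(ko)) 0L else 1L,
               supporting_species = if (is.na(ko)) "" else
                 template$species_code,
               tie_broken = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ko_assignments", "data.frame")
  out
}
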