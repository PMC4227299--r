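# KO -> pathway mapping, reconstruction, completeness, summaries, links.

KO_RE <- "^K\\d{5}$"
PATHWAY_RE <- "^(ko|map)\\d{5}$"

#' Build a KO-to-pathway index
#'
#' The index maps each K number to a definition and a set of pathway
#' ids, and each pathway id to a title (and optional class string). It
#' can be built from a four-column TSV (`ko`, `definition`,
#' semicolon-joined pathway ids, semicolon-joined pathway titles), from
#' a set of KGML files (each contributes its ortholog entries), or
#' both; sources are unioned and deduplicated. Conflicting titles for a
#' pathway id are fatal.
#'
#' @param tsv optional path to the index TSV.
#' @param kgml_files optional character vector of KGML paths.
#' @return A `ko_index` object: list with `definition` (named
#'   character), `pathways` (named list, KO -> pathway ids), `title`
#'   and `class` (named character by pathway id).
#' @export
build_ko_index <- function(tsv = NULL, kgml_files = NULL) {
  defn <- character()
  ko2pw <- list()
  title <- character()
  pclass <- character()
  add_title <- function(pid, tt) {
    if (pid %in% names(title) && title[[pid]] != tt)
      stop("conflicting titles for pathway ", pid, ": '",
           title[[pid]], "' vs '", tt, "'")
    title[[pid]] <<- tt
  }
  if (!is.null(tsv)) {
    if (!file.exists(tsv)) stop("no such file: ", tsv)
    tab <- utils::read.table(tsv, sep = "\t", header = FALSE, quote = "",
                             colClasses = "character",
                             col.names = c("ko", "definition",
                                           "pathways", "titles"))
    bad <- tab$ko[!grepl(KO_RE, tab$ko)]
    if (length(bad) > 0)
      stop("malformed K number(s) in index: ",
           paste(unique(bad), collapse = ", "))
    for (i in seq_len(nrow(tab))) {
      ko <- tab$ko[i]
      pids <- strsplit(tab$pathways[i], ";", fixed = TRUE)[[1]]
      tts <- strsplit(tab$titles[i], ";", fixed = TRUE)[[1]]
      if (length(pids) != length(tts))
        stop("row ", i, ": pathway id and title counts differ")
      badp <- pids[!grepl(PATHWAY_RE, pids)]
      if (length(badp) > 0)
        stop("malformed pathway id(s): ", paste(badp, collapse = ", "))
      defn[[ko]] <- tab$definition[i]
      ko2pw[[ko]] <- sort(unique(c(ko2pw[[ko]], pids)))
      for (j in seq_along(pids)) add_title(pids[j], tts[j])
    }
  }
  for (f in kgml_files %||% character()) {
    p <- parse_kgml(f)
    pid <- kgml_pathway_id(p)
    add_title(pid, p$attrs[["title"]] %||% pid)
    for (e in p$entries) {
      if ((e$attrs[["type"]] %||% "") != "ortholog") next
      for (ko in entry_kos(e)) {
        if (!ko %in% names(defn)) defn[[ko]] <- ""
        ko2pw[[ko]] <- sort(unique(c(ko2pw[[ko]], pid)))
      }
    }
  }
  if (length(ko2pw) == 0)
    stop("empty KO index: no mappings found in the given sources")
  structure(list(definition = defn, pathways = ko2pw, title = title,
                 class = pclass),
            class = "ko_index")
}

#' @export
print.ko_index <- function(x, ...) {
  cat("KO index:", length(x$pathways), "K numbers,",
      length(x$title), "pathways\n")
  invisible(x)
}

# Reverse map: pathway id -> reference KO set.
pathway_kos <- function(index) {
  pairs <- data.frame(
    ko = rep(names(index$pathways), lengths(index$pathways)),
    pid = unlist(index$pathways, use.names = FALSE),
    stringsAsFactors = FALSE)
  split(pairs$ko, pairs$pid)
}

#' Reconstruct pathways from KO assignments
#'
#' A pathway appears in the reconstruction iff at least one assigned KO
#' maps to it. Completeness is the fraction of the pathway's reference
#' KO set (all KOs the index lists for it) that is present. Unassigned
#' queries are ignored; assigned KOs absent from the index are skipped
#' with a warning.
#'
#' @param assignments a `ko_assignments` data.frame.
#' @param index a [build_ko_index()] result.
#' @return A `pathway_reconstruction` data.frame with one row per
#'   pathway: `pathway_id`, `title`, `members` and `present_kos`
#'   (list-columns), `n_members`, `n_present`, `n_reference`,
#'   `completeness`.
#' @export
reconstruct_pathways <- function(assignments, index) {
  stopifnot(inherits(index, "ko_index"))
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  known <- asg$ko %in% names(index$pathways)
  if (any(!known)) {
    warning(sum(!known), " assigned KO(s) absent from the index were ",
            "skipped: ", paste(unique(asg$ko[!known]), collapse = ", "))
    asg <- asg[known, , drop = FALSE]
  }
  ref <- pathway_kos(index)
  pids <- sort(unique(unlist(index$pathways[asg$ko], use.names = FALSE)))
  rows <- lapply(pids, function(pid) {
    kos_here <- ref[[pid]]
    hit <- asg[asg$ko %in% kos_here, , drop = FALSE]
    present <- sort(unique(hit$ko))
    data.frame(pathway_id = pid,
               title = if (pid %in% names(index$title))
                 unname(index$title[pid]) else NA_character_,
               n_members = nrow(hit),
               n_present = length(present),
               n_reference = length(kos_here),
               completeness = length(present) / length(kos_here),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pathway_id = character(), title = character(),
               n_members = integer(), n_present = integer(),
               n_reference = integer(), completeness = numeric(),
               stringsAsFactors = FALSE)
  out$members <- lapply(pids, function(pid)
    sort(unique(asg$query_id[asg$ko %in% ref[[pid]]])))
  out$present_kos <- lapply(pids, function(pid)
    sort(unique(asg$ko[asg$ko %in% ref[[pid]]])))
  rownames(out) <- NULL
  class(out) <- c("pathway_reconstruction", "data.frame")
  out
}

#' Pathway completeness
#'
#' Fraction of a pathway's reference KO set observed in a species:
#' `|present KOs in reference| / |reference KOs|`. Used as a proxy for
#' the quality of an annotation or assembly.
#'
#' @param present_kos K numbers detected in the species.
#' @param reference_kos the pathway's full KO set (non-empty).
#' @return A number in `[0, 1]`.
#' @export
pathway_completeness <- function(present_kos, reference_kos) {
  if (length(reference_kos) == 0) stop("empty reference KO set")
  length(intersect(unique(present_kos), unique(reference_kos))) /
    length(unique(reference_kos))
}

#' Summarize an annotation run
#'
#' The per-species bottom line: sequences submitted, sequences with a
#' final KO, distinct K numbers, and pathways reconstructed.
#'
#' @param assignments a `ko_assignments` data.frame.
#' @param reconstruction a [reconstruct_pathways()] result.
#' @param total_sequences number of sequences submitted (defaults to
#'   the number of assignment rows).
#' @return An `annotation_summary` list with `total_sequences`,
#'   `annotated_sequences`, `distinct_ko_terms`, `pathway_count`.
#' @export
summarize_annotation <- function(assignments, reconstruction,
                                 total_sequences = nrow(assignments)) {
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (nrow(asg) > total_sequences)
    stop("more assigned sequences than total_sequences")
  structure(list(total_sequences = as.integer(total_sequences),
                 annotated_sequences = nrow(asg),
                 distinct_ko_terms = length(unique(asg$ko)),
                 pathway_count = nrow(reconstruction)),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("Sequences:          ", x$total_sequences, "\n",
      "Annotated sequences:", x$annotated_sequences, "\n",
      "Distinct KO terms:  ", x$distinct_ko_terms, "\n",
      "Pathways:           ", x$pathway_count, "\n")
  invisible(x)
}

#' KEGG map link for a pathway and its present KOs
#'
#' Deterministic URL of the form
#' `https://www.kegg.jp/kegg-bin/show_pathway?map00903+K00001+...`
#' with the K numbers sorted lexicographically. The `ko`/`map` prefix
#' of the input id is normalized to `map`, matching public KEGG link
#' behavior.
#'
#' @param pathway_id a `ko#####` or `map#####` id.
#' @param present_kos K numbers to highlight (possibly empty).
#' @return The URL string.
#' @export
map_link <- function(pathway_id, present_kos = character()) {
  if (!grepl(PATHWAY_RE, pathway_id))
    stop("invalid pathway id: ", pathway_id)
  map_id <- sub("^(ko|map)", "map", pathway_id)
  kos <- sort(unique(present_kos))
  if (length(kos) > 0 && any(!grepl(KO_RE, kos)))
    stop("invalid K number(s): ",
         paste(kos[!grepl(KO_RE, kos)], collapse = ", "))
  paste0("https://www.kegg.jp/kegg-bin/show_pathway?",
         paste(c(map_id, kos), collapse = "+"))
}

#' Write pathway reconstruction outputs
#'
#' Emits the per-pathway TSV (`<prefix>.pathways.tsv`), a short
#' human-readable pathway summary (`<prefix>.summary.txt`), a pathway
#' list (`<prefix>.pathway_list.txt`) and the KEGG map links
#' (`<prefix>.links.txt`).
#'
#' @param reconstruction a [reconstruct_pathways()] result.
#' @param summary an [summarize_annotation()] result.
#' @param prefix output path prefix.
#' @return The written paths, invisibly.
#' @export
write_pathway_outputs <- function(reconstruction, summary, prefix) {
  tsv <- paste0(prefix, ".pathways.tsv")
  out <- data.frame(
    pathway_id = reconstruction$pathway_id,
    title = reconstruction$title,
    n_members = reconstruction$n_members,
    n_present = reconstruction$n_present,
    n_reference = reconstruction$n_reference,
    completeness = sprintf("%.4f", reconstruction$completeness),
    members = vapply(reconstruction$members, paste, character(1),
                     collapse = ","),
    present_kos = vapply(reconstruction$present_kos, paste, character(1),
                         collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  sfile <- paste0(prefix, ".summary.txt")
  writeLines(c(
    paste("Total sequences:", summary$total_sequences),
    paste("Annotated sequences:", summary$annotated_sequences),
    paste("Distinct KO terms:", summary$distinct_ko_terms),
    paste("Pathways:", summary$pathway_count)), sfile)
  lfile <- paste0(prefix, ".pathway_list.txt")
  writeLines(paste(reconstruction$pathway_id, reconstruction$title,
                   sep = "\t"), lfile)
  kfile <- paste0(prefix, ".links.txt")
  links <- mapply(map_link, reconstruction$pathway_id,
                  reconstruction$present_kos)
  writeLines(paste(reconstruction$pathway_id, links, sep = "\t"), kfile)
  invisible(c(tsv, sfile, lfile, kfile))
}
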