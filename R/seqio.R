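# Sequence sets, template databases and the longest-transcript merge.

PROTEIN_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYBZXU"
NUCLEOTIDE_ALPHABET <- "ACGTURYSWKMBDHVN"

#' Construct a sequence set
#'
#' A sequence set is a plain `data.frame` (class `seq_set`) with one row
#' per record and columns `id`, `description`, `residues`, `length`, plus
#' a `moltype` attribute (`"protein"` or `"nucleotide"`). Identifiers
#' must be unique, non-empty and free of whitespace; sequences must be
#' non-empty and drawn from the IUPAC alphabet for the molecule type.
#'
#' @param id character vector of record identifiers.
#' @param residues character vector of sequences (upper- or lower-case).
#' @param description optional free-text descriptions.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return A `seq_set` data.frame.
#' @export
seq_set <- function(id, residues, description = "",
                    moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  description <- rep_len(as.character(description), length(id))
  if (length(id) != length(residues))
    stop("id and residues must have equal length")
  if (any(id == "" | is.na(id)))
    stop("sequence ids must be non-empty")
  if (any(grepl("\\s", id)))
    stop("sequence ids may not contain whitespace: ",
         id[grepl("\\s", id)][1])
  dup <- id[duplicated(id)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  empty <- id[nchar(residues) == 0]
  if (length(empty) > 0)
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "))
  alpha <- if (moltype == "protein") PROTEIN_ALPHABET else NUCLEOTIDE_ALPHABET
  bad <- regexpr(sprintf("[^%s]", alpha), residues)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("record '", id[i], "' has character '",
         substr(residues[i], bad[i], bad[i]),
         "' outside the ", moltype, " alphabet at position ", bad[i])
  }
  out <- data.frame(id = id, description = description,
                    residues = residues, length = nchar(residues),
                    stringsAsFactors = FALSE)
  attr(out, "moltype") <- moltype
  class(out) <- c("seq_set", "data.frame")
  out
}

moltype <- function(x) attr(x, "moltype") %||% "protein"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA file
#'
#' Headers are split at the first whitespace into identifier and
#' description; wrapped and CRLF-terminated lines are joined. Stop
#' characters (`*`) in protein sequences are stripped with a warning.
#' Duplicate identifiers, empty sequences, and characters outside the
#' IUPAC alphabet are fatal.
#'
#' @param path path to a FASTA file.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("cannot parse FASTA file '", path,
                                         "': ", conditionMessage(e)))
  if (length(x) == 0) stop("no sequences in FASTA file '", path, "'")
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(x))
  names(seqs) <- NULL
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  if (moltype == "protein" && any(grepl("*", seqs, fixed = TRUE))) {
    n <- sum(grepl("*", seqs, fixed = TRUE))
    warning(n, " record(s) contained '*' stop characters; stripped")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (any(nchar(seqs) == 0))
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  seq_set(ids, seqs, desc, moltype)
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 60 columns. Descriptions, when present, are
#' appended to the identifier after a single space.
#'
#' @param x a [seq_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  headers <- ifelse(x$description == "", x$id,
                    paste(x$id, x$description))
  set <- Biostrings::BStringSet(x$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Build an annotated template database
#'
#' A template database couples one reference species' protein set with a
#' sidecar table of KO labels (`seq_id<TAB>K_number`, no header). A
#' record may carry several K numbers; unlabeled records are allowed.
#'
#' @param fasta path to the species' protein FASTA.
#' @param ko_table path to the two-column KO label TSV.
#' @param species_code short identifier for the species.
#' @return A `template_db` object.
#' @export
build_template_db <- function(fasta, ko_table, species_code) {
  records <- read_fasta(fasta, "protein")
  labels <- read_ko_table(ko_table)
  template_db(species_code, records, labels)
}

read_ko_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(data.frame(id = character(), ko = character()))
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           colClasses = "character",
                           col.names = c("id", "ko"))
  bad <- tab$ko[!grepl("^K\\d{5}$", tab$ko)]
  if (length(bad) > 0)
    stop("malformed K number(s): ", paste(unique(bad), collapse = ", "))
  tab
}

#' Construct a template database from in-memory pieces
#'
#' @param species_code short species identifier.
#' @param records a protein [seq_set()].
#' @param ko_labels either a two-column data.frame (`id`, `ko`) or a
#'   named list mapping record id to a character vector of K numbers.
#' @return A `template_db` object: a list with elements `species_code`,
#'   `records` and `ko_labels` (named list, id -> K numbers).
#' @export
template_db <- function(species_code, records, ko_labels = list()) {
  stopifnot(inherits(records, "seq_set"))
  if (is.data.frame(ko_labels)) {
    orphans <- setdiff(unique(ko_labels$id), records$id)
    if (length(orphans) > 0)
      stop("KO table references id(s) absent from the FASTA: ",
           paste(orphans, collapse = ", "))
    ko_labels <- split(ko_labels$ko, factor(ko_labels$id,
                                            levels = unique(ko_labels$id)))
    ko_labels <- lapply(ko_labels, function(k) sort(unique(k)))
  } else {
    orphans <- setdiff(names(ko_labels), records$id)
    if (length(orphans) > 0)
      stop("KO labels reference id(s) absent from the records: ",
           paste(orphans, collapse = ", "))
    bad <- unlist(ko_labels)[!grepl("^K\\d{5}$", unlist(ko_labels))]
    if (length(bad) > 0)
      stop("malformed K number(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(list(species_code = species_code, records = records,
                 ko_labels = ko_labels),
            class = "template_db")
}

#' @export
print.template_db <- function(x, ...) {
  cat("Template database '", x$species_code, "': ", nrow(x$records),
      " records, ", length(x$ko_labels), " KO-labeled\n", sep = "")
  invisible(x)
}

#' Merge two gene sets by the longest-transcript rule
#'
#' Merges a KEGG-derived gene set with an official gene set (OGS).
#' Records are matched by exact identifier. When an id occurs in both
#' sets the longer sequence is kept (the KEGG copy on an exact length
#' tie, since it carries the KO annotation); ids present in only one
#' set are kept as-is.
#'
#' @param kegg_set,ogs_set two [seq_set()] objects of the same moltype.
#' @return A list of class `merged_gene_set` with elements `records`
#'   (a `seq_set`) and `provenance` (named character: `kegg_only`,
#'   `ogs_only` or `both_kept_longer` per id).
#' @export
merge_gene_sets <- function(kegg_set, ogs_set) {
  stopifnot(inherits(kegg_set, "seq_set"), inherits(ogs_set, "seq_set"))
  if (moltype(kegg_set) != moltype(ogs_set))
    stop("gene sets have different molecule types")
  ids <- c(kegg_set$id, setdiff(ogs_set$id, kegg_set$id))
  ogs_idx <- match(ids, ogs_set$id)
  kegg_idx <- match(ids, kegg_set$id)
  pick <- function(i) {
    k <- kegg_idx[i]; o <- ogs_idx[i]
    if (is.na(o)) return(list(row = kegg_set[k, ], prov = "kegg_only"))
    if (is.na(k)) return(list(row = ogs_set[o, ], prov = "ogs_only"))
    if (ogs_set$length[o] > kegg_set$length[k])
      list(row = ogs_set[o, ], prov = "both_kept_longer")
    else
      list(row = kegg_set[k, ], prov = "both_kept_longer")
  }
  picked <- lapply(seq_along(ids), pick)
  rows <- do.call(rbind, lapply(picked, `[[`, "row"))
  prov <- vapply(picked, `[[`, character(1), "prov")
  names(prov) <- ids
  records <- seq_set(rows$id, rows$residues, rows$description,
                     moltype(kegg_set))
  structure(list(records = records, provenance = prov),
            class = "merged_gene_set")
}

#' @export
print.merged_gene_set <- function(x, ...) {
  tab <- table(x$provenance)
  cat("Merged gene set:", nrow(x$records), "records (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}
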