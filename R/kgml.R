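# KGML pathway files: parse, write, and species projection.

#' Parse a KGML pathway file
#'
#' Reads a KEGG Markup Language (v0.7.x vocabulary) pathway into an
#' in-memory model. All attributes are preserved verbatim, including
#' ones this package does not interpret; unrecognized child elements of
#' the pathway are carried along as raw XML so that a parse/write cycle
#' loses nothing. Entry ids must be unique and relation/reaction
#' endpoints must reference existing entries.
#'
#' @param path path to a KGML XML file.
#' @return A `kgml_pathway` object: list with `attrs` (named character
#'   of the `<pathway>` attributes), `entries`, `relations`,
#'   `reactions` (each a list of records with their own `attrs` and
#'   nested pieces), and `extras` (raw XML of unrecognized children).
#' @export
parse_kgml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "pathway")
    stop("not a KGML file: root element is <", xml2::xml_name(doc), ">")
  attrs <- xml2::xml_attrs(doc)
  entries <- list(); relations <- list(); reactions <- list()
  extras <- character()
  for (node in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(node)
    if (nm == "entry") {
      entries[[length(entries) + 1L]] <- list(
        attrs = xml2::xml_attrs(node),
        graphics = lapply(xml2::xml_find_all(node, "graphics"),
                          xml2::xml_attrs),
        components = lapply(xml2::xml_find_all(node, "component"),
                            xml2::xml_attrs))
    } else if (nm == "relation") {
      relations[[length(relations) + 1L]] <- list(
        attrs = xml2::xml_attrs(node),
        subtypes = lapply(xml2::xml_find_all(node, "subtype"),
                          xml2::xml_attrs))
    } else if (nm == "reaction") {
      reactions[[length(reactions) + 1L]] <- list(
        attrs = xml2::xml_attrs(node),
        substrates = lapply(xml2::xml_find_all(node, "substrate"),
                            xml2::xml_attrs),
        products = lapply(xml2::xml_find_all(node, "product"),
                          xml2::xml_attrs))
    } else {
      extras <- c(extras, as.character(node))
    }
  }
  p <- structure(list(attrs = attrs, entries = entries,
                      relations = relations, reactions = reactions,
                      extras = extras),
                 class = "kgml_pathway")
  validate_kgml(p)
  p
}

validate_kgml <- function(p) {
  ids <- vapply(p$entries, function(e) e$attrs[["id"]], character(1))
  if (anyDuplicated(ids))
    stop("duplicate entry id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (r in p$relations) {
    ends <- c(r$attrs[["entry1"]], r$attrs[["entry2"]])
    miss <- setdiff(ends, ids)
    if (length(miss) > 0)
      stop("relation references missing entry id(s): ",
           paste(miss, collapse = ", "))
  }
  for (r in p$reactions) {
    rid <- r$attrs[["id"]] %||% NA_character_
    ends <- c(rid,
              vapply(r$substrates, function(s) s[["id"]], character(1)),
              vapply(r$products, function(s) s[["id"]], character(1)))
    miss <- setdiff(ends[!is.na(ends)], ids)
    if (length(miss) > 0)
      stop("reaction references missing entry id(s): ",
           paste(miss, collapse = ", "))
  }
  num <- p$attrs[["number"]] %||% ""
  if (!grepl("^\\d{5}$", num))
    stop("pathway number must be five digits, got '", num, "'")
  invisible(p)
}

#' @export
print.kgml_pathway <- function(x, ...) {
  cat("KGML pathway ", x$attrs[["name"]] %||% "?", " '",
      x$attrs[["title"]] %||% "", "': ", length(x$entries), " entries, ",
      length(x$relations), " relations, ", length(x$reactions),
      " reactions\n", sep = "")
  invisible(x)
}

#' Write a KGML pathway file
#'
#' @param p a `kgml_pathway`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(p, path) {
  stopifnot(inherits(p, "kgml_pathway"))
  root <- xml2::xml_new_root("pathway")
  xml2::xml_set_attrs(root, p$attrs)
  add_with_attrs <- function(parent, tag, attrs) {
    node <- xml2::xml_add_child(parent, tag)
    xml2::xml_set_attrs(node, attrs)
    node
  }
  for (e in p$entries) {
    node <- add_with_attrs(root, "entry", e$attrs)
    for (g in e$graphics) add_with_attrs(node, "graphics", g)
    for (cc in e$components) add_with_attrs(node, "component", cc)
  }
  for (r in p$relations) {
    node <- add_with_attrs(root, "relation", r$attrs)
    for (s in r$subtypes) add_with_attrs(node, "subtype", s)
  }
  for (r in p$reactions) {
    node <- add_with_attrs(root, "reaction", r$attrs)
    for (s in r$substrates) add_with_attrs(node, "substrate", s)
    for (s in r$products) add_with_attrs(node, "product", s)
  }
  for (x in p$extras)
    xml2::xml_add_child(root, xml2::read_xml(x))
  xml2::write_xml(root, path)
  invisible(path)
}

# Canonical form for model comparison: attribute order is irrelevant,
# element order matters.
kgml_canonical <- function(p) {
  sort_attrs <- function(a) a[order(names(a))]
  list(attrs = sort_attrs(p$attrs),
       entries = lapply(p$entries, function(e)
         list(attrs = sort_attrs(e$attrs),
              graphics = lapply(e$graphics, sort_attrs),
              components = lapply(e$components, sort_attrs))),
       relations = lapply(p$relations, function(r)
         list(attrs = sort_attrs(r$attrs),
              subtypes = lapply(r$subtypes, sort_attrs))),
       reactions = lapply(p$reactions, function(r)
         list(attrs = sort_attrs(r$attrs),
              substrates = lapply(r$substrates, sort_attrs),
              products = lapply(r$products, sort_attrs))),
       extras = p$extras)
}

#' Model equality of two KGML pathways
#'
#' Attribute order is normalized before comparison; byte-level layout
#' of the XML is irrelevant.
#'
#' @param a,b two `kgml_pathway` objects.
#' @return `TRUE` or `FALSE`.
#' @export
kgml_equal <- function(a, b) {
  identical(kgml_canonical(a), kgml_canonical(b))
}

# K numbers named by an entry ("ko:K00001 ko:K00002" -> K00001 K00002).
entry_kos <- function(e) {
  nm <- e$attrs[["name"]] %||% ""
  toks <- strsplit(nm, "\\s+")[[1]]
  sub("^ko:", "", toks[grepl("^ko:K\\d{5}$", toks)])
}

kgml_pathway_id <- function(p) {
  nm <- p$attrs[["name"]] %||% ""
  if (grepl("(ko|map)\\d{5}$", nm))
    return(regmatches(nm, regexpr("(ko|map)\\d{5}$", nm)))
  paste0("ko", p$attrs[["number"]])
}

#' Project a reference pathway onto a target species
#'
#' Keeps the ortholog (and gene) entries whose K-number set intersects
#' `present_kos` — a KEGG box listing several KOs represents
#' alternative enzymes and is kept when any one is present. Map and
#' compound entries are always kept; group entries survive while at
#' least one member does. Relations and reactions touching a dropped
#' entry are dropped. `org` is set to `species_code`; graphics are
#' copied unchanged.
#'
#' @param template a `kgml_pathway` used as the reference topology.
#' @param present_kos K numbers present in the target species.
#' @param species_code value for the projected pathway's `org`.
#' @return A new `kgml_pathway`.
#' @export
project_pathway <- function(template, present_kos, species_code) {
  stopifnot(inherits(template, "kgml_pathway"))
  keep1 <- vapply(template$entries, function(e) {
    type <- e$attrs[["type"]] %||% ""
    if (type %in% c("map", "compound")) return(TRUE)
    if (type == "group") return(NA) # decided after members
    kos <- entry_kos(e)
    length(kos) > 0 && any(kos %in% present_kos)
  }, logical(1))
  ids <- vapply(template$entries, function(e) e$attrs[["id"]],
                character(1))
  kept_ids <- ids[which(keep1 %in% TRUE)]
  # groups: keep when any component survives, and prune components
  entries <- list()
  for (i in seq_along(template$entries)) {
    e <- template$entries[[i]]
    if (is.na(keep1[i])) {
      comp <- e$components
      comp <- comp[vapply(comp, function(cc) cc[["id"]] %in% kept_ids,
                          logical(1))]
      if (length(comp) == 0) next
      e$components <- comp
    } else if (!keep1[i]) next
    entries[[length(entries) + 1L]] <- e
  }
  final_ids <- vapply(entries, function(e) e$attrs[["id"]], character(1))
  relations <- Filter(function(r)
    all(c(r$attrs[["entry1"]], r$attrs[["entry2"]]) %in% final_ids),
    template$relations)
  reactions <- Filter(function(r) {
    ends <- c(r$attrs[["id"]] %||% character(0),
              vapply(r$substrates, function(s) s[["id"]], character(1)),
              vapply(r$products, function(s) s[["id"]], character(1)))
    all(ends %in% final_ids)
  }, template$reactions)
  attrs <- template$attrs
  attrs[["org"]] <- species_code
  structure(list(attrs = attrs, entries = entries,
                 relations = relations, reactions = reactions,
                 extras = template$extras),
            class = "kgml_pathway")
}

#' Build a minimal KGML pathway from a KO set
#'
#' Used when no reference KGML topology is available: one ortholog
#' entry per present KO, no relations or reactions, simple grid
#' graphics so viewers can open the file.
#'
#' @param pathway_id a `ko#####`/`map#####` id.
#' @param title pathway title.
#' @param org species/organism code.
#' @param kos present K numbers.
#' @return A `kgml_pathway`.
#' @export
new_kgml <- function(pathway_id, title, org, kos) {
  if (!grepl(PATHWAY_RE, pathway_id))
    stop("invalid pathway id: ", pathway_id)
  number <- sub("^(ko|map)", "", pathway_id)
  kos <- sort(unique(kos))
  entries <- lapply(seq_along(kos), function(i) {
    list(attrs = c(id = as.character(i),
                   name = paste0("ko:", kos[i]),
                   type = "ortholog"),
         graphics = list(c(name = kos[i], type = "rectangle",
                           x = as.character(40 + 100 * ((i - 1) %% 8)),
                           y = as.character(40 + 40 * ((i - 1) %/% 8)),
                           width = "46", height = "17")),
         components = list())
  })
  structure(list(
    attrs = c(name = paste0("path:", pathway_id), org = org,
              number = number, title = title),
    entries = entries, relations = list(), reactions = list(),
    extras = character()),
    class = "kgml_pathway")
}
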