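#' Write orthogroups as plain text, one orthogroup per line
#'
#' Line format: `OG<7-digit index>: name1 name2 ...`, gene names
#' space-separated and sorted by species then name. Unassigned genes go to a
#' companion file, one name per line.
#'
#' @param partition Partition tibble.
#' @param catalog Sequence catalogue.
#' @param path Output path for the orthogroups file.
#' @param unassigned_path Optional path for the unassigned-genes file.
#' @return `path`, invisibly.
#' @export
write_plain_text <- function(partition, catalog, path, unassigned_path = NULL) {
  pg <- partition_groups(partition)
  lines <- character(length(pg$groups))
  for (k in seq_along(pg$groups)) {
    genes <- pg$groups[[k]]
    idx <- match(genes, catalog$gene_id)
    ord <- order(catalog$species_id[idx], catalog$external_name[idx])
    lines[k] <- sprintf(
      "OG%07d: %s", k - 1L,
      paste(catalog$external_name[idx][ord], collapse = " ")
    )
  }
  writeLines(lines, path)
  if (!is.null(unassigned_path)) {
    idx <- match(pg$unassigned, catalog$gene_id)
    ord <- order(catalog$species_id[idx], catalog$external_name[idx])
    writeLines(catalog$external_name[idx][ord], unassigned_path)
  }
  invisible(path)
}

#' Read a plain-text orthogroup file into a partition
#'
#' Accepts the dialect of [write_plain_text()] and OrthoMCL-style
#' `GROUP: member member ...` lines (members separated by any whitespace).
#' Groups listing a single gene are treated as unassigned; catalogue genes not
#' listed anywhere are unassigned.
#'
#' @param path Path to the file (or raw `lines`).
#' @param catalog Sequence catalogue.
#' @param lines Optional character vector of lines instead of `path`.
#' @return Partition tibble over all catalogue genes.
#' @export
read_partition <- function(path = NULL, catalog, lines = NULL) {
  if (is.null(lines)) {
    lines <- readLines(path)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  seen <- character(0)
  clusters <- list()
  for (ln in lines) {
    body <- sub("^[^:]*:", "", ln)
    members <- strsplit(trimws(body), "\\s+")[[1]]
    members <- members[nzchar(members)]
    if (length(members) == 0) next
    ids <- match(members, catalog$external_name)
    if (anyNA(ids)) {
      stop(sprintf(
        "unknown gene name(s) in orthogroup file: %s",
        paste(members[is.na(ids)], collapse = ", ")
      ))
    }
    dup <- intersect(members, seen)
    if (length(dup) > 0 || anyDuplicated(members)) {
      dupnames <- unique(c(dup, members[duplicated(members)]))
      stop(sprintf("gene(s) assigned to more than one orthogroup: %s", paste(dupnames, collapse = ", ")))
    }
    seen <- c(seen, members)
    if (length(members) >= 2) {
      clusters[[length(clusters) + 1L]] <- catalog$gene_id[ids]
    }
  }
  new_partition(clusters, catalog)
}

#' Write a partition as OrthoXML
#'
#' Emits an OrthoXML 0.3 document: one `species` element per input proteome
#' (each with a `database`/`genes` block mapping internal integer gene ids to
#' external protein identifiers) and one `orthologGroup` per orthogroup.
#' XML-reserved characters in names are escaped by the writer.
#'
#' @param partition Partition tibble.
#' @param catalog Sequence catalogue.
#' @param path Output path.
#' @param origin,origin_version Strings recorded in the document header.
#' @return `path`, invisibly.
#' @export
write_orthoxml <- function(partition, catalog, path,
                           origin = "orthokit",
                           origin_version = as.character(utils::packageVersion("orthokit"))) {
  doc <- xml2::xml_new_root(
    "orthoXML",
    xmlns = "http://orthoXML.org/2011/",
    version = "0.3",
    origin = origin,
    originVersion = origin_version
  )
  for (sp in sort(unique(catalog$species_id))) {
    sub <- catalog[catalog$species_id == sp, ]
    sp_node <- xml2::xml_add_child(doc, "species",
      name = sub$species_name[1], NCBITaxId = as.character(sp)
    )
    db_node <- xml2::xml_add_child(sp_node, "database",
      name = origin, version = origin_version
    )
    genes_node <- xml2::xml_add_child(db_node, "genes")
    for (r in seq_len(nrow(sub))) {
      xml2::xml_add_child(genes_node, "gene",
        id = as.character(sub$gene_id[r]),
        protId = sub$external_name[r]
      )
    }
  }
  groups_node <- xml2::xml_add_child(doc, "groups")
  pg <- partition_groups(partition)
  for (k in seq_along(pg$groups)) {
    og <- xml2::xml_add_child(groups_node, "orthologGroup", id = sprintf("OG%07d", k - 1L))
    for (g in pg$groups[[k]]) {
      xml2::xml_add_child(og, "geneRef", id = as.character(g))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an OrthoXML file back into a partition
#'
#' @param path Path to an OrthoXML document.
#' @param catalog Sequence catalogue; geneRefs are matched to catalogue genes
#'   via the document's own gene id -> protId mapping.
#' @return Partition tibble.
#' @export
read_orthoxml <- function(path, catalog) {
  doc <- xml2::read_xml(path)
  ns <- c(o = "http://orthoXML.org/2011/")
  gene_nodes <- xml2::xml_find_all(doc, ".//o:gene", ns)
  id_map <- stats::setNames(
    xml2::xml_attr(gene_nodes, "protId"),
    xml2::xml_attr(gene_nodes, "id")
  )
  groups <- xml2::xml_find_all(doc, ".//o:groups/o:orthologGroup", ns)
  clusters <- lapply(groups, function(g) {
    refs <- xml2::xml_attr(xml2::xml_find_all(g, "./o:geneRef", ns), "id")
    prot <- unname(id_map[refs])
    ids <- catalog$gene_id[match(prot, catalog$external_name)]
    if (anyNA(ids)) {
      stop("OrthoXML geneRef resolves to a protein absent from the catalogue")
    }
    ids
  })
  new_partition(clusters, catalog)
}

#' Structural validity check for an OrthoXML document
#'
#' Enforces the structural constraints of the OrthoXML 0.3 schema: correct
#' root element, namespace and version; at least one `species`, each with a
#' `database`/`genes`/`gene` chain; unique gene ids; every `geneRef`
#' resolving to a declared gene; every `orthologGroup` holding at least two
#' members. Returns `TRUE` or stops with the accumulated problems.
#'
#' @param path Path to the document.
#' @return `TRUE` (invisibly) when the document passes.
#' @export
orthoxml_check <- function(path) {
  doc <- xml2::read_xml(path)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (xml2::xml_name(doc) != "orthoXML") note("root element is not <orthoXML>")
  ns_uri <- xml2::xml_ns(doc)
  if (!any(grepl("orthoXML.org", unlist(ns_uri), fixed = TRUE))) {
    note("missing orthoXML namespace")
  }
  if (!identical(xml2::xml_attr(doc, "version"), "0.3")) note("version attribute is not 0.3")
  if (is.na(xml2::xml_attr(doc, "origin"))) note("missing origin attribute")
  ns <- c(o = "http://orthoXML.org/2011/")
  species <- xml2::xml_find_all(doc, "./o:species", ns)
  if (length(species) == 0) note("no species elements")
  for (sp in species) {
    if (is.na(xml2::xml_attr(sp, "name"))) note("species without name attribute")
    if (is.na(xml2::xml_attr(sp, "NCBITaxId"))) note("species without NCBITaxId attribute")
    if (length(xml2::xml_find_all(sp, "./o:database/o:genes/o:gene", ns)) == 0) {
      note(sprintf("species '%s' declares no genes", xml2::xml_attr(sp, "name")))
    }
  }
  gene_nodes <- xml2::xml_find_all(doc, ".//o:gene", ns)
  gene_ids <- xml2::xml_attr(gene_nodes, "id")
  if (anyNA(gene_ids) || anyNA(suppressWarnings(as.integer(gene_ids)))) {
    note("gene elements must carry integer id attributes")
  }
  if (anyDuplicated(gene_ids)) note("duplicate gene ids")
  groups <- xml2::xml_find_all(doc, "./o:groups/o:orthologGroup", ns)
  for (g in groups) {
    refs <- xml2::xml_attr(xml2::xml_find_all(g, "./o:geneRef", ns), "id")
    if (length(refs) < 2) note("orthologGroup with fewer than 2 members")
    if (!all(refs %in% gene_ids)) note("geneRef id not declared as a gene")
  }
  all_refs <- xml2::xml_attr(xml2::xml_find_all(doc, ".//o:geneRef", ns), "id")
  if (anyDuplicated(all_refs)) note("gene referenced by more than one orthologGroup")
  if (length(problems) > 0) {
    stop(sprintf("OrthoXML structural check failed:\n- %s", paste(problems, collapse = "\n- ")))
  }
  invisible(TRUE)
}
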