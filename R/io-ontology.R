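#' Read a Gene Ontology DAG from an OBO file
#'
#' Parses the `[Term]` stanzas of an OBO 1.2/1.4 file, keeping the fields the
#' semantic similarity computation needs: term id, name, namespace, obsolete
#' flag, and `is_a` / `relationship: part_of` parent edges. Namespaces are
#' abbreviated to BP/MF/CC. The graph must be acyclic.
#'
#' @param path path to the OBO file.
#' @return an object of class `"ontology_dag"`: a list with `terms` (data
#'   frame: id, name, namespace, obsolete) and `edges` (data frame: child,
#'   parent, relation).
#' @export
read_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stopf("no [Term] stanzas found in '%s'", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(); nms <- character(); ns <- character(); obs <- logical()
  children <- character(); parents <- character(); rels <- character()
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  for (k in seq_along(starts)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]  # stop fields from a following stanza type
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ": "), block, value = TRUE)
      if (length(hit)) sub(paste0("^", key, ": "), "", hit[1L]) else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    nm1 <- get1("name")
    nms <- c(nms, if (is.na(nm1)) id else nm1)
    raw_ns <- get1("namespace")
    ns <- c(ns, if (!is.na(raw_ns) && raw_ns %in% names(ns_map)) ns_map[[raw_ns]]
              else if (!is.na(raw_ns)) raw_ns else NA_character_)
    obs <- c(obs, identical(get1("is_obsolete"), "true"))
    isa <- grep("^is_a: ", block, value = TRUE)
    for (x in isa) {
      tgt <- sub("^is_a: *([^ !]+).*$", "\\1", x)
      children <- c(children, id); parents <- c(parents, tgt)
      rels <- c(rels, "is_a")
    }
    rel <- grep("^relationship: part_of ", block, value = TRUE)
    for (x in rel) {
      tgt <- sub("^relationship: part_of *([^ !]+).*$", "\\1", x)
      children <- c(children, id); parents <- c(parents, tgt)
      rels <- c(rels, "part_of")
    }
  }
  if (anyDuplicated(ids))
    stopf("duplicate term id(s) in OBO: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keep <- parents %in% ids & children %in% ids
  edges <- data.frame(child = children[keep], parent = parents[keep],
                      relation = rels[keep], stringsAsFactors = FALSE)
  dag <- ontology_dag(data.frame(id = ids, name = nms, namespace = ns,
                                 obsolete = obs, stringsAsFactors = FALSE),
                      edges)
  dag
}

#' Construct an ontology DAG from term and edge tables
#'
#' @param terms data frame with columns id, name, namespace (BP/MF/CC),
#'   obsolete (logical).
#' @param edges data frame with columns child, parent, relation
#'   (`"is_a"` or `"part_of"`).
#' @return class `"ontology_dag"`; errors if the edge graph contains a cycle.
#' @export
ontology_dag <- function(terms, edges) {
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) stopf("ontology graph contains a cycle")
  }
  # child -> list of (parent, relation), the form the S-value walk consumes
  parent_idx <- split(seq_len(nrow(edges)), edges$child)
  structure(list(terms = terms, edges = edges, parent_idx = parent_idx),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms,", nrow(x$edges), "edges;",
      "namespaces:", paste(sort(unique(x$terms$namespace)), collapse = "/"),
      "\n")
  invisible(x)
}

term_namespace <- function(dag, term) {
  i <- match(term, dag$terms$id)
  if (is.na(i)) stopf("unknown ontology term '%s'", term)
  dag$terms$namespace[i]
}

#' Read gene annotations from a GAF 2.x file
#'
#' Lines starting with `!` are comments. Column 2 is taken as the gene
#' identifier, column 4 the qualifier, column 5 the ontology term, and column
#' 9 the aspect (P/F/C, mapped to BP/MF/CC). Rows whose qualifier contains
#' `NOT`, whose term is absent from the DAG, or whose term is obsolete are
#' dropped (counts reported via a message).
#'
#' @param path path to the GAF file.
#' @param dag an [ontology_dag()].
#' @param exclude_iea drop annotations with evidence code IEA (column 7).
#' @return class `"annotation_map"`: list with elements BP, MF, CC, each a
#'   named list mapping gene id -> character vector of term ids.
#' @export
read_annotations <- function(path, dag, exclude_iea = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) stopf("GAF file '%s' has no annotation rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 15L))
    stopf("GAF line %d has fewer than 15 columns",
          which(lengths(fields) < 15L)[1L])
  gene <- vapply(fields, `[[`, "", 2L)
  qual <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  evid <- vapply(fields, `[[`, "", 7L)
  aspect <- vapply(fields, `[[`, "", 9L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  if (exclude_iea) keep <- keep & evid != "IEA"
  known <- term %in% dag$terms$id[!dag$terms$obsolete]
  n_unknown <- sum(keep & !known)
  if (n_unknown)
    message("read_annotations: dropped ", n_unknown,
            " annotation(s) to unknown or obsolete terms")
  keep <- keep & known
  ns <- c(P = "BP", F = "MF", C = "CC")[aspect]
  keep <- keep & !is.na(ns)
  ann <- list(BP = list(), MF = list(), CC = list())
  for (space in c("BP", "MF", "CC")) {
    sel <- keep & ns == space
    if (any(sel))
      ann[[space]] <- lapply(split(term[sel], gene[sel]), unique)
  }
  structure(ann, class = "annotation_map")
}

#' Write an ontology DAG as a minimal OBO file
#' @param dag an [ontology_dag()].
#' @param path output path.
#' @export
write_ontology <- function(dag, path) {
  ns_map <- c(BP = "biological_process", MF = "molecular_function",
              CC = "cellular_component")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", dag$terms$name[i]),
             paste0("namespace: ", ns_map[[dag$terms$namespace[i]]]))
    if (dag$terms$obsolete[i]) out <- c(out, "is_obsolete: true")
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[j] == "is_a")
        paste0("is_a: ", e$parent[j])
        else paste0("relationship: part_of ", e$parent[j]))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Write an annotation map as a minimal GAF 2.2 file
#' @param ann an `annotation_map`.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  aspect_map <- c(BP = "P", MF = "F", CC = "C")
  rows <- character()
  for (space in c("BP", "MF", "CC")) {
    genes <- names(ann[[space]])
    for (g in genes) {
      for (t in ann[[space]][[g]]) {
        rows <- c(rows, paste(c("SYN", g, g, "", t, "SYN:ref", "IEA", "",
                                aspect_map[[space]], g, "", "protein",
                                "taxon:9606", "20260101", "SYN", "", ""),
                              collapse = "\t"))
      }
    }
  }
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}
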