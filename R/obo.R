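# OBO 1.2/1.4 reader and writer for the is_a fragment of a chemical
# ontology. Only the tags the subsumption pipeline needs are interpreted:
# id, name, is_a, is_obsolete and the property_value (or synonym key)
# carrying the SMILES annotation. ChEBI stores SMILES as
#   property_value: http://purl.obolibrary.org/obo/chebi/smiles "..." xsd:string

#' OBO dialect configuration
#'
#' Where in the OBO file the SMILES annotation lives. ChEBI uses a
#' property_value whose key is the chebi/smiles IRI; the default also accepts
#' a bare \code{smiles} key so toy files stay readable.
#'
#' @param smilesKeys character vector of accepted property_value keys; a key
#'   matches if it equals the property key or is its trailing path segment.
#' @return a named list
#' @export
oboDialect <- function(smilesKeys = c("http://purl.obolibrary.org/obo/chebi/smiles",
                                      "smiles")) {
  list(smilesKeys = smilesKeys)
}

.matchesSmilesKey <- function(key, dialect) {
  key %in% dialect$smilesKeys ||
    sub(".*/", "", key) %in% sub(".*/", "", dialect$smilesKeys)
}

#' Load an ontology from an OBO file
#'
#' Parses \code{[Term]} stanzas into an [OntologyGraph-class]: obsolete terms
#' are dropped entirely, only is_a edges are retained (parthood and other
#' relationship types do not define the subsumption order here), and SMILES
#' annotations are read from the property configured in \code{dialect}.
#' Acyclicity is verified on load. Edges pointing at terms that were dropped
#' (or never declared) are removed with a warning.
#'
#' @param path path to an OBO 1.2/1.4 file
#' @param dialect an [oboDialect()] list
#' @return an [OntologyGraph-class]
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: X:1", "name: root",
#'   "", "[Term]", "id: X:2", "name: ethanol", "is_a: X:1",
#'   "property_value: smiles \"CCO\" xsd:string"), obo)
#' loadOBO(obo)
#' @export
loadOBO <- function(path, dialect = oboDialect()) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  inTerm <- FALSE
  inOtherStanza <- FALSE
  flush <- function() {
    if (!is.null(cur)) {
      if (is.null(cur$id)) stop("OBO format error: [Term] without id near line ", cur$line)
      terms[[length(terms) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    line <- sub("\\s+$", "", raw)
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      flush()
      if (identical(line, "[Term]")) {
        inTerm <- TRUE; inOtherStanza <- FALSE
        cur <- list(line = ln, parents = character(), obsolete = FALSE,
                    smiles = NA_character_, name = NA_character_)
      } else if (grepl("^\\[[A-Za-z]+\\]$", line)) {
        inTerm <- FALSE; inOtherStanza <- TRUE
      } else {
        stop("OBO format error at line ", ln, ": malformed stanza header '", line, "'")
      }
      next
    }
    if (!inTerm) {
      if (!inOtherStanza && !grepl("^[A-Za-z_-]+\\s*:", line))
        stop("OBO format error at line ", ln, ": expected 'tag: value', got '", line, "'")
      next  # header or non-Term stanza content
    }
    m <- regmatches(line, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m) < 3L)
      stop("OBO format error at line ", ln, ": expected 'tag: value', got '", line, "'")
    tag <- m[2]; value <- m[3]
    value <- sub("\\s*!.*$", "", value)       # trailing comment
    if (tag == "id") {
      cur$id <- value
    } else if (tag == "name") {
      cur$name <- value
    } else if (tag == "is_a") {
      cur$parents <- c(cur$parents, sub("\\s.*$", "", value))
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(tolower(value), "true")
    } else if (tag == "property_value") {
      pv <- regmatches(value, regexec("^(\\S+)\\s+\"((?:[^\"\\\\]|\\\\.)*)\"", value))[[1]]
      if (length(pv) == 3L && .matchesSmilesKey(pv[2], dialect)) {
        cur$smiles <- gsub("\\\\(.)", "\\1", pv[3])
      }
    }
  }
  flush()
  obsolete <- vapply(terms, `[[`, logical(1), "obsolete")
  terms <- terms[!obsolete]
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("OBO format error: duplicate term id ",
                               ids[duplicated(ids)][1])
  parents <- lapply(terms, function(t) unique(t$parents))
  known <- lapply(parents, function(p) p[p %in% ids])
  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling))
    warning("dropping is_a edges to missing or obsolete terms: ",
            paste(head(dangling, 5L), collapse = ", "))
  g <- OntologyGraph(
    ids = ids,
    classNames = vapply(terms, function(t) if (is.na(t$name)) t$id else t$name, character(1)),
    smiles = vapply(terms, `[[`, character(1), "smiles"),
    parents = known,
    metadata = list(source = path)
  )
  g
}

#' Write an ontology (or fragment) as OBO
#'
#' @param graph an [OntologyGraph-class]
#' @param path output file path
#' @param dialect an [oboDialect()]; the first smilesKey is used for
#'   emitted SMILES property_value lines
#' @return \code{path}, invisibly
#' @export
writeOBO <- function(graph, path, dialect = oboDialect()) {
  key <- dialect$smilesKeys[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_along(graph@ids)) {
    out <- c("[Term]",
             paste0("id: ", graph@ids[i]),
             paste0("name: ", graph@classNames[i]))
    for (p in graph@parents[[i]]) out <- c(out, paste0("is_a: ", p))
    if (!is.na(graph@smiles[i]))
      out <- c(out, paste0("property_value: ", key, " \"",
                           gsub("([\"\\\\])", "\\\\\\1", graph@smiles[i]),
                           "\" xsd:string"))
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Export an ontology fragment as a JSON node/edge list
#'
#' @param graph an [OntologyGraph-class]
#' @param path output JSON path
#' @return \code{path}, invisibly
#' @export
writeFragmentJSON <- function(graph, path) {
  nodes <- data.frame(id = graph@ids, name = graph@classNames,
                      smiles = graph@smiles, stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(seq_along(graph@ids), function(i) {
    if (length(graph@parents[[i]]))
      data.frame(child = graph@ids[i], parent = graph@parents[[i]],
                 stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(child = character(), parent = character())
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       dataframe = "rows", na = "null", auto_unbox = TRUE)
  invisible(path)
}
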