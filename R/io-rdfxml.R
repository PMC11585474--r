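# RDF/XML reader and writer for the BioPAX subset.
#
# Reading handles the striped RDF/XML that BioPAX exporters emit: typed node
# elements with rdf:about / rdf:ID, property elements with rdf:resource,
# nested node elements, and text literals with rdf:datatype / xml:lang.
# Blank nodes (missing identifier or rdf:nodeID) are skolemized to stable
# urn:skolem: IRIs in document order so that graphs always compare as plain
# triple sets. Writing is deterministic string assembly: identical graphs
# serialize byte-identically.

.is_absolute_iri <- function(x) grepl("^[A-Za-z][A-Za-z0-9+.\\-]*:", x)

.resolve_ref <- function(ref, base) {
  if (.is_absolute_iri(ref)) return(ref)
  if (startsWith(ref, "#")) return(paste0(base, ref))
  if (ref == "") return(base)
  paste0(base, "#", ref)
}

#' Read a BioPAX Level 3 document
#'
#' Parses an RDF/XML BioPAX document (the canonical serialization used by
#' Reactome and PathwayCommons exports) into a [biopax_graph()]. Files whose
#' name ends in `.ttl` are read with the bundled Turtle subset reader
#' instead.
#'
#' @param path Path to the document.
#' @param base Base IRI used to resolve `rdf:ID` and relative `rdf:about`
#'   references when the document declares no `xml:base`.
#' @return A [biopax_graph()].
#' @seealso [write_biopax()]
#' @export
read_biopax <- function(path, base = "http://biopax.example/base") {
  if (!file.exists(path)) {
    abort(paste0("Cannot read BioPAX document: no such file: ", path))
  }
  if (grepl("\\.ttl$", path, ignore.case = TRUE)) {
    return(read_biopax_turtle(path))
  }
  doc <- tryCatch(
    suppressWarnings(xml2::read_xml(path)),
    error = function(e) {
      abort(paste0("Malformed RDF/XML in ", path, ": ", conditionMessage(e)))
    }
  )
  root <- xml2::xml_root(doc)
  ns_map <- tryCatch(xml2::xml_ns(doc), error = function(e) character())
  ns_vec <- stats::setNames(as.character(ns_map), names(ns_map))

  rdf_prefix <- names(ns_vec)[ns_vec == RDF_NS][1]
  if (is.na(rdf_prefix)) {
    abort(paste0("Not an RDF/XML document (no RDF namespace declared): ", path))
  }
  # namespace map for attribute lookup; the xml: prefix is implicit in XML
  # and absent from the document's declarations
  attr_ns <- ns_vec
  if (!"http://www.w3.org/XML/1998/namespace" %in% attr_ns) {
    attr_ns <- c(attr_ns, xml = "http://www.w3.org/XML/1998/namespace")
  }
  root_attrs <- xml2::xml_attrs(root)
  xb <- root_attrs[intersect(c("xml:base", "base"), names(root_attrs))]
  if (length(xb) > 0) base <- sub("#$", "", unname(xb[1]))

  state <- new.env(parent = emptyenv())
  state$rows <- vector("list", 256L)
  state$n <- 0L
  state$bnode <- 0L

  add_triple <- function(s, p, o, lit = FALSE, dt = NA_character_,
                         lang = NA_character_) {
    # force arguments before touching the counter: evaluating a nested node
    # element as the object recursively appends triples of its own
    row <- list(s, p, o, lit, dt, lang)
    state$n <- state$n + 1L
    if (state$n > length(state$rows)) {
      length(state$rows) <- 2L * length(state$rows)
    }
    state$rows[[state$n]] <- row
  }

  el_iri <- function(el) {
    qn <- xml2::xml_name(el, ns = ns_map)
    if (grepl(":", qn, fixed = TRUE)) {
      parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
      paste0(ns_vec[[parts[1]]], parts[2])
    } else {
      qn
    }
  }

  node_subject <- function(el) {
    attrs <- xml2::xml_attrs(el, ns = attr_ns)
    about <- attrs[paste0(rdf_prefix, ":about")]
    id <- attrs[paste0(rdf_prefix, ":ID")]
    node_id <- attrs[paste0(rdf_prefix, ":nodeID")]
    if (!is.na(about)) return(.resolve_ref(unname(about), base))
    if (!is.na(id)) return(paste0(base, "#", unname(id)))
    if (!is.na(node_id)) return(paste0("urn:skolem:nodeid-", unname(node_id)))
    state$bnode <- state$bnode + 1L
    paste0("urn:skolem:b", state$bnode)
  }

  parse_node <- function(el) {
    subject <- node_subject(el)
    type_iri <- el_iri(el)
    if (type_iri != paste0(RDF_NS, "Description")) {
      add_triple(subject, RDF_TYPE, type_iri)
    }
    for (child in xml2::xml_children(el)) {
      pred <- el_iri(child)
      attrs <- xml2::xml_attrs(child, ns = attr_ns)
      res <- attrs[paste0(rdf_prefix, ":resource")]
      node_id <- attrs[paste0(rdf_prefix, ":nodeID")]
      kids <- xml2::xml_children(child)
      if (!is.na(res)) {
        add_triple(subject, pred, .resolve_ref(unname(res), base))
      } else if (!is.na(node_id)) {
        add_triple(subject, pred, paste0("urn:skolem:nodeid-", unname(node_id)))
      } else if (length(kids) > 0) {
        add_triple(subject, pred, parse_node(kids[[1]]))
      } else {
        dt <- attrs[paste0(rdf_prefix, ":datatype")]
        lang <- attrs["xml:lang"]
        add_triple(subject, pred, xml2::xml_text(child), lit = TRUE,
                   dt = unname(dt) %||% NA_character_,
                   lang = unname(lang) %||% NA_character_)
      }
    }
    subject
  }

  for (el in xml2::xml_children(root)) parse_node(el)

  rows <- state$rows[seq_len(state$n)]
  tr <- if (length(rows) == 0) {
    .empty_triples()
  } else {
    rdf_triples(
      subject = vapply(rows, function(r) r[[1]], ""),
      predicate = vapply(rows, function(r) r[[2]], ""),
      object = vapply(rows, function(r) r[[3]], ""),
      object_is_literal = vapply(rows, function(r) r[[4]], TRUE),
      datatype = vapply(rows, function(r) ifelse(is.na(r[[5]]), NA_character_,
                                                 r[[5]]), ""),
      lang = vapply(rows, function(r) ifelse(is.na(r[[6]]), NA_character_,
                                             r[[6]]), "")
    )
  }

  extra_ns <- ns_vec[!names(ns_vec) %in% names(DEFAULT_NAMESPACES)]
  g <- biopax_graph(tr, namespaces = extra_ns, check_vocabulary = FALSE)
  validate_biopax_graph(g, on_unknown_predicate = "warn")
  g
}

.xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.xml_escape_attr <- function(x) {
  gsub("\"", "&quot;", .xml_escape_text(x), fixed = TRUE)
}

.is_ncname <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_.\\-]*$", x)

# Split an IRI into (namespace, local name) at the last '#' or '/'.
.split_iri <- function(iri) {
  pos <- regexpr("[#/][^#/]*$", iri)
  if (pos < 0) return(NULL)
  local <- substring(iri, pos + 1L)
  if (!.is_ncname(local)) return(NULL)
  list(ns = substring(iri, 1L, pos), local = local)
}

#' Write a graph as RDF/XML
#'
#' Serializes a [biopax_graph()] to RDF/XML deterministically: subjects,
#' predicates and objects are emitted in sorted order, so identical graphs
#' produce byte-identical documents, and [read_biopax()] on the output
#' recovers the identical triple set.
#'
#' @param graph A [biopax_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_biopax <- function(graph, path) {
  tr <- graph$triples
  ns <- graph$namespaces

  # Predicates and node-element types must be QName-able; mint prefixes for
  # namespaces the table does not cover yet (deterministically, sorted).
  needed <- unique(c(tr$predicate, tr$object[tr$predicate == RDF_TYPE &
                                               !tr$object_is_literal]))
  extra <- character()
  for (iri in sort(needed)) {
    parts <- .split_iri(iri)
    if (is.null(parts)) {
      abort(paste0("Cannot form an XML QName for IRI: ", iri))
    }
    if (!parts$ns %in% c(ns, extra)) extra <- c(extra, parts$ns)
  }
  if (length(extra) > 0) {
    names(extra) <- paste0("ns", seq_along(extra))
    ns <- c(ns, extra)
  }

  qname <- function(iri) {
    parts <- .split_iri(iri)
    pfx <- names(ns)[ns == parts$ns][1]
    paste0(pfx, ":", parts$local)
  }

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<rdf:RDF",
           paste0("\n  xmlns:", names(ns), "=\"", .xml_escape_attr(unname(ns)),
                  "\"", collapse = ""),
           ">")
  )

  for (subj in sort(unique(tr$subject))) {
    rows <- tr[tr$subject == subj, , drop = FALSE]
    is_type <- rows$predicate == RDF_TYPE & !rows$object_is_literal
    types <- sort(rows$object[is_type])
    el <- if (length(types) > 0) qname(types[1]) else "rdf:Description"
    out <- c(out, paste0("  <", el, " rdf:about=\"",
                         .xml_escape_attr(subj), "\">"))
    for (extra_type in types[-1]) {
      out <- c(out, paste0("    <rdf:type rdf:resource=\"",
                           .xml_escape_attr(extra_type), "\"/>"))
    }
    props <- rows[!is_type, , drop = FALSE]
    props <- props[order(props$predicate, props$object, method = "radix"), ,
                   drop = FALSE]
    for (i in seq_len(nrow(props))) {
      p <- qname(props$predicate[i])
      if (props$object_is_literal[i]) {
        dt <- props$datatype[i]
        lang <- props$lang[i]
        attrs <- ""
        if (!is.na(dt)) {
          attrs <- paste0(attrs, " rdf:datatype=\"", .xml_escape_attr(dt), "\"")
        }
        if (!is.na(lang)) {
          attrs <- paste0(attrs, " xml:lang=\"", .xml_escape_attr(lang), "\"")
        }
        out <- c(out, paste0("    <", p, attrs, ">",
                             .xml_escape_text(props$object[i]), "</", p, ">"))
      } else {
        out <- c(out, paste0("    <", p, " rdf:resource=\"",
                             .xml_escape_attr(props$object[i]), "\"/>"))
      }
    }
    out <- c(out, paste0("  </", el, ">"))
  }

  out <- c(out, "</rdf:RDF>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
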