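#' Export a process diagram as GraphML
#'
#' Writes the bipartite graph with typed keys: node kind, display label,
#' composition key, per-molecule site lists, rule id/ordinal/reversible
#' flag, arc kind, stoichiometry and the level-dependent site/context
#' labels as `;`-joined strings. The document is self-contained:
#' [read_graphml()] reconstructs an equal `mpd_graph`. Node coordinates
#' from a layout are attached as numeric keys when `graphics = TRUE`.
#'
#' @param graph an `mpd_graph`.
#' @param layout optional layout from [mpd_layout()].
#' @param graphics attach x/y/w/h node keys (requires `layout`).
#' @param file optional output path.
#' @return an `xml_document` (invisibly when `file` is given).
#' @export
to_graphml <- function(graph, layout = NULL, graphics = !is.null(layout),
                       file = NULL) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns",
    "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance",
    "xsi:schemaLocation" = paste(
      "http://graphml.graphdrawing.org/xmlns",
      "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd"))
  keydefs <- list(
    c("d_kind", "node", "kind", "string"),
    c("d_label", "node", "label", "string"),
    c("d_composition", "node", "composition", "string"),
    c("d_sites", "node", "sites", "string"),
    c("d_members", "node", "members", "string"),
    c("d_rule", "node", "rule_id", "string"),
    c("d_ordinal", "node", "ordinal", "int"),
    c("d_rev", "node", "reversible", "boolean"),
    c("d_name", "node", "name", "string"),
    c("d_akind", "edge", "kind", "string"),
    c("d_stoich", "edge", "stoichiometry", "int"),
    c("d_slabels", "edge", "site_labels", "string"),
    c("d_clabels", "edge", "context_labels", "string"),
    c("d_level", "graph", "level", "int"),
    c("d_model", "graph", "model_name", "string"))
  if (graphics)
    keydefs <- c(keydefs, lapply(c("x", "y", "w", "h"), function(q)
      c(paste0("d_", q), "node", q, "double")))
  for (k in keydefs)
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  g <- xml2::xml_add_child(doc, "graph", id = "mpd", edgedefault = "directed")
  dat <- function(parent, key, value) {
    d <- xml2::xml_add_child(parent, "data", key = key)
    xml2::xml_set_text(d, as.character(value))
  }
  dat(g, "d_level", graph$level)
  dat(g, "d_model", graph$provenance$model_name)

  ckeys <- names(graph$complex_nodes)
  cid <- stats::setNames(paste0("c", seq_along(ckeys) - 1L), ckeys)
  box <- function(node_id) {
    if (is.null(layout)) return(NULL)
    layout[layout$id == node_id, , drop = FALSE]
  }
  for (key in ckeys) {
    cn <- graph$complex_nodes[[key]]
    nd <- xml2::xml_add_child(g, "node", id = cid[[key]])
    dat(nd, "d_kind", "complex")
    dat(nd, "d_label", cn$label)
    dat(nd, "d_composition", cn$key)
    dat(nd, "d_sites", encode_sites(cn$site_map))
    dat(nd, "d_members", encode_members(cn$member_patterns))
    if (graphics) {
      b <- box(paste0("c:", key))
      if (nrow(b)) for (q in c("x", "y", "w", "h"))
        dat(nd, paste0("d_", q), b[[q]])
    }
  }
  for (pn in graph$process_nodes) {
    nd <- xml2::xml_add_child(g, "node", id = paste0("p", pn$ordinal))
    dat(nd, "d_kind", "process")
    dat(nd, "d_label", pn$rule_id)
    dat(nd, "d_rule", pn$rule_id)
    dat(nd, "d_ordinal", pn$ordinal)
    dat(nd, "d_rev", tolower(as.character(pn$reversible)))
    if (!is.na(pn$name)) dat(nd, "d_name", pn$name)
    if (graphics) {
      b <- box(paste0("p:", pn$rule_id))
      if (nrow(b)) for (q in c("x", "y", "w", "h"))
        dat(nd, paste0("d_", q), b[[q]])
    }
  }
  ord_of <- stats::setNames(
    vapply(graph$process_nodes, `[[`, 1L, "ordinal"),
    vapply(graph$process_nodes, `[[`, "", "rule_id"))
  for (i in seq_along(graph$arcs)) {
    a <- graph$arcs[[i]]
    pnode <- paste0("p", ord_of[[a$rule_id]])
    cnode <- cid[[a$complex_key]]
    ep <- if (a$kind == "CONSUMPTION") c(cnode, pnode) else c(pnode, cnode)
    ed <- xml2::xml_add_child(g, "edge", id = paste0("e", i - 1L),
                              source = ep[1], target = ep[2])
    dat(ed, "d_akind", a$kind)
    dat(ed, "d_stoich", a$stoichiometry)
    if (length(a$site_labels))
      dat(ed, "d_slabels", paste(a$site_labels, collapse = ";"))
    if (length(a$context_labels))
      dat(ed, "d_clabels", paste(a$context_labels, collapse = ";"))
  }
  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}

encode_members <- function(members) {
  paste(vapply(members, function(m)
    paste(m$rule_id, m$side, m$index, sep = ","), ""), collapse = ";")
}

decode_members <- function(txt) {
  if (!nzchar(txt)) return(list())
  lapply(strsplit(txt, ";", fixed = TRUE)[[1]], function(s) {
    p <- strsplit(s, ",", fixed = TRUE)[[1]]
    list(rule_id = p[1], side = p[2], index = as.integer(p[3]))
  })
}

encode_sites <- function(site_map) {
  paste(vapply(names(site_map), function(tp)
    paste0(tp, "=", paste(site_map[[tp]], collapse = ",")), ""),
    collapse = ";")
}

decode_sites <- function(txt) {
  if (!nzchar(txt)) return(stats::setNames(list(), character(0)))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    out[[kv[1]]] <- if (length(kv) > 1 && nzchar(kv[2]))
      strsplit(kv[2], ",", fixed = TRUE)[[1]] else character(0)
  }
  out
}

#' Reconstruct a process diagram from GraphML
#'
#' Inverse of [to_graphml()]: reading a written document yields an
#' `mpd_graph` equal to the original (graphics keys are ignored).
#'
#' @param x an `xml_document` or a path to a GraphML file.
#' @return an `mpd_graph`.
#' @export
read_graphml <- function(x) {
  # reserialize so namespace bindings are normalized regardless of how
  # the document was constructed
  doc <- if (inherits(x, "xml_document")) xml2::read_xml(as.character(x))
  else xml2::read_xml(x)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  key_nodes <- xml2::xml_find_all(doc, ".//g:key", ns)
  keymap <- stats::setNames(xml2::xml_attr(key_nodes, "attr.name"),
                            xml2::xml_attr(key_nodes, "id"))
  gr <- xml2::xml_find_first(doc, ".//g:graph", ns)
  read_data <- function(el) {
    ds <- xml2::xml_find_all(el, "./g:data", ns)
    stats::setNames(xml2::xml_text(ds),
                    keymap[xml2::xml_attr(ds, "key")])
  }
  gd <- read_data(gr)
  complexes <- list()
  processes <- list()
  id_kind <- character()
  id_ref <- character()
  for (nd in xml2::xml_find_all(gr, "./g:node", ns)) {
    d <- read_data(nd)
    nid <- xml2::xml_attr(nd, "id")
    if (d[["kind"]] == "complex") {
      complexes[[d[["composition"]]]] <-
        list(key = d[["composition"]], label = d[["label"]],
             member_patterns = decode_members(d[["members"]]),
             site_map = decode_sites(d[["sites"]]))
      id_kind[nid] <- "complex"
      id_ref[nid] <- d[["composition"]]
    } else {
      processes[[length(processes) + 1]] <-
        list(rule_id = d[["rule_id"]],
             ordinal = as.integer(d[["ordinal"]]),
             reversible = identical(d[["reversible"]], "true"),
             name = if ("name" %in% names(d)) d[["name"]]
             else NA_character_)
      id_kind[nid] <- "process"
      id_ref[nid] <- d[["rule_id"]]
    }
  }
  processes <- processes[order(vapply(processes, `[[`, 1L, "ordinal"))]
  arcs <- list()
  for (ed in xml2::xml_find_all(gr, "./g:edge", ns)) {
    d <- read_data(ed)
    src <- xml2::xml_attr(ed, "source")
    tgt <- xml2::xml_attr(ed, "target")
    ckey <- unname(if (id_kind[src] == "complex") id_ref[src]
                   else id_ref[tgt])
    rid <- unname(if (id_kind[src] == "process") id_ref[src]
                  else id_ref[tgt])
    arcs[[length(arcs) + 1]] <-
      list(kind = d[["kind"]], complex_key = ckey, rule_id = rid,
           stoichiometry = as.integer(d[["stoichiometry"]]),
           site_labels = if ("site_labels" %in% names(d))
             strsplit(d[["site_labels"]], ";", fixed = TRUE)[[1]]
           else character(0),
           context_labels = if ("context_labels" %in% names(d))
             strsplit(d[["context_labels"]], ";", fixed = TRUE)[[1]]
           else character(0))
  }
  structure(list(
    complex_nodes = complexes[sort(names(complexes))],
    process_nodes = processes,
    arcs = arcs,
    level = as.integer(gd[["level"]]),
    provenance = list(model_name = gd[["model_name"]],
                      level = as.integer(gd[["level"]]),
                      reversible_merged = TRUE)),
    class = "mpd_graph")
}
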