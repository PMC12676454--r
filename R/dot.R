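#' Export a process diagram as DOT
#'
#' Complexes become boxes, processes small squares; arcs become directed
#' edges labeled with stoichiometry (when above one) and any site or
#' context labels the graph carries. Output is deterministic.
#'
#' @param graph an `mpd_graph`.
#' @param file optional output path.
#' @return the DOT document as a single string.
#' @export
to_dot <- function(graph, file = NULL) {
  esc <- function(s) gsub("\"", "\\\"", s, fixed = TRUE)
  lines <- c("digraph mpd {", "  rankdir=LR;")
  ckeys <- names(graph$complex_nodes)
  cid <- stats::setNames(paste0("c", seq_along(ckeys) - 1L), ckeys)
  for (key in ckeys) {
    lines <- c(lines, sprintf('  %s [shape=box, label="%s"];',
                              cid[[key]],
                              esc(graph$complex_nodes[[key]]$label)))
  }
  for (pn in graph$process_nodes) {
    lines <- c(lines, sprintf(
      '  p%d [shape=square, width=0.3, label="%s"];',
      pn$ordinal, esc(pn$rule_id)))
  }
  ord_of <- stats::setNames(
    vapply(graph$process_nodes, `[[`, 1L, "ordinal"),
    vapply(graph$process_nodes, `[[`, "", "rule_id"))
  for (a in graph$arcs) {
    pnode <- paste0("p", ord_of[[a$rule_id]])
    cnode <- cid[[a$complex_key]]
    ep <- if (a$kind == "CONSUMPTION") c(cnode, pnode) else c(pnode, cnode)
    bits <- character(0)
    if (a$stoichiometry > 1) bits <- as.character(a$stoichiometry)
    bits <- c(bits, a$site_labels, a$context_labels)
    attr_txt <- if (length(bits))
      sprintf(' [label="%s"]', esc(paste(bits, collapse = "\\n"))) else ""
    lines <- c(lines, sprintf("  %s -> %s%s;", ep[1], ep[2], attr_txt))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file, useBytes = TRUE)
  txt
}
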