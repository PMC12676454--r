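#' Composition key of a complex pattern
#'
#' The molecular-complex grouping of a process diagram ignores states and
#' bond topology: a pattern's key is the lexicographically sorted multiset
#' of its molecule type names (with the compartment appended as
#' `type@compartment` when present), joined by `|`. Two patterns share a
#' complex node iff their keys agree, so `EGFR(ecd!+,tmd)` and
#' `EGFR(Y1~P)` both collapse onto the `EGFR` node while
#' `EGF(site!1).EGFR(ecd!1)` forms the distinct node `EGF|EGFR`.
#'
#' @param cx a `complex_pattern`.
#' @return a single key string.
#' @export
composition_key <- function(cx) {
  parts <- vapply(cx$molecules, function(mol) {
    if (is.na(mol$compartment)) mol$type
    else paste0(mol$type, "@", mol$compartment)
  }, "")
  paste(sort(parts), collapse = "|")
}

composition_label <- function(key) {
  gsub("|", "·", key, fixed = TRUE)   # "EGF|EGFR" -> "EGF·EGFR"
}

#' Build a Molecular Process Diagram
#'
#' Constructs the bipartite graph with one process node per reaction rule
#' (reversible rules included: one node, flagged reversible) and one
#' molecular-complex node per distinct composition key occurring in any
#' reactant or product pattern, shared across rules and across sides.
#' Consumption arcs run complex to process, production arcs process to
#' complex; reactant patterns of a rule with equal keys merge into a
#' single arc whose stoichiometry is their count (a dimerization shows
#' one consumption arc labeled 2, never two parallel arcs).
#'
#' Resolution levels only grow annotations — node and arc sets are
#' identical across levels:
#'
#' * level 1 — complexes, processes, arcs with stoichiometry;
#' * level 2 — plus modified-site labels: state changes as
#'   `"U→P@Y1"` on consumption arcs and `"P@Y1"` on production arcs;
#'   bond changes (`"bond@ecd–site"`, `"unbind@tmd"`) on consumption
#'   arcs only;
#' * level 3 — plus molecular-context labels (`"unbound@tmd"`,
#'   `"bound@ecd"`, `"P@Y1"`) on consumption arcs.
#'
#' @param model a `bngl_model`.
#' @param level resolution level, 1, 2 or 3.
#' @return an `mpd_graph`: lists `complex_nodes` (key, label,
#'   member_patterns), `process_nodes` (rule_id, ordinal, reversible,
#'   name), `arcs` (kind, complex_key, rule_id, stoichiometry,
#'   site_labels, context_labels), plus `level` and `provenance`.
#' @export
build_mpd <- function(model, level = 1) {
  if (!level %in% 1:3) stop("level must be 1, 2 or 3", call. = FALSE)
  complexes <- list()   # key -> list(key, label, member_patterns)
  arcs <- list()
  processes <- list()

  note_member <- function(key, rule_id, side, pat_idx) {
    if (is.null(complexes[[key]]))
      complexes[[key]] <<- list(key = key, label = composition_label(key),
                                member_patterns = list())
    complexes[[key]]$member_patterns[[
      length(complexes[[key]]$member_patterns) + 1]] <<-
      list(rule_id = rule_id, side = side, index = pat_idx)
  }

  for (i in seq_along(model$rules)) {
    ru <- model$rules[[i]]
    processes[[length(processes) + 1]] <-
      list(rule_id = ru$id, ordinal = i, reversible = ru$reversible,
           name = ru$name)
    cls <- if (level >= 2) classify_sites(ru, model = model) else NULL

    for (side in c("reactant", "product")) {
      pats <- if (side == "reactant") ru$reactants else ru$products
      keys <- vapply(pats, composition_key, "")
      for (p in seq_along(pats)) note_member(keys[p], ru$id, side, p)
      for (key in unique(keys)) {
        members <- which(keys == key)
        arc <- list(kind = if (side == "reactant") "CONSUMPTION"
                    else "PRODUCTION",
                    complex_key = key, rule_id = ru$id,
                    stoichiometry = length(members),
                    site_labels = character(0),
                    context_labels = character(0))
        if (level >= 2)
          arc$site_labels <- arc_site_labels(ru, cls, side, members, model)
        if (level >= 3 && side == "reactant")
          arc$context_labels <- arc_context_labels(ru, cls, members, model)
        arcs[[length(arcs) + 1]] <- arc
      }
    }
  }
  for (key in names(complexes)) {
    tps <- sub("@.*$", "", strsplit(key, "|", fixed = TRUE)[[1]])
    um <- unique(tps)
    complexes[[key]]$site_map <- stats::setNames(lapply(um, function(tp)
      vapply(model$molecule_types[[tp]]$components, `[[`, "", "name")), um)
  }
  keys <- sort(names(complexes))
  structure(list(
    complex_nodes = complexes[keys],
    process_nodes = processes,
    arcs = arcs,
    level = level,
    provenance = list(model_name = model$name, level = level,
                      reversible_merged = TRUE)),
    class = "mpd_graph")
}

# prefix the site name with the molecule type when another type in the
# same pattern group carries a site of the same name
site_ref <- function(type, comp_name, ambiguous_names) {
  if (comp_name %in% ambiguous_names) paste0(type, ".", comp_name)
  else comp_name
}

ambiguous_site_names <- function(entries) {
  if (!nrow(entries)) return(character(0))
  tab <- unique(entries[, c("type", "comp_name")])
  names(which(table(tab$comp_name) > 1))
}

arc_site_labels <- function(ru, cls, side, members, model) {
  e <- cls$entries
  amb <- ambiguous_site_names(e)
  out <- character(0)
  if (side == "reactant") {
    sel <- e[e$side == "reactant" & e$r_pat %in% members &
               e$label %in% c("MODIFIED_STATE", "MODIFIED_BOND",
                              "MODIFIED_BOTH"), , drop = FALSE]
    for (r in seq_len(nrow(sel))) {
      en <- sel[r, ]
      ref <- site_ref(en$type, en$comp_name, amb)
      if (en$state_changed && !is.na(en$p_pat)) {
        b <- if (is.na(en$before_state)) "?" else en$before_state
        a <- if (is.na(en$after_state)) "?" else en$after_state
        out <- c(out, sprintf("%s→%s@%s", b, a, ref))
      }
      if (en$bond_changed && !is.na(en$p_pat)) {
        if (identical(en$after_bondclass, "BOUND")) {
          partner <- en$p_partner_site
          out <- c(out, if (!is.na(partner))
            sprintf("bond@%s–%s", ref, sub("^[^.]*\\.", "", partner))
            else sprintf("bond@%s", ref))
        } else {
          partner <- en$r_partner_site
          out <- c(out, if (!is.na(partner))
            sprintf("unbind@%s–%s", ref, sub("^[^.]*\\.", "", partner))
            else sprintf("unbind@%s", ref))
        }
      }
    }
  } else {
    sel <- e[!is.na(e$p_pat) & e$p_pat %in% members &
               e$label %in% c("MODIFIED_STATE", "MODIFIED_BOTH") &
               e$state_changed & e$side == "reactant", , drop = FALSE]
    for (r in seq_len(nrow(sel))) {
      en <- sel[r, ]
      if (is.na(en$after_state)) next
      out <- c(out, sprintf("%s@%s", en$after_state,
                            site_ref(en$type, en$comp_name, amb)))
    }
  }
  unique(out)
}

arc_context_labels <- function(ru, cls, members, model) {
  e <- cls$entries
  amb <- ambiguous_site_names(e)
  sel <- e[e$side == "reactant" & e$r_pat %in% members &
             e$label == "CONTEXT", , drop = FALSE]
  out <- character(0)
  for (r in seq_len(nrow(sel))) {
    en <- sel[r, ]
    ref <- site_ref(en$type, en$comp_name, amb)
    if (!identical(en$before_bondclass, "ANY")) {
      out <- c(out, sprintf("%s@%s",
                            if (en$before_bondclass == "UNBOUND") "unbound"
                            else "bound", ref))
    }
    if (!is.na(en$before_state))
      out <- c(out, sprintf("%s@%s", en$before_state, ref))
  }
  unique(out)
}

#' Summary statistics of a process diagram
#'
#' @param graph an `mpd_graph`.
#' @return `list(processes, complexes, arcs, consumption, production,
#'   site_labels, context_labels, level)`.
#' @export
mpd_stats <- function(graph) {
  kinds <- vapply(graph$arcs, `[[`, "", "kind")
  list(processes = length(graph$process_nodes),
       complexes = length(graph$complex_nodes),
       arcs = length(graph$arcs),
       consumption = sum(kinds == "CONSUMPTION"),
       production = sum(kinds == "PRODUCTION"),
       site_labels = sum(vapply(graph$arcs, function(a)
         length(a$site_labels), 1L)),
       context_labels = sum(vapply(graph$arcs, function(a)
         length(a$context_labels), 1L)),
       level = graph$level)
}

#' @export
print.mpd_graph <- function(x, ...) {
  s <- mpd_stats(x)
  cat(sprintf(
    "<mpd_graph level %d: %d processes, %d complexes, %d arcs>\n",
    s$level, s$processes, s$complexes, s$arcs))
  invisible(x)
}
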