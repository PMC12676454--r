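#' Map reactant molecules to product molecules of a rule
#'
#' Molecules are paired by type name in order of appearance across the
#' concatenated reactant side and the concatenated product side: the
#' leftmost reactant occurrence of a type pairs with the leftmost product
#' occurrence of that type, and so on. Surplus occurrences are reported
#' as created (product side) or destroyed (reactant side) — legal
#' synthesis/degradation, never an error. When a type occurs more than
#' once on both sides the leftmost-first resolution is recorded in
#' `$notes` so the (deterministic, documented) choice is visible.
#'
#' @param rule a resolved rule.
#' @return `list(rule_id, pairs, created, destroyed, notes)`; `pairs`,
#'   `created` and `destroyed` are data.frames of occurrence coordinates
#'   (`r_pat`/`r_mol` index reactant pattern and molecule within it;
#'   `p_pat`/`p_mol` likewise for products).
#' @export
map_rule_molecules <- function(rule) {
  occs <- function(side) {
    rows <- list()
    for (p in seq_along(side))
      for (m in seq_along(side[[p]]$molecules))
        rows[[length(rows) + 1]] <-
          data.frame(pat = p, mol = m,
                     type = side[[p]]$molecules[[m]]$type,
                     stringsAsFactors = FALSE)
    if (!length(rows))
      return(data.frame(pat = integer(0), mol = integer(0),
                        type = character(0), stringsAsFactors = FALSE))
    do.call(rbind, rows)
  }
  r <- occs(rule$reactants)
  p <- occs(rule$products)
  pairs <- created <- destroyed <- list()
  notes <- character(0)
  for (tp in unique(c(r$type, p$type))) {
    ri <- which(r$type == tp)
    pi <- which(p$type == tp)
    k <- min(length(ri), length(pi))
    if (length(ri) > 1 && length(pi) > 1)
      notes <- c(notes, sprintf(
        "type %s occurs %d/%d times on reactant/product side; paired leftmost-first",
        tp, length(ri), length(pi)))
    if (k)
      pairs[[length(pairs) + 1]] <- data.frame(
        r_pat = r$pat[ri[1:k]], r_mol = r$mol[ri[1:k]],
        p_pat = p$pat[pi[1:k]], p_mol = p$mol[pi[1:k]],
        type = tp, stringsAsFactors = FALSE)
    ri_extra <- if (k) ri[-(1:k)] else ri
    pi_extra <- if (k) pi[-(1:k)] else pi
    if (length(ri_extra))
      destroyed[[length(destroyed) + 1]] <- data.frame(
        r_pat = r$pat[ri_extra], r_mol = r$mol[ri_extra],
        type = tp, stringsAsFactors = FALSE)
    if (length(pi_extra))
      created[[length(created) + 1]] <- data.frame(
        p_pat = p$pat[pi_extra], p_mol = p$mol[pi_extra],
        type = tp, stringsAsFactors = FALSE)
  }
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(integer(0)), length(cols)),
                                        cols))
    df$type <- character(0)
    df
  }
  list(rule_id = rule$id,
       pairs = if (length(pairs)) do.call(rbind, pairs)
       else empty(c("r_pat", "r_mol", "p_pat", "p_mol")),
       created = if (length(created)) do.call(rbind, created)
       else empty(c("p_pat", "p_mol")),
       destroyed = if (length(destroyed)) do.call(rbind, destroyed)
       else empty(c("r_pat", "r_mol")),
       notes = notes)
}

# partner component name of an explicit bond endpoint, NA otherwise
partner_site <- function(cx, mol_idx, type_pos) {
  cp <- NULL
  for (c0 in cx$molecules[[mol_idx]]$comps)
    if (c0$type_pos == type_pos) cp <- c0
  if (is.null(cp) || cp$bond$kind != BOND_NUM) return(NA_character_)
  for (b in bond_endpoints(cx)) {
    if (b$index != cp$bond$index) next
    for (q in 1:2) {
      if (b$mol[q] == mol_idx &&
          cx$molecules[[b$mol[q]]]$comps[[b$comp[q]]]$type_pos == type_pos) {
        o <- 3 - q
        om <- cx$molecules[[b$mol[o]]]
        return(paste0(om$type, ".", om$comps[[b$comp[o]]]$name))
      }
    }
  }
  NA_character_
}

#' Classify every reactant-side site of a rule
#'
#' Implements the three-layer semantics of molecular process diagrams:
#' each site of each reactant-side molecule is exactly one of
#'
#' * `MODIFIED_STATE` — internal state constraint differs between the
#'   reactant and product side;
#' * `MODIFIED_BOND` — bond class changes (classes are unconstrained,
#'   unbound and bound; `!n` and `!+` both count as bound), or the
#'   explicit bond partner changes at equal class;
#' * `MODIFIED_BOTH` — both of the above, and every site of a created or
#'   destroyed molecule;
#' * `CONTEXT` — unchanged but carrying at least one non-wildcard
#'   constraint (the "molecular context" required for the rule to fire);
#' * `UNCONSTRAINED` — wildcard on both state and bond (irrelevant site).
#'
#' A site that is unconstrained on the reactant side but concretely
#' constrained on the product side is inconsistent rule-writing; it is
#' labeled modified and a warning is recorded in `$warnings` — never
#' silently dropped. `!?` on both sides is never a modification:
#' wildcards carry no commitment.
#'
#' @param rule a resolved rule.
#' @param corr correspondence from [map_rule_molecules()] (computed when
#'   missing).
#' @param model the `bngl_model`.
#' @return `list(rule_id, entries, warnings)`; `entries` is a data.frame
#'   with one row per (molecule occurrence, type component): coordinates,
#'   `comp_name`, `comp_pos`, `label`, before/after state and bond class,
#'   partner sites of explicit bonds and change flags.
#' @export
classify_sites <- function(rule, corr = map_rule_molecules(rule), model) {
  rows <- list()
  warnings <- character(0)
  add <- function(row) rows[[length(rows) + 1]] <<- row

  entry_row <- function(side, r_pat, r_mol, p_pat, p_mol, type, cp_r, cp_p,
                        r_cx, p_cx, model) {
    before_state <- if (is.null(cp_r)) NA_character_ else cp_r$state
    after_state <- if (is.null(cp_p)) NA_character_ else cp_p$state
    before_class <- if (is.null(cp_r)) NA_character_ else bond_class(cp_r$bond)
    after_class <- if (is.null(cp_p)) NA_character_ else bond_class(cp_p$bond)
    rp <- if (!is.null(cp_r) && cp_r$bond$kind == BOND_NUM)
      partner_site(r_cx, r_mol, cp_r$type_pos) else NA_character_
    pp <- if (!is.null(cp_p) && cp_p$bond$kind == BOND_NUM)
      partner_site(p_cx, p_mol, cp_p$type_pos) else NA_character_
    data.frame(side = side, type = type,
               r_pat = r_pat, r_mol = r_mol, p_pat = p_pat, p_mol = p_mol,
               comp_pos = if (!is.null(cp_r)) cp_r$type_pos else cp_p$type_pos,
               comp_name = if (!is.null(cp_r)) cp_r$name else cp_p$name,
               label = NA_character_,
               before_state = before_state, after_state = after_state,
               before_bondclass = before_class, after_bondclass = after_class,
               r_partner_site = rp, p_partner_site = pp,
               state_changed = FALSE, bond_changed = FALSE,
               after_bond_plus = !is.null(cp_p) &&
                 cp_p$bond$kind == BOND_PLUS,
               stringsAsFactors = FALSE)
  }

  same <- function(a, b) (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) &&
                                                      a == b)

  # paired molecules
  if (nrow(corr$pairs)) for (i in seq_len(nrow(corr$pairs))) {
    pr <- corr$pairs[i, ]
    r_cx <- rule$reactants[[pr$r_pat]]
    p_cx <- rule$products[[pr$p_pat]]
    rm <- expand_components(r_cx$molecules[[pr$r_mol]], model)
    pm <- expand_components(p_cx$molecules[[pr$p_mol]], model)
    for (k in seq_along(rm$comps)) {
      cp_r <- rm$comps[[k]]
      cp_p <- pm$comps[[k]]
      e <- entry_row("reactant", pr$r_pat, pr$r_mol, pr$p_pat, pr$p_mol,
                     pr$type, cp_r, cp_p, r_cx, p_cx, model)
      e$state_changed <- !same(e$before_state, e$after_state)
      class_changed <- !same(e$before_bondclass, e$after_bondclass)
      partner_changed <- identical(e$before_bondclass, "BOUND") &&
        identical(e$after_bondclass, "BOUND") &&
        !is.na(e$r_partner_site) && !is.na(e$p_partner_site) &&
        e$r_partner_site != e$p_partner_site
      e$bond_changed <- class_changed || partner_changed
      if (e$state_changed && is.na(e$before_state))
        warnings <- c(warnings, sprintf(
          "rule %s: site %s.%s has wildcard state on the reactant side but '%s' on the product side",
          rule$id, pr$type, e$comp_name, e$after_state))
      if (e$bond_changed && identical(e$before_bondclass, "ANY"))
        warnings <- c(warnings, sprintf(
          "rule %s: site %s.%s has wildcard bond on the reactant side but a concrete bond on the product side",
          rule$id, pr$type, e$comp_name))
      e$label <- if (e$state_changed && e$bond_changed) "MODIFIED_BOTH"
      else if (e$state_changed) "MODIFIED_STATE"
      else if (e$bond_changed) "MODIFIED_BOND"
      else if (!is.na(e$before_state) ||
               !identical(e$before_bondclass, "ANY")) "CONTEXT"
      else "UNCONSTRAINED"
      add(e)
    }
  }

  # destroyed molecules: all sites modified (they vanish)
  if (nrow(corr$destroyed)) for (i in seq_len(nrow(corr$destroyed))) {
    d <- corr$destroyed[i, ]
    r_cx <- rule$reactants[[d$r_pat]]
    rm <- expand_components(r_cx$molecules[[d$r_mol]], model)
    for (k in seq_along(rm$comps)) {
      e <- entry_row("reactant", d$r_pat, d$r_mol, NA_integer_, NA_integer_,
                     d$type, rm$comps[[k]], NULL, r_cx, NULL, model)
      e$label <- "MODIFIED_BOTH"
      e$state_changed <- TRUE
      e$bond_changed <- TRUE
      add(e)
    }
  }

  # created molecules: all sites modified (they appear)
  if (nrow(corr$created)) for (i in seq_len(nrow(corr$created))) {
    cr <- corr$created[i, ]
    p_cx <- rule$products[[cr$p_pat]]
    pm <- expand_components(p_cx$molecules[[cr$p_mol]], model)
    for (k in seq_along(pm$comps)) {
      e <- entry_row("product", NA_integer_, NA_integer_, cr$p_pat, cr$p_mol,
                     cr$type, NULL, pm$comps[[k]], NULL, p_cx, model)
      e$label <- "MODIFIED_BOTH"
      e$state_changed <- TRUE
      e$bond_changed <- TRUE
      add(e)
    }
  }

  entries <- if (length(rows)) do.call(rbind, rows) else
    classify_empty_entries()
  list(rule_id = rule$id, entries = entries, warnings = warnings)
}

classify_empty_entries <- function() {
  data.frame(side = character(0), type = character(0),
             r_pat = integer(0), r_mol = integer(0),
             p_pat = integer(0), p_mol = integer(0),
             comp_pos = integer(0), comp_name = character(0),
             label = character(0),
             before_state = character(0), after_state = character(0),
             before_bondclass = character(0), after_bondclass = character(0),
             r_partner_site = character(0), p_partner_site = character(0),
             state_changed = logical(0), bond_changed = logical(0),
             after_bond_plus = logical(0), stringsAsFactors = FALSE)
}

#' Site classification table for a whole model
#'
#' Tab-separated-ready dump of the per-rule classification: one row per
#' reactant-side site, with its label and before/after records.
#'
#' @param model a `bngl_model`.
#' @return a data.frame with columns `rule_id`, `molecule`, `component`,
#'   `label`, `before`, `after`.
#' @export
site_classification_table <- function(model) {
  rows <- lapply(model$rules, function(r) {
    cls <- classify_sites(r, model = model)
    e <- cls$entries
    e <- e[e$side == "reactant", , drop = FALSE]
    if (!nrow(e))
      return(NULL)
    fmt <- function(st, bc) {
      s <- ifelse(is.na(st), "", st)
      b <- ifelse(is.na(bc), "", tolower(bc))
      trimws(paste(s, b))
    }
    data.frame(rule_id = r$id, molecule = e$type, component = e$comp_name,
               label = e$label,
               before = fmt(e$before_state, e$before_bondclass),
               after = fmt(e$after_state, e$after_bondclass),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(rule_id = character(0), molecule = character(0),
                      component = character(0), label = character(0),
                      before = character(0), after = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
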