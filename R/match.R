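#' @title Pattern matching and rule expansion
#' @description Brute-force embedding of complex patterns into concrete
#'   species, and expansion of a single rule over a seed-species pool into
#'   distinct concrete reactions. This is the semantic oracle of the
#'   package: one rule represents many reactions, and the expansion makes
#'   that set explicit on small inputs.
#' @name pattern-matching
NULL

# ---- concrete species ---------------------------------------------------

# A concrete species is a complex_pattern in normal form: every type
# component present in type order, concrete states wherever the type has
# states, bonds only UNBOUND or explicit indices.

assert_concrete <- function(cx, model, line = NA) {
  for (mol in cx$molecules) {
    mt <- model$molecule_types[[mol$type]]
    listed <- vapply(mol$comps, `[[`, 1L, "type_pos")
    for (k in seq_along(mt$components)) {
      cd <- mt$components[[k]]
      hit <- which(listed == k)
      if (!length(hit)) {
        if (length(cd$states))
          parse_stop(sprintf(
            "concrete species must specify a state for %s.%s",
            mol$type, cd$name), line)
        next
      }
      cp <- mol$comps[[hit[1]]]
      if (length(cd$states) && is.na(cp$state))
        parse_stop(sprintf(
          "concrete species must specify a state for %s.%s",
          mol$type, cd$name), line)
      if (cp$bond$kind %in% c(BOND_ANY, BOND_PLUS))
        parse_stop(sprintf(
          "concrete species cannot carry bond wildcards (%s.%s)",
          mol$type, cp$name), line)
    }
  }
  invisible(cx)
}

# fill omitted (stateless) components as unbound; order comps by type_pos
normalize_species <- function(cx, model) {
  cx$molecules <- lapply(cx$molecules, function(mol) {
    mol <- expand_components(mol, model)
    mol$comps <- lapply(mol$comps, function(cp) {
      if (cp$bond$kind == BOND_ANY) cp$bond <- list(kind = BOND_NONE,
                                                    index = NA_integer_)
      cp$state_wild <- FALSE
      cp
    })
    mol$had_parens <- TRUE
    mol
  })
  cx
}

#' Build a concrete species from pattern text
#'
#' @param txt BNGL pattern text, fully specified (concrete states, no
#'   bond wildcards); omitted stateless components default to unbound.
#' @param model the model providing molecule types.
#' @return a normalized concrete species (`complex_pattern`).
#' @export
concrete_species <- function(txt, model) {
  cx <- parse_pattern(txt, model)
  assert_concrete(cx, model)
  normalize_species(cx, model)
}

# ---- instance graphs ----------------------------------------------------

# Mutable working form for expansion: per molecule, a state vector and a
# bond-id vector indexed by type component position (NA = unbound).

species_to_inst <- function(sp, model) {
  mols <- lapply(sp$molecules, function(mol) {
    n <- length(mol$comps)
    states <- vapply(mol$comps, function(cp)
      if (is.na(cp$state)) NA_character_ else cp$state, "")
    bonds <- vapply(mol$comps, function(cp)
      if (cp$bond$kind == BOND_NUM) cp$bond$index else NA_integer_, 1L)
    list(type = mol$type, compartment = mol$compartment,
         states = states, bonds = bonds)
  })
  list(mols = mols)
}

inst_to_species_list <- function(inst, model) {
  n <- length(inst$mols)
  if (!n) return(list())
  # connected components over shared bond ids
  comp_id <- seq_len(n)
  repeat {
    changed <- FALSE
    bond_owner <- list()
    for (i in seq_len(n)) {
      for (b in inst$mols[[i]]$bonds) {
        if (is.na(b)) next
        key <- as.character(b)
        prev <- bond_owner[[key]]
        if (is.null(prev)) bond_owner[[key]] <- i
        else if (comp_id[i] != comp_id[prev]) {
          tgt <- min(comp_id[i], comp_id[prev])
          comp_id[comp_id == comp_id[i] | comp_id == comp_id[prev]] <- tgt
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lapply(unique(comp_id), function(cid) {
    members <- which(comp_id == cid)
    sub <- inst$mols[members]
    origins <- vapply(sub, function(m)
      if (is.null(m$origin)) NA_integer_ else m$origin, 1L)
    # renumber bonds in first-occurrence order
    relabel <- integer(0)
    nxt <- 1L
    mols <- lapply(sub, function(m) {
      mt <- model$molecule_types[[m$type]]
      comps <- lapply(seq_along(m$states), function(k) {
        b <- m$bonds[k]
        if (!is.na(b)) {
          key <- as.character(b)
          if (is.na(relabel[key])) {
            relabel[key] <<- nxt
            nxt <<- nxt + 1L
          }
          cp <- component_pattern(mt$components[[k]]$name,
                                  state = m$states[k],
                                  bond_kind = BOND_NUM,
                                  bond_index = relabel[key])
        } else {
          cp <- component_pattern(mt$components[[k]]$name,
                                  state = m$states[k])
        }
        cp$type_pos <- k
        cp
      })
      molecule_pattern(m$type, comps, compartment = m$compartment)
    })
    out <- complex_pattern(mols)
    attr(out, "origins") <- origins
    out
  })
}

# ---- matching -----------------------------------------------------------

#' Match a pattern against a concrete species
#'
#' Enumerates every injective mapping of the pattern's molecules onto the
#' species' molecules that respects type names, compartments (a pattern
#' without a compartment matches any), component identity (positional for
#' duplicate names), state constraints (unconstrained matches anything)
#' and bond constraints: a listed component without a bond must be
#' unbound, `!+` matches any bond, `!?` matches anything, and the two
#' endpoints of an explicit `!n` must land on the two endpoints of one
#' species bond. Search is exhaustive and the embedding order is
#' deterministic (lexicographic in species molecule indices).
#'
#' @param pattern a resolved `complex_pattern`.
#' @param species a concrete species ([concrete_species()]).
#' @param model the `bngl_model`.
#' @return list of embeddings, each `list(mol_map = integer vector)`
#'   mapping pattern molecule i to species molecule `mol_map[i]`.
#' @export
match_pattern <- function(pattern, species, model) {
  np <- length(pattern$molecules)
  ns <- length(species$molecules)
  out <- list()
  assign_next <- function(i, used, mol_map) {
    if (i > np) {
      if (bonds_consistent(pattern, species, mol_map))
        out[[length(out) + 1]] <<- list(mol_map = mol_map)
      return(invisible(NULL))
    }
    pm <- pattern$molecules[[i]]
    for (j in seq_len(ns)) {
      if (used[j]) next
      if (!molecule_matches(pm, species$molecules[[j]])) next
      used[j] <- TRUE
      mol_map[i] <- j
      assign_next(i + 1, used, mol_map)
      used[j] <- FALSE
    }
  }
  assign_next(1L, rep(FALSE, ns), integer(np))
  out
}

molecule_matches <- function(pm, sm) {
  if (pm$type != sm$type) return(FALSE)
  if (!is.na(pm$compartment) &&
      (is.na(sm$compartment) || pm$compartment != sm$compartment))
    return(FALSE)
  for (cp in pm$comps) {
    sc <- sm$comps[[cp$type_pos]]
    if (!is.na(cp$state) && (is.na(sc$state) || cp$state != sc$state))
      return(FALSE)
    ok <- switch(cp$bond$kind,
                 any = TRUE,
                 none = sc$bond$kind == BOND_NONE,
                 plus = sc$bond$kind == BOND_NUM,
                 num = sc$bond$kind == BOND_NUM)
    if (!ok) return(FALSE)
  }
  TRUE
}

# explicit pattern bonds must map onto shared species bonds
bonds_consistent <- function(pattern, species, mol_map) {
  for (b in bond_endpoints(pattern)) {
    e1 <- pattern$molecules[[b$mol[1]]]$comps[[b$comp[1]]]
    e2 <- pattern$molecules[[b$mol[2]]]$comps[[b$comp[2]]]
    s1 <- species$molecules[[mol_map[b$mol[1]]]]$comps[[e1$type_pos]]
    s2 <- species$molecules[[mol_map[b$mol[2]]]]$comps[[e2$type_pos]]
    if (s1$bond$kind != BOND_NUM || s2$bond$kind != BOND_NUM) return(FALSE)
    if (s1$bond$index != s2$bond$index) return(FALSE)
  }
  TRUE
}

# ---- state enumeration --------------------------------------------------

#' Enumerate internal-state combinations of a molecule type
#'
#' Counts (and optionally lists) the combinations of internal states a
#' molecule type can take, ignoring bonds. A molecule with nine two-state
#' sites has 2^9 = 512 states; this product is the textbook illustration
#' of why explicit network enumeration does not scale.
#'
#' @param mt a `molecule_type`.
#' @param list_states when `TRUE`, also return the combinations as a
#'   data.frame (one column per stateful component).
#' @return the count, or `list(count, states)` when `list_states`.
#' @export
enumerate_states <- function(mt, list_states = FALSE) {
  ns <- vapply(mt$components, function(cd) max(1L, length(cd$states)), 1L)
  count <- prod(ns)
  if (!list_states) return(count)
  stateful <- which(vapply(mt$components, function(cd)
    length(cd$states) > 0, TRUE))
  grid <- if (length(stateful))
    expand.grid(lapply(mt$components[stateful], `[[`, "states"),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)
  if (length(stateful))
    names(grid) <- vapply(mt$components[stateful], `[[`, "", "name")
  list(count = count, states = grid)
}

# ---- rule application ---------------------------------------------------

expand_stop <- function(msg) {
  stop(structure(class = c("mpd_expand_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Apply one rule to a chosen tuple of species (one per reactant pattern,
# counted with multiplicity). Returns the list of product species.
apply_rule_once <- function(rule, corr, cls, chosen, embeddings, model) {
  # disjoint union of the chosen species instances
  inst <- list(mols = list())
  offset <- integer(length(chosen))
  bond_base <- 0L
  for (i in seq_along(chosen)) {
    sp <- species_to_inst(chosen[[i]], model)
    # shift bond ids to keep them disjoint across instances; remember the
    # combined-index provenance of every molecule for diff tracing
    base_idx <- length(inst$mols)
    sp$mols <- lapply(seq_along(sp$mols), function(q) {
      m <- sp$mols[[q]]
      m$bonds <- m$bonds + bond_base
      m$origin <- base_idx + q
      m
    })
    mx <- unlist(lapply(sp$mols, function(m) m$bonds))
    bond_base <- max(c(bond_base, mx), na.rm = TRUE)
    offset[i] <- length(inst$mols)
    inst$mols <- c(inst$mols, sp$mols)
  }
  next_bond <- bond_base + 1L

  # map reactant occurrence (pattern p, molecule m) -> inst molecule index
  r_inst <- function(p, m) offset[p] + embeddings[[p]]$mol_map[m]

  ent <- cls$entries
  # 1. state changes on paired molecules
  st <- ent[ent$side == "reactant" &
              ent$label %in% c("MODIFIED_STATE", "MODIFIED_BOTH") &
              !is.na(ent$p_pat), , drop = FALSE]
  for (r in seq_len(nrow(st))) {
    e <- st[r, ]
    if (is.na(e$after_state)) {
      if (!is.na(e$before_state) || !identical(e$before_bondclass,
                                               e$after_bondclass))
        expand_stop(sprintf(
          "rule %s: product leaves the state of %s unspecified",
          rule$id, e$comp_name))
      next
    }
    im <- r_inst(e$r_pat, e$r_mol)
    inst$mols[[im]]$states[e$comp_pos] <- e$after_state
  }

  # 2. break bonds at every bond-modified reactant endpoint
  bm <- ent[ent$side == "reactant" &
              ent$label %in% c("MODIFIED_BOND", "MODIFIED_BOTH") &
              !is.na(ent$p_pat) & ent$bond_changed, , drop = FALSE]
  for (r in seq_len(nrow(bm))) {
    e <- bm[r, ]
    if (identical(e$after_bondclass, "BOUND") && e$after_bond_plus)
      expand_stop(sprintf(
        "rule %s: cannot concretize a '!+' product bond", rule$id))
    im <- r_inst(e$r_pat, e$r_mol)
    bid <- inst$mols[[im]]$bonds[e$comp_pos]
    if (!is.na(bid)) {
      for (k in seq_along(inst$mols))
        inst$mols[[k]]$bonds[inst$mols[[k]]$bonds %in% bid] <- NA_integer_
    }
  }

  # 3. destroy molecules (their bonds go with them)
  destroyed <- integer(0)
  if (nrow(corr$destroyed)) {
    for (r in seq_len(nrow(corr$destroyed))) {
      d <- corr$destroyed[r, ]
      im <- r_inst(d$r_pat, d$r_mol)
      destroyed <- c(destroyed, im)
      for (bid in inst$mols[[im]]$bonds) {
        if (is.na(bid)) next
        for (k in seq_along(inst$mols))
          inst$mols[[k]]$bonds[inst$mols[[k]]$bonds %in% bid] <- NA_integer_
      }
    }
  }

  # 4. create product-only molecules (must be fully specified)
  created_inst <- integer(0)  # indexed by created row
  if (nrow(corr$created)) {
    for (r in seq_len(nrow(corr$created))) {
      cr <- corr$created[r, ]
      pm <- rule$products[[cr$p_pat]]$molecules[[cr$p_mol]]
      mt <- model$molecule_types[[pm$type]]
      states <- rep(NA_character_, length(mt$components))
      for (cp in pm$comps) {
        if (cp$bond$kind %in% c(BOND_ANY, BOND_PLUS))
          expand_stop(sprintf(
            "rule %s: created molecule carries a bond wildcard", rule$id))
        states[cp$type_pos] <- cp$state
      }
      for (k in seq_along(mt$components)) {
        if (length(mt$components[[k]]$states) && is.na(states[k]))
          expand_stop(sprintf(
            "rule %s: created molecule %s is not fully specified",
            rule$id, pm$type))
      }
      inst$mols[[length(inst$mols) + 1]] <-
        list(type = pm$type, compartment = pm$compartment,
             states = states,
             bonds = rep(NA_integer_, length(mt$components)),
             origin = NA_integer_)
      created_inst[r] <- length(inst$mols)
    }
  }

  # product occurrence -> inst molecule index
  p_inst <- function(p, m) {
    hit <- which(corr$pairs$p_pat == p & corr$pairs$p_mol == m)
    if (length(hit))
      return(r_inst(corr$pairs$r_pat[hit], corr$pairs$r_mol[hit]))
    hit <- which(corr$created$p_pat == p & corr$created$p_mol == m)
    created_inst[hit]
  }

  # 5. add product bonds whose endpoints include a modified or created site
  for (p in seq_along(rule$products)) {
    for (b in bond_endpoints(rule$products[[p]])) {
      ep <- lapply(1:2, function(q) {
        mol <- rule$products[[p]]$molecules[[b$mol[q]]]
        cp <- mol$comps[[b$comp[q]]]
        list(inst = p_inst(p, b$mol[q]), pos = cp$type_pos)
      })
      im1 <- ep[[1]]$inst; k1 <- ep[[1]]$pos
      im2 <- ep[[2]]$inst; k2 <- ep[[2]]$pos
      b1 <- inst$mols[[im1]]$bonds[k1]
      b2 <- inst$mols[[im2]]$bonds[k2]
      if (!is.na(b1) && !is.na(b2) && b1 == b2) next  # pre-existing bond
      if (!is.na(b1) || !is.na(b2))
        expand_stop(sprintf(
          "rule %s: product bond conflicts with an existing bond", rule$id))
      inst$mols[[im1]]$bonds[k1] <- next_bond
      inst$mols[[im2]]$bonds[k2] <- next_bond
      next_bond <- next_bond + 1L
    }
  }

  if (length(destroyed)) inst$mols <- inst$mols[-destroyed]
  inst_to_species_list(inst, model)
}

#' Expand a rule over a pool of concrete species
#'
#' Applies one rule to every combination of embeddings of its reactant
#' patterns into species of the pool (species may be used with
#' multiplicity, as in dimerization), producing concrete reactions.
#' Reactions are deduplicated by canonical reactant/product multisets, so
#' embeddings that differ only by an automorphism of the reactant side
#' collapse into one reaction. With `max_iterations > 1` newly produced
#' species join the pool and expansion repeats to a fixed point or the
#' iteration cap.
#'
#' @param rule a rule from the model (reversible rules are expanded in
#'   the forward direction).
#' @param seeds list of concrete species (e.g. `model$seed_species`
#'   entries' `$species`, or [concrete_species()] results).
#' @param model the `bngl_model`.
#' @param max_iterations iteration cap (>= 1).
#' @param species_cap hard cap on the species pool; exceeding it raises
#'   an error of class `mpd_expand_error` rather than truncating.
#' @param trace when `TRUE`, each reaction additionally records its
#'   embedding: the chosen reactant species, the molecule maps, and the
#'   product species with per-molecule provenance (`origins` attribute:
#'   index into the combined reactant molecule list, `NA` for created
#'   molecules). Used by consistency checks.
#' @return `list(reactions, species, fixed_point)`: `reactions` is a list
#'   of `list(rule_id, reactants, products)` with canonical-string
#'   multisets; `species` the final pool keyed by canonical string;
#'   `fixed_point` whether no new species appeared in the last round.
#' @export
expand_rule <- function(rule, seeds, model, max_iterations = 1,
                        species_cap = 10000, trace = FALSE) {
  stopifnot(max_iterations >= 1)
  corr <- map_rule_molecules(rule)
  cls <- classify_sites(rule, corr, model)
  pool <- list()
  for (s in seeds) pool[[canonical_form(s, model)]] <- s
  reactions <- list()
  fixed_point <- FALSE
  for (iter in seq_len(max_iterations)) {
    new_species <- list()
    pool_list <- if (length(pool)) pool[order(names(pool))] else pool
    # all (species, embedding) choices per reactant pattern
    choices <- lapply(rule$reactants, function(pat) {
      out <- list()
      for (key in names(pool_list)) {
        sp <- pool_list[[key]]
        for (e in match_pattern(pat, sp, model))
          out[[length(out) + 1]] <- list(species = sp, emb = e, key = key)
      }
      out
    })
    if (!length(rule$reactants)) choices <- list()
    combos <- combo_indices(vapply(choices, length, 1L))
    for (ci in combos) {
      chosen <- lapply(seq_along(ci), function(i) choices[[i]][[ci[i]]])
      prods <- apply_rule_once(rule, corr, cls,
                               lapply(chosen, `[[`, "species"),
                               lapply(chosen, `[[`, "emb"), model)
      r_keys <- sort(vapply(chosen, `[[`, "", "key"))
      p_keys <- sort(vapply(prods, canonical_form, "", model = model))
      rid <- paste(paste(r_keys, collapse = " + "), "->",
                   paste(p_keys, collapse = " + "))
      if (is.null(reactions[[rid]]))
        reactions[[rid]] <- list(
          rule_id = rule$id, reactants = r_keys, products = p_keys,
          trace = if (trace) list(
            species = lapply(chosen, `[[`, "species"),
            mol_maps = lapply(chosen, function(ch) ch$emb$mol_map),
            products = prods) else NULL,
          text = paste(
            paste(sort(vapply(chosen, function(ch)
              pattern_to_string(ch$species), "")), collapse = " + "),
            "->",
            paste(sort(vapply(prods, pattern_to_string, "")),
                  collapse = " + ")))
      for (q in seq_along(prods)) {
        key <- p_keys[q]
        if (is.null(pool[[key]]) && is.null(new_species[[key]]))
          new_species[[key]] <- prods[[q]]
      }
    }
    if (!length(new_species)) {
      fixed_point <- TRUE
      break
    }
    pool <- c(pool, new_species)
    if (length(pool) > species_cap)
      expand_stop(sprintf("species pool exceeded cap (%d)", species_cap))
  }
  list(reactions = unname(reactions), species = pool,
       fixed_point = fixed_point)
}

# cartesian product of index vectors 1..n[i]; empty n -> one empty combo
combo_indices <- function(n) {
  if (!length(n)) return(list(integer(0)))
  if (any(n == 0)) return(list())
  grid <- expand.grid(rev(lapply(n, seq_len)), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(n)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}
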