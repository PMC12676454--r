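#' @title Core model types
#' @description Constructors and validators for the rule-based model
#'   representation: molecule type definitions, molecule/complex patterns,
#'   rules and whole models. Patterns follow BNGL conventions: a component
#'   listed without a bond is required unbound, `!n` is an explicit bond,
#'   `!+` requires a bond to an unspecified partner, `!?` leaves bonding
#'   unconstrained, `~s` fixes an internal state and `~?` (or omitting the
#'   component entirely) leaves it unconstrained.
#' @name mpdiagram-types
NULL

BOND_ANY   <- "any"    # "!?": no commitment
BOND_NONE  <- "none"   # default for a listed component: must be unbound
BOND_PLUS  <- "plus"   # "!+": bound to an unspecified partner
BOND_NUM   <- "num"    # "!n": explicit bond endpoint

#' Component definition of a molecule type
#'
#' @param name component (site) name.
#' @param states character vector of allowed internal states (may be empty).
#' @return a `component_def` list.
#' @export
component_def <- function(name, states = character()) {
  stopifnot(is.character(name), nzchar(name))
  structure(list(name = name, states = as.character(states)),
            class = "component_def")
}

#' Molecule type definition
#'
#' Duplicate component names are permitted (e.g. two identical binding arms)
#' and are distinguished by position.
#'
#' @param name molecule type name.
#' @param components list of [component_def()] objects.
#' @return a `molecule_type` list.
#' @export
molecule_type <- function(name, components = list()) {
  stopifnot(is.character(name), nzchar(name))
  structure(list(name = name, components = components),
            class = "molecule_type")
}

# A component pattern inside a molecule pattern.
# state: NA_character_ = unconstrained (ANY); otherwise a state identifier.
# state_wild: TRUE when the wildcard was written explicitly as "~?"
#   (round-trip detail only; semantically identical to NA with FALSE).
# bond: list(kind = BOND_*, index = integer or NA).
# type_pos: position in the molecule type's component list; filled in
#   during model resolution (positional left-to-right for duplicates).
component_pattern <- function(name, state = NA_character_, state_wild = FALSE,
                              bond_kind = BOND_NONE, bond_index = NA_integer_) {
  list(name = name, state = state, state_wild = isTRUE(state_wild),
       bond = list(kind = bond_kind, index = as.integer(bond_index)),
       type_pos = NA_integer_)
}

molecule_pattern <- function(type, comps = list(), compartment = NA_character_,
                             had_parens = TRUE) {
  structure(list(type = type, compartment = compartment, comps = comps,
                 had_parens = isTRUE(had_parens)),
            class = "molecule_pattern")
}

complex_pattern <- function(molecules) {
  structure(list(molecules = molecules), class = "complex_pattern")
}

#' Construct a reaction rule
#'
#' @param reactants,products lists of complex patterns (as returned by
#'   [parse_pattern()]); an empty list denotes synthesis/degradation.
#' @param rate_forward,rate_reverse opaque rate expression strings;
#'   `rate_reverse` must be present iff `reversible`.
#' @param reversible logical.
#' @param name optional rule label.
#' @param id identifier; assigned automatically ("R1".."Rn") by
#'   [bngl_model()] / [parse_model()] when `NA`.
#' @return a `bngl_rule` object.
#' @export
rule <- function(reactants, products, rate_forward = "1",
                 rate_reverse = NULL, reversible = !is.null(rate_reverse),
                 name = NA_character_, id = NA_character_) {
  if (reversible && is.null(rate_reverse))
    stop("reversible rule requires a reverse rate expression", call. = FALSE)
  if (!reversible && !is.null(rate_reverse))
    stop("irreversible rule must not carry a reverse rate", call. = FALSE)
  structure(list(id = id, name = name,
                 reactants = reactants, products = products,
                 reversible = isTRUE(reversible),
                 rate_forward = rate_forward,
                 rate_reverse = if (reversible) rate_reverse else NA_character_),
            class = "bngl_rule")
}

#' Construct a model programmatically
#'
#' Performs the same resolution and validation as [parse_model()]: every
#' type reference is checked, pattern components are bound to type
#' components positionally (leftmost unused occurrence for duplicate
#' names), bond indices must pair exactly twice per complex pattern, and
#' each complex pattern must be connected.
#'
#' @param molecule_types list of [molecule_type()] objects.
#' @param rules list of [rule()] objects.
#' @param parameters named character vector of parameter expressions.
#' @param seed_species list of `list(species, amount)` where `species`
#'   is a concrete complex pattern.
#' @param compartments data.frame with columns `name`, `dim`, `rest`.
#' @param observables,functions character vectors of opaque block lines.
#' @param name model name carried into diagram provenance.
#' @return a validated `bngl_model`.
#' @export
bngl_model <- function(molecule_types, rules = list(),
                       parameters = character(), seed_species = list(),
                       compartments = NULL, observables = character(),
                       functions = character(), name = "model") {
  names(molecule_types) <- vapply(molecule_types, `[[`, "", "name")
  if (anyDuplicated(names(molecule_types)))
    stop("duplicate molecule type name", call. = FALSE)
  m <- structure(list(molecule_types = molecule_types,
                      parameters = parameters,
                      rules = rules,
                      seed_species = seed_species,
                      compartments = compartments,
                      observables = observables,
                      functions = functions,
                      name = name),
                 class = "bngl_model")
  resolve_model(m)
}

# ---- resolution & validation -------------------------------------------

parse_stop <- function(msg, line = NA) {
  where <- if (!is.na(line)) sprintf("line %s: ", line) else ""
  stop(structure(class = c("mpd_parse_error", "error", "condition"),
                 list(message = paste0(where, msg), call = NULL)))
}

unsupported_stop <- function(construct, line = NA) {
  where <- if (!is.na(line)) sprintf("line %s: ", line) else ""
  stop(structure(class = c("mpd_unsupported_error", "error", "condition"),
                 list(message = paste0(where, "unsupported construct: ",
                                       construct),
                      call = NULL)))
}

# Bind each pattern component to a type component position, leftmost unused
# occurrence for duplicate names; validate states against allowed_states.
resolve_molecule <- function(mol, model, line = NA) {
  mt <- model$molecule_types[[mol$type]]
  if (is.null(mt))
    parse_stop(sprintf("reference to undeclared molecule type '%s'",
                       mol$type), line)
  type_names <- vapply(mt$components, `[[`, "", "name")
  used <- rep(FALSE, length(type_names))
  for (i in seq_along(mol$comps)) {
    cp <- mol$comps[[i]]
    pos <- which(type_names == cp$name & !used)
    if (!length(pos))
      parse_stop(sprintf(
        "component '%s' not available in molecule type '%s'",
        cp$name, mol$type), line)
    pos <- pos[1]
    used[pos] <- TRUE
    if (!is.na(cp$state)) {
      allowed <- mt$components[[pos]]$states
      if (!cp$state %in% allowed)
        parse_stop(sprintf(
          "state '%s' not in allowed states of %s.%s",
          cp$state, mol$type, cp$name), line)
    }
    mol$comps[[i]]$type_pos <- pos
  }
  mol
}

validate_complex <- function(cx, line = NA) {
  idx <- integer(0)
  for (mol in cx$molecules)
    for (cp in mol$comps)
      if (cp$bond$kind == BOND_NUM) idx <- c(idx, cp$bond$index)
  tab <- table(idx)
  bad <- names(tab)[tab != 2]
  if (length(bad))
    parse_stop(sprintf(
      "bond index %s must appear exactly twice within a complex pattern",
      bad[1]), line)
  # connectivity over the bond graph
  n <- length(cx$molecules)
  if (n > 1) {
    ends <- bond_endpoints(cx)
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (b in ends) {
      adj[[b$mol[1]]] <- c(adj[[b$mol[1]]], b$mol[2])
      adj[[b$mol[2]]] <- c(adj[[b$mol[2]]], b$mol[1])
    }
    seen <- rep(FALSE, n)
    stack <- 1L
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, adj[[v]])
    }
    if (!all(seen))
      parse_stop("complex pattern is not connected", line)
  }
  invisible(cx)
}

# list of bonds: each list(index, mol = c(i, j), comp = c(ci, cj)) where
# comp holds the component position within the pattern's comps list.
bond_endpoints <- function(cx) {
  pool <- list()
  for (i in seq_along(cx$molecules)) {
    comps <- cx$molecules[[i]]$comps
    for (ci in seq_along(comps)) {
      b <- comps[[ci]]$bond
      if (b$kind == BOND_NUM) {
        key <- as.character(b$index)
        pool[[key]] <- c(pool[[key]], list(c(i, ci)))
      }
    }
  }
  lapply(names(pool), function(k) {
    ep <- pool[[k]]
    list(index = as.integer(k),
         mol = c(ep[[1]][1], ep[[2]][1]),
         comp = c(ep[[1]][2], ep[[2]][2]))
  })
}

resolve_complex <- function(cx, model, line = NA) {
  cx$molecules <- lapply(cx$molecules, resolve_molecule, model = model,
                         line = line)
  validate_complex(cx, line)
  cx
}

resolve_model <- function(m) {
  for (r in seq_along(m$rules)) {
    ru <- m$rules[[r]]
    if (is.na(ru$id)) ru$id <- paste0("R", r)
    ru$reactants <- lapply(ru$reactants, resolve_complex, model = m)
    ru$products <- lapply(ru$products, resolve_complex, model = m)
    if (ru$reversible && is.na(ru$rate_reverse))
      parse_stop(sprintf("rule %s: reversible arrow requires two rates",
                         ru$id))
    m$rules[[r]] <- ru
  }
  m$seed_species <- lapply(m$seed_species, function(ss) {
    ss$species <- resolve_complex(ss$species, model = m)
    assert_concrete(ss$species, m)
    ss$species <- normalize_species(ss$species, m)
    ss
  })
  m
}

# ---- small utilities ----------------------------------------------------

bond_class <- function(bond) {
  switch(bond$kind,
         any = "ANY", none = "UNBOUND", plus = "BOUND", num = "BOUND")
}

n_type_components <- function(model, type) {
  length(model$molecule_types[[type]]$components)
}

#' @export
print.bngl_model <- function(x, ...) {
  cat(sprintf("<bngl_model '%s': %d molecule types, %d rules, %d seeds>\n",
              x$name, length(x$molecule_types), length(x$rules),
              length(x$seed_species)))
  invisible(x)
}

#' @export
print.bngl_rule <- function(x, ...) {
  cat(rule_to_string(x), "\n")
  invisible(x)
}

#' @export
print.complex_pattern <- function(x, ...) {
  cat(pattern_to_string(x), "\n")
  invisible(x)
}
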