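#' Configuration for the random model generator
#'
#' The generator drives the property-test suites: it must produce valid
#' models deterministically per seed while exercising every component
#' constraint kind (concrete states, explicit `~?`, omission, unbound,
#' `!?`, `!+`, explicit bonds) with nonzero frequency at the defaults.
#'
#' @param n_molecule_types number of molecule types.
#' @param comps_range integer range (min, max) of components per type.
#' @param states_range integer range of allowed states per component
#'   (0 = stateless).
#' @param n_rules number of rules.
#' @param max_pattern_size maximum molecules per complex pattern (the
#'   generator itself builds patterns of at most 2 molecules plus
#'   context; the cap is validated for feasibility).
#' @param p_state_wildcard probability that a listed stateful component
#'   carries an explicit `~?` instead of a concrete state.
#' @param p_bond_wildcard probability that a context component carries a
#'   `!?` or `!+` wildcard instead of being required unbound.
#' @param p_context probability that any given extra component is listed
#'   as context at all (otherwise omitted = unconstrained).
#' @param p_reversible probability that a state-change or binding rule is
#'   reversible.
#' @param seed RNG seed; identical config and seed give identical models.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_molecule_types = 3, comps_range = c(1, 4),
                             states_range = c(0, 3), n_rules = 6,
                             max_pattern_size = 3,
                             p_state_wildcard = 0.15,
                             p_bond_wildcard = 0.25,
                             p_context = 0.5, p_reversible = 0.25,
                             seed = 1) {
  cfg <- list(n_molecule_types = n_molecule_types,
              comps_range = comps_range, states_range = states_range,
              n_rules = n_rules, max_pattern_size = max_pattern_size,
              p_state_wildcard = p_state_wildcard,
              p_bond_wildcard = p_bond_wildcard,
              p_context = p_context, p_reversible = p_reversible,
              seed = seed)
  stopifnot(n_molecule_types >= 0, n_rules >= 0,
            all(comps_range >= 0), all(states_range >= 0),
            max_pattern_size >= 0)
  for (p in c(p_state_wildcard, p_bond_wildcard, p_context, p_reversible))
    if (p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (n_rules > 0 && (max_pattern_size == 0 || n_molecule_types == 0))
    stop("infeasible configuration: rules need molecules and patterns",
         call. = FALSE)
  structure(cfg, class = "generator_config")
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Generate a random, valid rule-based model
#'
#' Rules are drawn from archetypes (state change, binding, unbinding,
#' synthesis, degradation), each built so reactant and product sides are
#' coherent: the product is a copy of the reactant side with exactly the
#' intended sites changed, so context constraints are identical on both
#' sides by construction. The result always satisfies the full model
#' invariants (resolvable references, paired bond indices, connected
#' complex patterns) and is deterministic per seed.
#'
#' @param config a [generator_config()].
#' @return a validated `bngl_model`.
#' @export
random_model <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_preserved_rng(config$seed, generate_model(config))
}

generate_model <- function(cfg) {
  pick <- function(v) v[sample.int(length(v), 1)]   # no 1:n surprise
  types <- list()
  for (i in seq_len(cfg$n_molecule_types)) {
    nc <- pick(cfg$comps_range[1]:cfg$comps_range[2])
    nc <- max(nc, 1L)
    comps <- lapply(seq_len(nc), function(k) {
      ns <- pick(cfg$states_range[1]:cfg$states_range[2])
      if (ns == 1) ns <- 2   # a single allowed state is vacuous
      component_def(letters[k],
                    if (ns > 0) paste0("S", seq_len(ns) - 1) else character())
    })
    types[[i]] <- molecule_type(paste0("M", i), comps)
  }
  type_names <- vapply(types, `[[`, "", "name")

  stateful <- function(mt) which(vapply(mt$components, function(cd)
    length(cd$states) > 0, TRUE))

  # a partially constrained molecule pattern; `fix` names components that
  # must be present with the given constraints (list pos -> component_pattern)
  context_molecule <- function(ti, fix = list()) {
    mt <- types[[ti]]
    comps <- list()
    for (k in seq_along(mt$components)) {
      if (!is.null(fix[[as.character(k)]])) {
        comps[[length(comps) + 1]] <- fix[[as.character(k)]]
        next
      }
      if (stats::runif(1) >= cfg$p_context) next  # omitted: unconstrained
      cd <- mt$components[[k]]
      st <- NA_character_
      wild <- FALSE
      if (length(cd$states)) {
        if (stats::runif(1) < cfg$p_state_wildcard) wild <- TRUE
        else st <- pick(cd$states)
      }
      bk <- BOND_NONE
      if (stats::runif(1) < cfg$p_bond_wildcard)
        bk <- pick(c(BOND_ANY, BOND_PLUS))
      comps[[length(comps) + 1]] <-
        component_pattern(cd$name, state = st, state_wild = wild,
                          bond_kind = bk)
    }
    molecule_pattern(mt$name, comps)
  }

  fixed <- function(k, ...) {
    stats::setNames(list(component_pattern(...)), as.character(k))
  }

  concrete_molecule <- function(ti) {
    mt <- types[[ti]]
    comps <- lapply(seq_along(mt$components), function(k) {
      cd <- mt$components[[k]]
      component_pattern(cd$name,
                        state = if (length(cd$states)) pick(cd$states)
                        else NA_character_)
    })
    molecule_pattern(mt$name, comps)
  }

  rules <- list()
  params <- character()
  for (r in seq_len(cfg$n_rules)) {
    kind <- sample(c("state", "bind", "unbind", "synth", "degrade"), 1,
                   prob = c(0.35, 0.25, 0.15, 0.1, 0.15))
    stateful_types <- which(vapply(types, function(mt)
      length(stateful(mt)) > 0, TRUE))
    if (kind == "state" && !length(stateful_types)) kind <- "degrade"
    rev <- FALSE
    if (kind == "state") {
      ti <- if (length(stateful_types) == 1) stateful_types
      else pick(stateful_types)
      k <- pick(stateful(types[[ti]]))
      cd <- types[[ti]]$components[[k]]
      s1 <- pick(cd$states)
      s2 <- pick(cd$states)
      react <- context_molecule(ti, fixed(k, cd$name, state = s1))
      prod <- react
      for (q in seq_along(prod$comps))
        if (prod$comps[[q]]$name == cd$name &&
            identical(prod$comps[[q]]$state, s1)) {
          prod$comps[[q]]$state <- s2
          break
        }
      reactants <- list(complex_pattern(list(react)))
      products <- list(complex_pattern(list(prod)))
      rev <- stats::runif(1) < cfg$p_reversible
    } else if (kind %in% c("bind", "unbind")) {
      t1 <- pick(seq_along(types))
      t2 <- pick(seq_along(types))
      k1 <- pick(seq_along(types[[t1]]$components))
      k2 <- pick(seq_along(types[[t2]]$components))
      n1 <- types[[t1]]$components[[k1]]$name
      n2 <- types[[t2]]$components[[k2]]$name
      free1 <- context_molecule(t1, fixed(k1, n1, bond_kind = BOND_NONE))
      free2 <- context_molecule(t2, fixed(k2, n2, bond_kind = BOND_NONE))
      bound1 <- free1
      bound2 <- free2
      fix_bond <- function(mol, nm, kpos) {
        for (q in seq_along(mol$comps))
          if (mol$comps[[q]]$name == nm &&
              mol$comps[[q]]$bond$kind == BOND_NONE) {
            mol$comps[[q]]$bond <- list(kind = BOND_NUM, index = 1L)
            break
          }
        mol
      }
      bound1 <- fix_bond(bound1, n1, k1)
      bound2 <- fix_bond(bound2, n2, k2)
      if (kind == "bind") {
        reactants <- list(complex_pattern(list(free1)),
                          complex_pattern(list(free2)))
        products <- list(complex_pattern(list(bound1, bound2)))
        rev <- stats::runif(1) < cfg$p_reversible
      } else {
        reactants <- list(complex_pattern(list(bound1, bound2)))
        products <- list(complex_pattern(list(free1)),
                         complex_pattern(list(free2)))
      }
    } else if (kind == "synth") {
      ti <- pick(seq_along(types))
      reactants <- list()
      products <- list(complex_pattern(list(concrete_molecule(ti))))
    } else {  # degrade
      ti <- pick(seq_along(types))
      reactants <- list(complex_pattern(list(context_molecule(ti))))
      products <- list()
    }
    kf <- paste0("k", r, "f")
    params[kf] <- "1"
    if (rev) params[paste0("k", r, "r")] <- "1"
    rules[[r]] <- rule(reactants, products, rate_forward = kf,
                       rate_reverse = if (rev) paste0("k", r, "r"),
                       reversible = rev)
  }
  bngl_model(molecule_types = types, rules = rules, parameters = params,
             name = sprintf("random_seed%d", cfg$seed))
}

#' Instantiate a pattern as a concrete species
#'
#' Fills every wildcard deterministically: unconstrained or `~?` states
#' become the first allowed state, omitted components are added unbound,
#' `!?` becomes unbound. Patterns carrying `!+` cannot be instantiated
#' standalone (the partner is unspecified) and yield `NULL`.
#'
#' @param cx a resolved `complex_pattern`.
#' @param model the `bngl_model`.
#' @return a concrete species, or `NULL` when not instantiable.
#' @export
instantiate_pattern <- function(cx, model) {
  cx$molecules <- lapply(cx$molecules, expand_components, model = model)
  for (i in seq_along(cx$molecules)) {
    mol <- cx$molecules[[i]]
    mt <- model$molecule_types[[mol$type]]
    for (q in seq_along(mol$comps)) {
      cp <- mol$comps[[q]]
      if (cp$bond$kind == BOND_PLUS) return(NULL)
      if (cp$bond$kind == BOND_ANY)
        cp$bond <- list(kind = BOND_NONE, index = NA_integer_)
      states <- mt$components[[cp$type_pos]]$states
      if (length(states) && is.na(cp$state)) cp$state <- states[1]
      cp$state_wild <- FALSE
      cx$molecules[[i]]$comps[[q]] <- cp
    }
  }
  normalize_species(cx, model)
}
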