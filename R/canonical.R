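#' Canonical string form of a complex pattern
#'
#' Two complex patterns receive the same canonical string iff they are
#' isomorphic: there is a bijection of molecules (and their components)
#' preserving type names, compartments, component identity, state
#' constraints, bond constraints and bond topology. Omitted components
#' are semantically unconstrained and are expanded before serialization,
#' so `A(x~?)` and `A()` canonicalize identically for a type `A(x~U~P)`.
#'
#' The algorithm is exhaustive permutation canonicalization: molecules are
#' pre-sorted by an index-free signature, all permutations within groups
#' of equal signature are tried, bond indices are relabeled in first-use
#' order, and the lexicographically smallest serialization wins. Patterns
#' in rules are small (~10 molecules at most), so exhaustive search is
#' preferred over heuristic canonical labeling.
#'
#' @param cx a resolved `complex_pattern` (from a model or
#'   [parse_pattern()] with `model`).
#' @param model the `bngl_model` providing molecule type definitions.
#' @return a single canonical string.
#' @export
canonical_form <- function(cx, model) {
  full <- lapply(cx$molecules, expand_components, model = model)
  sigs <- vapply(full, molecule_signature, "")
  ord <- order(sigs)
  full <- full[ord]
  sigs <- sigs[ord]
  groups <- split(seq_along(sigs), sigs)
  perms <- permutation_candidates(groups, length(sigs))
  best <- NULL
  for (p in perms) {
    s <- serialize_ordered(full[p])
    if (is.null(best) || s < best) best <- s
  }
  best
}

# Expand a resolved molecule pattern to the full type component list in
# type order; omitted components become (ANY state, ANY bond).
expand_components <- function(mol, model) {
  mt <- model$molecule_types[[mol$type]]
  n <- length(mt$components)
  slots <- vector("list", n)
  for (cp in mol$comps) slots[[cp$type_pos]] <- cp
  for (k in seq_len(n)) {
    if (is.null(slots[[k]])) {
      cp <- component_pattern(mt$components[[k]]$name,
                              bond_kind = BOND_ANY)
      cp$type_pos <- k
      slots[[k]] <- cp
    }
  }
  mol$comps <- slots
  mol
}

# signature independent of bond index values and molecule order
molecule_signature <- function(mol) {
  comps <- vapply(mol$comps, function(cp) {
    st <- if (is.na(cp$state)) "?" else cp$state
    bk <- switch(cp$bond$kind, any = "?", none = "-", plus = "+", num = "#")
    paste0(cp$name, "~", st, "!", bk)
  }, "")
  paste0(mol$type, "@", if (is.na(mol$compartment)) "" else mol$compartment,
         "(", paste(comps, collapse = ","), ")")
}

# all molecule orderings obtained by permuting within equal-signature groups
permutation_candidates <- function(groups, n) {
  perm_lists <- lapply(groups, function(idx) {
    if (length(idx) == 1) list(idx) else all_perms(idx)
  })
  combos <- list(integer(0))
  for (pl in perm_lists) {
    combos <- unlist(lapply(combos, function(base)
      lapply(pl, function(p) c(base, p))), recursive = FALSE)
  }
  combos
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_perms(v[-i]), function(p) c(v[i], p)))
  out
}

serialize_ordered <- function(mols) {
  relabel <- integer(0)      # old bond index -> new
  next_id <- 1L
  parts <- character(length(mols))
  for (i in seq_along(mols)) {
    comps <- vapply(mols[[i]]$comps, function(cp) {
      st <- if (is.na(cp$state)) "?" else cp$state
      b <- cp$bond
      bs <- switch(b$kind, any = "!?", none = "", plus = "!+", num = {
        key <- as.character(b$index)
        if (is.na(relabel[key])) {
          relabel[key] <<- next_id
          next_id <<- next_id + 1L
        }
        paste0("!", relabel[key])
      })
      paste0(cp$name, "~", st, bs)
    }, "")
    parts[i] <- paste0(mols[[i]]$type, "@",
                       if (is.na(mols[[i]]$compartment)) ""
                       else mols[[i]]$compartment,
                       "(", paste(comps, collapse = ","), ")")
  }
  paste(parts, collapse = ".")
}
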