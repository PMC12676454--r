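# Independent brute-force oracles. These deliberately re-derive their
# answers from first principles (plain permutation search over expanded
# component lists) rather than calling the package's matching or
# canonicalization internals, so a bug in one path cannot hide in the
# other.

# full (state, bond-kind, bond-index) table of a pattern, one row per
# (molecule, type component); omitted components expand to wildcards
oracle_expand <- function(cx, model) {
  rows <- list()
  for (i in seq_along(cx$molecules)) {
    mol <- cx$molecules[[i]]
    mt <- model$molecule_types[[mol$type]]
    n <- length(mt$components)
    st <- rep(NA_character_, n)
    bk <- rep("any", n)
    bi <- rep(NA_integer_, n)
    for (cp in mol$comps) {
      st[cp$type_pos] <- cp$state
      bk[cp$type_pos] <- cp$bond$kind
      bi[cp$type_pos] <- cp$bond$index
    }
    rows[[i]] <- list(type = mol$type, compartment = mol$compartment,
                      state = st, bond_kind = bk, bond_index = bi)
  }
  rows
}

oracle_perms <- function(n) {
  if (n == 0) return(list(integer(0)))
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1))
    for (pos in seq_len(n))
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
  out
}

# every injective map of pattern molecules into species molecules, checked
# by direct constraint comparison; returns the number of embeddings
oracle_count_embeddings <- function(pattern, species, model) {
  pm <- oracle_expand(pattern, model)
  sm <- oracle_expand(species, model)
  np <- length(pm)
  ns <- length(sm)
  if (np > ns) return(0L)
  count <- 0L
  # choose an ordered selection of np distinct species indices
  sel <- function(chosen, remaining) {
    if (length(chosen) == np) {
      if (oracle_check(pm, sm, chosen)) count <<- count + 1L
      return(invisible(NULL))
    }
    for (j in remaining) sel(c(chosen, j), setdiff(remaining, j))
  }
  sel(integer(0), seq_len(ns))
  count
}

oracle_check <- function(pm, sm, map) {
  for (i in seq_along(pm)) {
    p <- pm[[i]]
    s <- sm[[map[i]]]
    if (p$type != s$type) return(FALSE)
    if (!is.na(p$compartment) &&
        (is.na(s$compartment) || p$compartment != s$compartment))
      return(FALSE)
    for (k in seq_along(p$state)) {
      if (!is.na(p$state[k]) &&
          (is.na(s$state[k]) || p$state[k] != s$state[k])) return(FALSE)
      pk <- p$bond_kind[k]
      sk <- s$bond_kind[k]
      if (pk == "none" && sk != "none") return(FALSE)
      if (pk == "plus" && sk != "num") return(FALSE)
      if (pk == "num" && sk != "num") return(FALSE)
    }
  }
  oracle_bonds_ok(pm, sm, map)
}

# separate pass: explicit pattern bonds map onto shared species bonds
oracle_bonds_ok <- function(pm, sm, map) {
  ends <- list()
  for (i in seq_along(pm)) {
    p <- pm[[i]]
    for (k in seq_along(p$bond_kind)) {
      if (p$bond_kind[k] == "num") {
        key <- as.character(p$bond_index[k])
        ends[[key]] <- c(ends[[key]],
                         list(c(mol = map[i], comp = k)))
      }
    }
  }
  for (key in names(ends)) {
    ep <- ends[[key]]
    if (length(ep) != 2) return(FALSE)
    b1 <- sm[[ep[[1]]["mol"]]]$bond_index[ep[[1]]["comp"]]
    b2 <- sm[[ep[[2]]["mol"]]]$bond_index[ep[[2]]["comp"]]
    if (is.na(b1) || is.na(b2) || b1 != b2) return(FALSE)
  }
  TRUE
}

# brute-force isomorphism of two complex patterns: try every bijection of
# molecules and compare expanded tables with bond relabeling
oracle_isomorphic <- function(a, b, model) {
  ta <- oracle_expand(a, model)
  tb <- oracle_expand(b, model)
  if (length(ta) != length(tb)) return(FALSE)
  for (perm in oracle_perms(length(ta))) {
    if (oracle_iso_under(ta, tb, perm)) return(TRUE)
  }
  FALSE
}

oracle_iso_under <- function(ta, tb, perm) {
  relabel <- character(0)   # a-bond-id -> b-bond-id
  for (i in seq_along(ta)) {
    x <- ta[[i]]
    y <- tb[[perm[i]]]
    if (x$type != y$type) return(FALSE)
    if (!identical(x$compartment, y$compartment) &&
        !(is.na(x$compartment) && is.na(y$compartment))) return(FALSE)
    for (k in seq_along(x$state)) {
      if (!identical(is.na(x$state[k]), is.na(y$state[k]))) return(FALSE)
      if (!is.na(x$state[k]) && x$state[k] != y$state[k]) return(FALSE)
      if (x$bond_kind[k] != y$bond_kind[k]) return(FALSE)
      if (x$bond_kind[k] == "num") {
        key <- as.character(x$bond_index[k])
        val <- as.character(y$bond_index[k])
        if (is.na(relabel[key])) relabel[key] <- val
        else if (relabel[key] != val) return(FALSE)
      }
    }
  }
  # relabeling must be injective
  !anyDuplicated(relabel)
}

# random isomorphic variant: permute molecules, relabel bond indices
shuffle_pattern <- function(cx, perm = sample(length(cx$molecules)),
                            bond_shift = 10L) {
  cx$molecules <- cx$molecules[perm]
  for (i in seq_along(cx$molecules)) {
    for (q in seq_along(cx$molecules[[i]]$comps)) {
      b <- cx$molecules[[i]]$comps[[q]]$bond
      if (b$kind == "num")
        cx$molecules[[i]]$comps[[q]]$bond$index <- b$index + bond_shift
    }
  }
  cx
}

# Expansion consistency: the concrete sites that differ between the
# reactant and product species of every traced reaction must be exactly
# the image of the rule's MODIFIED sites under the embedding. The diff is
# computed here from the species structures alone, independently of how
# the expansion applied its changes.
check_expansion_consistency <- function(rule, res, model) {
  corr <- map_rule_molecules(rule)
  cls <- classify_sites(rule, corr, model)
  for (rx in res$reactions) {
    tr <- rx$trace
    # combined reactant molecule tables, bond ids namespaced per instance
    combined <- list()
    offsets <- integer(length(tr$species))
    for (i in seq_along(tr$species)) {
      offsets[i] <- length(combined)
      tab <- oracle_expand(tr$species[[i]], model)
      for (mrow in tab) {
        mrow$bond_ns <- ifelse(is.na(mrow$bond_index), NA_character_,
                               paste0(i, ":", mrow$bond_index))
        combined[[length(combined) + 1]] <- mrow
      }
    }
    partner_of <- function(tabs, bond_ns, self) {
      for (j in seq_along(tabs)) {
        hit <- which(!is.na(tabs[[j]]$bond_ns) & tabs[[j]]$bond_ns == bond_ns)
        for (k in hit) if (!(j == self["mol"] && k == self["comp"]))
          return(c(mol = j, comp = k))
      }
      NULL
    }
    # product tables with provenance
    ptabs <- list()
    porigin <- integer(0)
    for (q in seq_along(tr$products)) {
      tab <- oracle_expand(tr$products[[q]], model)
      orig <- attr(tr$products[[q]], "origins")
      for (w in seq_along(tab)) {
        tab[[w]]$bond_ns <- ifelse(is.na(tab[[w]]$bond_index),
                                   NA_character_,
                                   paste0("p", q, ":", tab[[w]]$bond_index))
        ptabs[[length(ptabs) + 1]] <- tab[[w]]
        porigin[length(ptabs)] <- orig[w]
      }
    }
    where_in_products <- match(seq_along(combined), porigin)
    diffs <- character(0)
    for (ci in seq_along(combined)) {
      rm_ <- combined[[ci]]
      pj <- where_in_products[ci]
      if (is.na(pj)) {   # destroyed: every site differs
        diffs <- c(diffs, paste0(ci, "/", seq_along(rm_$state)))
        next
      }
      pm_ <- ptabs[[pj]]
      for (k in seq_along(rm_$state)) {
        changed <- FALSE
        if (!identical(rm_$state[k], pm_$state[k])) changed <- TRUE
        r_bound <- !is.na(rm_$bond_index[k])
        p_bound <- !is.na(pm_$bond_index[k])
        if (r_bound != p_bound) changed <- TRUE
        else if (r_bound && p_bound) {
          rp <- partner_of(list_single(combined), rm_$bond_ns[k],
                           c(mol = ci, comp = k))
          pp <- partner_of(list_single(ptabs), pm_$bond_ns[k],
                           c(mol = pj, comp = k))
          # compare partner provenance
          r_partner <- rp["mol"]
          p_partner <- porigin[pp["mol"]]
          if (is.na(p_partner) || r_partner != p_partner ||
              rp["comp"] != pp["comp"]) changed <- TRUE
        }
        if (changed) diffs <- c(diffs, paste0(ci, "/", k))
      }
    }
    # image of MODIFIED reactant-side sites under the embedding
    e <- cls$entries[cls$entries$side == "reactant" &
                       grepl("MODIFIED", cls$entries$label), , drop = FALSE]
    image <- character(0)
    if (nrow(e)) for (r in seq_len(nrow(e))) {
      en <- e[r, ]
      ci <- offsets[en$r_pat] + tr$mol_maps[[en$r_pat]][en$r_mol]
      image <- c(image, paste0(ci, "/", en$comp_pos))
    }
    testthat::expect_setequal(diffs, image)
  }
  invisible(NULL)
}

# wrap per-molecule tables so partner_of can scan them uniformly
list_single <- function(tabs) tabs

no_overlap <- function(lay) {
  n <- nrow(lay)
  if (n < 2) return(invisible(NULL))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sep <- lay$x[i] + lay$w[i] <= lay$x[j] ||
      lay$x[j] + lay$w[j] <= lay$x[i] ||
      lay$y[i] + lay$h[i] <= lay$y[j] ||
      lay$y[j] + lay$h[j] <= lay$y[i]
    testthat::expect_true(sep, label = paste("no overlap of", lay$id[i],
                                             "and", lay$id[j]))
  }
  invisible(NULL)
}

# shared tiny helpers ----------------------------------------------------

egfr <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- egfr_model()
    cache
  }
})

egfr_seeds <- function(m = egfr()) lapply(m$seed_species, `[[`, "species")

reactant_site_count <- function(rule, model) {
  sum(vapply(rule$reactants, function(cx) sum(vapply(cx$molecules,
    function(mol) length(model$molecule_types[[mol$type]]$components),
    1L)), 1L))
}
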