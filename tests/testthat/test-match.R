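test_that("bond and state constraints gate embeddings as drawn", {
  m <- egfr()
  bound <- concrete_species("EGF(site!1).EGFR(ecd!1,tmd,Y1~U,Y2~U)", m)
  free <- concrete_species("EGFR(ecd,tmd,Y1~P,Y2~U)", m)
  # a listed site without a bond must be unbound
  expect_length(match_pattern(parse_pattern("EGFR(ecd)", m), bound, m), 0)
  expect_length(match_pattern(parse_pattern("EGFR(ecd)", m), free, m), 1)
  # "?" wildcards match anything
  expect_length(match_pattern(parse_pattern("EGFR(Y1~?!?)", m), free, m), 1)
  expect_length(match_pattern(parse_pattern("EGFR(ecd!?)", m), bound, m), 1)
  # "+" requires some bond
  expect_length(match_pattern(parse_pattern("EGFR(ecd!+)", m), bound, m), 1)
  expect_length(match_pattern(parse_pattern("EGFR(ecd!+)", m), free, m), 0)
  # explicit bonds must land on a shared species bond
  expect_length(match_pattern(
    parse_pattern("EGF(site!3).EGFR(ecd!3)", m), bound, m), 1)
  # state mismatch
  expect_length(match_pattern(parse_pattern("EGFR(Y1~U)", m), free, m), 0)
})

test_that("symmetric patterns produce automorphic embeddings", {
  m <- egfr()
  dimer <- concrete_species(
    "EGFR(ecd,tmd!1,Y1~U,Y2~U).EGFR(ecd,tmd!1,Y1~P,Y2~P)", m)
  embs <- match_pattern(parse_pattern("EGFR(tmd!1).EGFR(tmd!1)", m),
                        dimer, m)
  expect_length(embs, 2)   # the two orientations of the dimer
  embs2 <- match_pattern(parse_pattern("EGFR(tmd!1).EGFR(tmd!1,Y1~U)", m),
                         dimer, m)
  expect_length(embs2, 1)
})

test_that("embedding counts agree with the brute-force oracle", {
  m <- egfr()
  species <- c(egfr_seeds(m), list(
    concrete_species("EGF(site!1).EGFR(ecd!1,tmd,Y1~P,Y2~U)", m),
    concrete_species(
      "EGFR(ecd,tmd!1,Y1~U,Y2~U).EGFR(ecd,tmd!1,Y1~P,Y2~P)", m),
    concrete_species(
      "EGFR(ecd,tmd!1,Y1~U,Y2~U).EGFR(ecd,tmd!1,Y1~U,Y2~U)", m)))
  pats <- lapply(c("EGF(site)", "EGFR(ecd)", "EGFR(ecd!+,tmd)",
                   "EGFR(Y1~U)", "EGFR(tmd!1).EGFR(tmd!1)",
                   "EGFR(tmd!1).EGFR(tmd!1,Y1~U)",
                   "EGF(site!2).EGFR(ecd!2)"),
                 parse_pattern, model = m)
  for (p in pats) for (sp in species) {
    expect_equal(length(match_pattern(p, sp, m)),
                 oracle_count_embeddings(p, sp, m),
                 info = pattern_to_string(p))
  }
  # and on random models with instantiated patterns
  for (s in c(2, 9, 27)) {
    rm <- random_model(generator_config(seed = s))
    sps <- list()
    for (r in rm$rules) for (cx in c(r$reactants, r$products)) {
      inst <- instantiate_pattern(cx, rm)
      if (!is.null(inst)) sps[[length(sps) + 1]] <- inst
    }
    pats <- unlist(lapply(rm$rules, function(r) r$reactants),
                   recursive = FALSE)
    for (p in pats) for (sp in sps) {
      expect_equal(length(match_pattern(p, sp, rm)),
                   oracle_count_embeddings(p, sp, rm),
                   info = paste("seed", s, pattern_to_string(p)))
    }
  }
})

test_that("the binding rule expands to four reactions over the seed set", {
  m <- egfr()
  res <- expand_rule(m$rules[[1]], egfr_seeds(m), m)
  expect_length(res$reactions, 4)
  expect_false(res$fixed_point)   # products are new species
  # with one receptor species only, a single reaction
  res1 <- expand_rule(m$rules[[1]], list(
    egfr_seeds(m)[[1]],
    concrete_species("EGFR(ecd,tmd,Y1~U,Y2~U)", m)), m)
  expect_length(res1$reactions, 1)
})

test_that("expansion is invariant to seed order and bond relabeling", {
  m <- egfr()
  dimer_seeds <- lapply(
    c("EGFR(ecd,tmd!1,Y1~U,Y2~U).EGFR(ecd,tmd!1,Y1~U,Y2~P)",
      "EGFR(ecd,tmd!4,Y1~P,Y2~U).EGFR(ecd,tmd!4,Y1~U,Y2~U)"),
    concrete_species, model = m)
  r5 <- m$rules[[5]]
  base <- expand_rule(r5, dimer_seeds, m)
  flip <- expand_rule(r5, rev(dimer_seeds), m)
  key <- function(res) sort(vapply(res$reactions, function(x)
    paste(paste(x$reactants, collapse = "+"), "->",
          paste(x$products, collapse = "+")), ""))
  expect_equal(key(flip), key(base))
  # transphosphorylation applied to one symmetric dimer gives one
  # reaction (automorphic embeddings collapse)
  sym <- concrete_species(
    "EGFR(ecd,tmd!1,Y1~U,Y2~U).EGFR(ecd,tmd!1,Y1~U,Y2~U)", m)
  expect_length(expand_rule(r5, list(sym), m)$reactions, 1)
})

test_that("iterative expansion reaches a fixed point and respects caps", {
  m <- egfr()
  res <- expand_rule(m$rules[[2]], list(
    concrete_species("EGFR(ecd,tmd,Y1~P,Y2~P)", m)), m,
    max_iterations = 5)
  expect_true(res$fixed_point)
  expect_length(res$species, 2)   # Y1~P and Y1~U variants
  expect_error(
    expand_rule(m$rules[[1]], egfr_seeds(m), m, max_iterations = 2,
                species_cap = 5),
    "cap", class = "mpd_expand_error")
})

test_that("degradation splits and synthesis creates fully specified species", {
  m <- parse_model(c(
    "begin molecule types", "A(x,y~U~P)", "B(z)", "end molecule types",
    "begin reaction rules",
    "A(x!1).B(z!1) -> A(x) + B(z) kunb",
    "0 -> A(x,y~U) ksyn",
    "A() -> 0 kdeg",
    "end reaction rules"))
  ab <- concrete_species("A(x!1,y~P).B(z!1)", m)
  res <- expand_rule(m$rules[[1]], list(ab), m)
  expect_length(res$reactions, 1)
  expect_length(res$reactions[[1]]$products, 2)
  syn <- expand_rule(m$rules[[2]], list(), m)
  expect_length(syn$reactions, 1)
  expect_equal(syn$reactions[[1]]$reactants, character(0))
  deg <- expand_rule(m$rules[[3]], list(ab), m)
  expect_length(deg$reactions, 1)
  # degrading A out of the A.B complex leaves free B
  expect_length(deg$reactions[[1]]$products, 1)
  expect_match(deg$reactions[[1]]$products, "^B")
})

test_that("concrete reaction diffs equal the MODIFIED image (fixture)", {
  m <- egfr()
  pool <- egfr_seeds(m)
  # grow the pool so every rule has matches
  pool <- unname(expand_rule(m$rules[[1]], pool, m,
                             max_iterations = 2)$species)
  pool <- unname(expand_rule(m$rules[[4]], pool, m,
                             max_iterations = 2)$species)
  for (r in m$rules) {
    res <- expand_rule(r, pool, m, trace = TRUE)
    check_expansion_consistency(r, res, m)
  }
})

test_that("concrete reaction diffs equal the MODIFIED image (corpus)", {
  for (s in c(5, 18, 23, 36, 49)) {
    m <- random_model(generator_config(seed = s))
    seeds <- list()
    for (r in m$rules) for (cx in r$reactants) {
      inst <- instantiate_pattern(cx, m)
      if (!is.null(inst)) seeds[[length(seeds) + 1]] <- inst
    }
    for (r in m$rules) {
      res <- tryCatch(expand_rule(r, seeds, m, trace = TRUE),
                      mpd_expand_error = function(e) NULL)
      if (is.null(res)) next
      check_expansion_consistency(r, res, m)
    }
  }
})

test_that("state spaces multiply out over components", {
  nine <- molecule_type("R", lapply(1:9, function(i)
    component_def(paste0("y", i), c("U", "P"))))
  expect_equal(enumerate_states(nine), 512)
  expect_equal(enumerate_states(molecule_type("B", list(
    component_def("a"), component_def("b")))), 1)
  m <- egfr()
  es <- enumerate_states(m$molecule_types[["EGFR"]], list_states = TRUE)
  expect_equal(es$count, 4)
  expect_equal(nrow(es$states), 4)
  expect_named(es$states, c("Y1", "Y2"))
})
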