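reverse_rule <- function(r) {
  rule(r$products, r$reactants, rate_forward = r$rate_forward,
       reversible = FALSE, id = r$id)
}

test_that("molecule correspondence pairs by type, leftmost first", {
  m <- egfr()
  corr <- map_rule_molecules(m$rules[[1]])
  expect_equal(nrow(corr$pairs), 2)
  expect_setequal(corr$pairs$type, c("EGF", "EGFR"))
  expect_equal(nrow(corr$created), 0)
  expect_equal(nrow(corr$destroyed), 0)

  mt <- molecule_type("A", list(component_def("x")))
  deg <- rule(list(parse_pattern("A(x)")), list(), rate_forward = "k")
  md <- bngl_model(list(mt), list(deg))
  cd <- map_rule_molecules(md$rules[[1]])
  expect_equal(nrow(cd$pairs), 0)
  expect_equal(cd$destroyed$type, "A")

  # surplus on both sides triggers a provenance note
  dim2 <- parse_model(c(
    "begin molecule types", "A(x,y)", "end molecule types",
    "begin reaction rules",
    "A(x) + A(x) -> A(x!1).A(x!1) k", "end reaction rules"))
  cc <- map_rule_molecules(dim2$rules[[1]])
  expect_equal(nrow(cc$pairs), 2)
  expect_match(cc$notes, "leftmost-first")
})

test_that("the fixture rules classify exactly as the three-layer semantics", {
  m <- egfr()
  lab <- function(cls, type, comp) {
    e <- cls$entries
    unique(e$label[e$side == "reactant" & e$type == type &
                     e$comp_name == comp])
  }
  # binding: EGF.site and EGFR.ecd modified bonds; tmd context (unbound
  # required); tyrosines irrelevant
  c1 <- classify_sites(m$rules[[1]], model = m)
  expect_equal(lab(c1, "EGF", "site"), "MODIFIED_BOND")
  expect_equal(lab(c1, "EGFR", "ecd"), "MODIFIED_BOND")
  expect_equal(lab(c1, "EGFR", "tmd"), "CONTEXT")
  expect_equal(lab(c1, "EGFR", "Y1"), "UNCONSTRAINED")
  expect_equal(lab(c1, "EGFR", "Y2"), "UNCONSTRAINED")
  e1 <- c1$entries
  bond_row <- e1[e1$type == "EGFR" & e1$comp_name == "ecd", ]
  expect_equal(bond_row$before_bondclass, "UNBOUND")
  expect_equal(bond_row$after_bondclass, "BOUND")

  # dimerization: ecd bound context, tmd forms the bond
  c4 <- classify_sites(m$rules[[4]], model = m)
  expect_equal(lab(c4, "EGFR", "ecd"), "CONTEXT")
  expect_equal(lab(c4, "EGFR", "tmd"), "MODIFIED_BOND")

  # transphosphorylation: Y1 state change on one monomer, tmd context both
  c5 <- classify_sites(m$rules[[5]], model = m)
  e5 <- c5$entries[c5$entries$side == "reactant", ]
  y1 <- e5[e5$comp_name == "Y1", ]
  expect_setequal(y1$label, c("MODIFIED_STATE", "UNCONSTRAINED"))
  mod <- y1[y1$label == "MODIFIED_STATE", ]
  expect_equal(mod$before_state, "U")
  expect_equal(mod$after_state, "P")
  expect_equal(unique(e5$label[e5$comp_name == "tmd"]), "CONTEXT")
})

test_that("identity rules yield zero modified sites", {
  m <- parse_model(c("begin molecule types", "A(x~U~P,y)",
                     "end molecule types",
                     "begin reaction rules",
                     "A(x~U,y) -> A(x~U,y) k",
                     "end reaction rules"))
  cls <- classify_sites(m$rules[[1]], model = m)
  expect_false(any(grepl("MODIFIED", cls$entries$label)))
  expect_setequal(cls$entries$label[cls$entries$comp_name == "x"], "CONTEXT")
})

test_that("wildcard-to-concrete product constraints warn but never drop", {
  m <- parse_model(c("begin molecule types", "A(x~U~P)",
                     "end molecule types",
                     "begin reaction rules",
                     "A() -> A(x~P!?) k",
                     "end reaction rules"))
  cls <- classify_sites(m$rules[[1]], model = m)
  expect_equal(cls$entries$label, "MODIFIED_STATE")
  expect_match(cls$warnings, "wildcard state", all = FALSE)

  # a listed product site also constrains the bond: wildcard -> unbound
  m2 <- parse_model(c("begin molecule types", "A(x~U~P)",
                      "end molecule types",
                      "begin reaction rules",
                      "A() -> A(x~P) k",
                      "end reaction rules"))
  cls2 <- classify_sites(m2$rules[[1]], model = m2)
  expect_equal(cls2$entries$label, "MODIFIED_BOTH")
})

test_that("wildcard bonds on both sides never count as modification", {
  m <- parse_model(c("begin molecule types", "A(x,y~U~P)",
                     "end molecule types",
                     "begin reaction rules",
                     "A(x!?,y~U) -> A(x!?,y~P) k",
                     "end reaction rules"))
  cls <- classify_sites(m$rules[[1]], model = m)
  e <- cls$entries
  expect_equal(e$label[e$comp_name == "x"], "UNCONSTRAINED")
  expect_equal(e$label[e$comp_name == "y"], "MODIFIED_STATE")
})

test_that("labels partition all reactant-side sites on the random corpus", {
  for (s in 1:100) {
    m <- random_model(generator_config(seed = s))
    for (r in m$rules) {
      cls <- classify_sites(r, model = m)
      e <- cls$entries[cls$entries$side == "reactant", ]
      expect_equal(nrow(e), reactant_site_count(r, m),
                   info = paste("seed", s, r$id))
      expect_true(all(e$label %in% c("MODIFIED_STATE", "MODIFIED_BOND",
                                     "MODIFIED_BOTH", "CONTEXT",
                                     "UNCONSTRAINED")))
      # context sites carry at least one real constraint
      ctx <- e[e$label == "CONTEXT", ]
      expect_true(all(!is.na(ctx$before_state) |
                        ctx$before_bondclass != "ANY"))
      unc <- e[e$label == "UNCONSTRAINED", ]
      expect_true(all(is.na(unc$before_state) &
                        unc$before_bondclass == "ANY"))
    }
  }
})

test_that("classification of the reversed rule mirrors modified records", {
  for (s in c(1, 7, 19, 33)) {
    m <- random_model(generator_config(seed = s))
    for (r in m$rules) {
      if (!length(r$reactants) || !length(r$products)) next
      fwd <- classify_sites(r, model = m)
      bwd <- classify_sites(reverse_rule(r), model = m)
      f <- fwd$entries[fwd$entries$side == "reactant" &
                         !is.na(fwd$entries$p_pat), ]
      b <- bwd$entries[bwd$entries$side == "reactant" &
                         !is.na(bwd$entries$p_pat), ]
      key <- function(d) order(d$type, d$p_pat, d$p_mol, d$comp_pos)
      f <- f[order(f$type, f$r_pat, f$r_mol, f$comp_pos), ]
      b <- b[order(b$type, b$p_pat, b$p_mol, b$comp_pos), ]
      expect_equal(nrow(f), nrow(b))
      expect_equal(b$before_state, f$after_state)
      expect_equal(b$after_state, f$before_state)
      expect_equal(b$before_bondclass, f$after_bondclass)
      expect_equal(b$after_bondclass, f$before_bondclass)
      expect_equal(b$label[b$label %in% c("CONTEXT", "UNCONSTRAINED")],
                   f$label[f$label %in% c("CONTEXT", "UNCONSTRAINED")])
    }
  }
})

test_that("the site classification dump covers every rule of the fixture", {
  tab <- site_classification_table(egfr())
  expect_named(tab, c("rule_id", "molecule", "component", "label",
                      "before", "after"))
  expect_setequal(unique(tab$rule_id), paste0("R", 1:6))
  expect_equal(sum(tab$rule_id == "R1"), 5)  # EGF.site + 4 EGFR sites
})
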