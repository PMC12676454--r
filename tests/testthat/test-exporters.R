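test_that("layout ranks the fixture left-to-right and never overlaps", {
  g <- build_mpd(egfr(), 1)
  lay <- mpd_layout(g)
  rank_of <- function(id) lay$rank[lay$id == id]
  # hand-computed longest-path ranks on the fixture graph
  expect_equal(rank_of("c:EGF"), 0)
  expect_equal(rank_of("c:EGFR"), 0)
  expect_equal(rank_of("p:R1"), 1)
  expect_equal(rank_of("c:EGF|EGFR"), 2)
  expect_equal(rank_of("c:EGFR|EGFR"), 2)
  expect_equal(rank_of("p:R5"), 3)
  no_overlap(lay)
  # determinism
  expect_identical(lay, mpd_layout(build_mpd(egfr(), 1)))
  # empty graph
  empty <- build_mpd(parse_model(c("begin molecule types", "A(x)",
                                   "end molecule types",
                                   "begin reaction rules",
                                   "end reaction rules")), 1)
  expect_equal(nrow(mpd_layout(empty)), 0)
})

test_that("layouts of random graphs never overlap", {
  for (s in c(4, 11, 58)) {
    g <- build_mpd(random_model(generator_config(seed = s)), 2)
    no_overlap(mpd_layout(g))
  }
})

test_that("GraphML round-trips the fixture at every level", {
  m <- egfr()
  for (lv in 1:3) {
    g <- build_mpd(m, lv)
    expect_equal(read_graphml(to_graphml(g, mpd_layout(g))), g)
    expect_equal(read_graphml(to_graphml(g)), g)   # graphics optional
  }
  # node count in the XML is forced by the graph
  g <- build_mpd(m, 1)
  doc <- xml2::read_xml(as.character(to_graphml(g)))
  nodes <- xml2::xml_find_all(
    doc, "//*[local-name() = 'node']")
  expect_length(nodes, length(g$complex_nodes) + length(g$process_nodes))
})

test_that("GraphML round-trips across the random corpus", {
  for (s in 1:100) {
    g <- build_mpd(random_model(generator_config(seed = s)), 3)
    expect_equal(read_graphml(to_graphml(g)), g, info = paste("seed", s))
  }
})

test_that("file-based GraphML export reads back equal", {
  g <- build_mpd(egfr(), 2)
  path <- withr::local_tempfile(fileext = ".graphml")
  to_graphml(g, file = path)
  expect_equal(read_graphml(path), g)
})

test_that("SBGN-ML documents are structurally valid PD maps", {
  g <- build_mpd(egfr(), 3)
  lay <- mpd_layout(g)
  doc <- xml2::read_xml(as.character(to_sbgnml(g, lay, level = 3)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  expect_equal(xml2::xml_name(xml2::xml_root(doc)), "sbgn")
  expect_equal(xml2::xml_attr(xml2::xml_find_first(doc, "//s:map", ns),
                              "language"), "process description")
  glyphs <- xml2::xml_find_all(doc, "//s:glyph", ns)
  ids <- xml2::xml_attr(glyphs, "id")
  expect_false(anyDuplicated(ids) > 0)
  # every glyph carries a bbox
  for (gl in glyphs)
    expect_length(xml2::xml_find_all(gl, "./s:bbox", ns), 1)
  # arcs reference existing glyph ids
  arcs <- xml2::xml_find_all(doc, "//s:arc", ns)
  expect_length(arcs, length(g$arcs))
  for (a in arcs) {
    expect_true(xml2::xml_attr(a, "source") %in% ids)
    expect_true(xml2::xml_attr(a, "target") %in% ids)
    expect_true(xml2::xml_attr(a, "class") %in%
                  c("consumption", "production"))
  }
})

test_that("glyph classes follow composition: multimer, complex, state vars", {
  g <- build_mpd(egfr(), 1)
  doc <- xml2::read_xml(as.character(to_sbgnml(g, mpd_layout(g))))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  class_of <- function(label) {
    for (gl in xml2::xml_find_all(doc, "//s:map/s:glyph", ns)) {
      lb <- xml2::xml_find_first(gl, "./s:label", ns)
      if (!inherits(lb, "xml_missing") &&
          identical(xml2::xml_attr(lb, "text"), label))
        return(xml2::xml_attr(gl, "class"))
    }
    NA_character_
  }
  expect_equal(class_of("EGF"), "macromolecule")
  expect_equal(class_of("EGF·EGFR"), "complex")
  # the homodimer renders as a multimer with cardinality N:2
  dimer <- Filter(function(gl)
    xml2::xml_attr(gl, "class") == "macromolecule multimer",
    xml2::xml_find_all(doc, "//s:map/s:glyph", ns))
  expect_length(dimer, 1)
  card <- xml2::xml_find_first(dimer[[1]],
                               ".//s:glyph[@class='unit of information']",
                               ns)
  expect_equal(xml2::xml_attr(xml2::xml_find_first(card, "./s:label", ns),
                              "text"), "N:2")
  # state variables once per molecule: EGFR macromolecule shows 4 sites
  egfr_glyph <- Filter(function(gl)
    xml2::xml_attr(gl, "class") == "macromolecule" &&
      identical(xml2::xml_attr(
        xml2::xml_find_first(gl, "./s:label", ns), "text"), "EGFR"),
    xml2::xml_find_all(doc, "//s:map/s:glyph", ns))
  svs <- xml2::xml_find_all(egfr_glyph[[1]],
                            "./s:glyph[@class='state variable']", ns)
  expect_setequal(
    xml2::xml_attr(xml2::xml_find_all(svs, "./s:state", ns), "variable"),
    c("ecd", "tmd", "Y1", "Y2"))
  # processes: one glyph per rule
  expect_length(xml2::xml_find_all(doc, "//s:glyph[@class='process']", ns),
                6)
})

test_that("level-2/3 annotations ride in extensions with figure labels", {
  g <- build_mpd(egfr(), 3)
  lay <- mpd_layout(g)
  doc3 <- xml2::read_xml(as.character(to_sbgnml(g, lay, level = 3)))
  txt3 <- as.character(doc3)
  expect_match(txt3, "P@Y1")          # production-side state label
  expect_match(txt3, "unbound@tmd")   # binding context
  expect_match(txt3, "bound@ecd")     # dimerization context
  # annotations only inside extension elements
  anns <- xml2::xml_find_all(doc3, "//*[local-name()='site' or
                                        local-name()='context']")
  expect_gt(length(anns), 0)
  for (a in anns)
    expect_true("extension" %in% xml2::xml_name(xml2::xml_parents(a)))
  # level bound respected
  expect_error(to_sbgnml(build_mpd(egfr(), 1), lay, level = 2), "level")
  # level 2 drops context but keeps site labels
  txt2 <- as.character(to_sbgnml(g, lay, level = 2))
  expect_match(txt2, "P@Y1")
  expect_no_match(txt2, "unbound@tmd")
  # stoichiometry 2 on the dimerization arc as a cardinality glyph
  card <- xml2::xml_find_all(doc3, "//*[local-name()='arc']//
                             *[local-name()='glyph'][@class='cardinality']")
  expect_length(card, 1)
})

test_that("stripping extensions from level 3 reproduces level 1 exactly", {
  m <- egfr()
  lay <- mpd_layout(build_mpd(m, 1))
  s1 <- as.character(to_sbgnml(build_mpd(m, 1), lay, level = 1))
  s3 <- to_sbgnml(build_mpd(m, 3), lay, level = 3)
  expect_identical(as.character(strip_mpd_extensions(s3)), s1)
  # also for a random model
  rm <- random_model(generator_config(seed = 13))
  layr <- mpd_layout(build_mpd(rm, 1))
  r1 <- as.character(to_sbgnml(build_mpd(rm, 1), layr, level = 1))
  r3 <- to_sbgnml(build_mpd(rm, 3), layr, level = 3)
  expect_identical(as.character(strip_mpd_extensions(r3)), r1)
})

test_that("DOT output lists every node and arc deterministically", {
  g <- build_mpd(egfr(), 2)
  d <- to_dot(g)
  lines <- strsplit(d, "\n")[[1]]
  expect_length(grep("shape=", lines), 10)   # 4 complexes + 6 processes
  expect_length(grep("->", lines, fixed = TRUE), length(g$arcs))
  expect_identical(to_dot(build_mpd(egfr(), 2)), d)
  expect_match(d, 'label="2')   # dimerization stoichiometry
  # empty graph: header-only digraph
  empty <- build_mpd(parse_model(c("begin molecule types", "A(x)",
                                   "end molecule types",
                                   "begin reaction rules",
                                   "end reaction rules")), 1)
  expect_length(grep("->", strsplit(to_dot(empty), "\n")[[1]]), 0)
})
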