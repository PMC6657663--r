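ns_basic <- c(ex = NS_EX, rdf = NS_RDF, rdfs = NS_RDFS, xsd = NS_XSD)

test_that("map_namespaces emits the prefix table in canonical order", {
  out <- map_namespaces(c(rdfs = NS_RDFS, rdf = NS_RDF))
  expect_equal(json_serialize(out, "minified"),
               sprintf('{"rdf":"%s","rdfs":"%s"}', NS_RDF, NS_RDFS))
  expect_equal(json_serialize(map_namespaces(character(0)), "minified"), "{}")
  out2 <- map_namespaces(c(sbmlRdf = "http://sbml.org/sbmlRdf#"))
  expect_equal(out2[["sbmlRdf"]], "http://sbml.org/sbmlRdf#")
})

test_that("compact_iri abbreviates with the longest matching namespace", {
  ns <- c(sbmlRdf = "http://sbml.org/sbmlRdf#")
  expect_equal(compact_iri("http://sbml.org/sbmlRdf#KineticLaw", ns),
               "sbmlRdf:KineticLaw")
  expect_equal(compact_iri("http://other.org/x", character(0)),
               "http://other.org/x")
  ns2 <- c(a = "http://example.org/", b = "http://example.org/sub/")
  expect_equal(compact_iri("http://example.org/sub/item", ns2), "b:item")
  expect_equal(compact_iri("http://example.org/top", ns2), "a:top")
  # remainder with IRI structure cannot be a local name
  expect_equal(compact_iri("http://example.org/sub/a/b", ns2),
               "http://example.org/sub/a/b")
})

test_that("map_literal produces value/datatype (and lang when tagged)", {
  out <- map_literal(rdf_literal("42", paste0(NS_XSD, "integer")), ns_basic)
  expect_equal(json_serialize(out, "minified"),
               '{"value":"42","datatype":"xsd:integer"}')
  out <- map_literal(rdf_literal("protein", lang = "en"), ns_basic)
  expect_equal(json_serialize(out, "minified"),
               '{"value":"protein","datatype":"rdf:langString","lang":"en"}')
  out <- map_literal(rdf_literal(""), ns_basic)
  expect_equal(json_serialize(out, "minified"),
               '{"value":"","datatype":"xsd:string"}')
  expect_error(map_literal(rdf_iri(NS_EX), ns_basic),
               class = "rdf2json_contract_error")
})

test_that("map_reference wraps the (compacted) target under rdf:resource", {
  ns <- c(sbmlRdf = "http://sbml.org/sbmlRdf#", rdf = NS_RDF)
  out <- map_reference("http://sbml.org/sbmlRdf#KineticLaw", ns)
  expect_equal(json_serialize(out, "minified"),
               '{"rdf:resource":"sbmlRdf:KineticLaw"}')
  out <- map_reference("http://unknown.org/x", ns)
  expect_equal(out[["rdf:resource"]], "http://unknown.org/x")
  out <- map_reference(rdf_iri(paste0(NS_RDF, "nil")), ns)
  expect_equal(out[["rdf:resource"]], "rdf:nil")
})

test_that("merge_values keeps single values unwrapped and merges repeats", {
  v1 <- jobj(value = "a", datatype = "xsd:string")
  v2 <- jobj(value = "b", datatype = "xsd:string")
  expect_identical(merge_values(list(v1)), v1)
  out <- merge_values(list(v1, v2))
  expect_s3_class(out, "json_arr")
  expect_length(out, 2L)
  expect_error(merge_values(list()), class = "rdf2json_contract_error")
  # three distinct lexical forms survive as a 3-array
  out3 <- merge_values(list(v1, v2, jobj(value = "c", datatype = "xsd:string")))
  expect_length(out3, 3L)
})

test_that("merged arrays never have one element on migrated random graphs", {
  check_arrays <- function(x, key = NA_character_) {
    if (inherits(x, "json_arr")) {
      # collection "items" arrays may have any length; merged values not
      if (!identical(key, "items")) expect_gte(length(x), 2L)
      lapply(unclass(x), check_arrays)
    } else if (inherits(x, "json_obj")) {
      for (k in names(x)) if (!is.character(x[[k]])) check_arrays(x[[k]], k)
    }
    invisible()
  }
  for (seed in 1:5) {
    doc <- migrate_graph(generate_graph(fixture_spec(seed = seed,
                                                     n_subjects = 15,
                                                     p_repeat = 0.5)))
    check_arrays(doc)
  }
})

test_that("expand_blank maps a blank description recursively", {
  g <- graph_of(lit_row_b("B", paste0(NS_EX, "x"), "1",
                          paste0(NS_XSD, "integer")))
  out <- expand_blank(g, rdf_blank("B"))
  expect_equal(json_serialize(out, "minified"),
               '{"ex:x":{"value":"1","datatype":"xsd:integer"}}')
  g2 <- graph_of(tr_row("iri", paste0(NS_EX, "s"), paste0(NS_EX, "p"),
                        "blank", "B"))
  expect_equal(json_serialize(expand_blank(g2, rdf_blank("B")), "minified"), "{}")
})

test_that("expand_blank terminates on cycles with a back-reference", {
  g <- cycle_graph(2L)
  out <- expand_blank(g, rdf_blank("B1"))
  expect_equal(json_serialize(out, "minified"),
               '{"ex:q":{"ex:q":{"rdf:nodeID":"B1"}}}')
  # a node already on the path is answered without recursion
  expect_equal(json_serialize(expand_blank(g, rdf_blank("B1"),
                                           path = "B1"), "minified"),
               '{"rdf:nodeID":"B1"}')
  # self-loop
  gs <- graph_of(tr_row("blank", "S", paste0(NS_EX, "q"), "blank", "S"))
  expect_equal(json_serialize(expand_blank(gs, rdf_blank("S")), "minified"),
               '{"ex:q":{"rdf:nodeID":"S"}}')
})

test_that("map_container keeps the type and the ordinal members", {
  g <- graph_of(
    tr_row("blank", "C", paste0(NS_RDF, "type"), "iri", paste0(NS_RDF, "Seq")),
    lit_row_b("C", paste0(NS_RDF, "_1"), "a"),
    lit_row_b("C", paste0(NS_RDF, "_2"), "b"))
  out <- map_container(g, rdf_blank("C"), "container_seq")
  expect_equal(json_serialize(out, "minified"),
    paste0('{"rdf:type":"rdf:Seq","rdf:_1":{"value":"a","datatype":"xsd:string"},',
           '"rdf:_2":{"value":"b","datatype":"xsd:string"}}'))

  g2 <- graph_of(
    tr_row("blank", "C", paste0(NS_RDF, "type"), "iri", paste0(NS_RDF, "Bag")),
    tr_row("blank", "C", paste0(NS_RDF, "_1"), "iri", paste0(NS_EX, "m")))
  expect_equal(json_serialize(map_container(g2, rdf_blank("C"), "container_bag"),
                              "minified"),
               '{"rdf:type":"rdf:Bag","rdf:_1":{"rdf:resource":"ex:m"}}')

  g3 <- graph_of(
    tr_row("blank", "C", paste0(NS_RDF, "type"), "iri", paste0(NS_RDF, "Alt")))
  expect_equal(json_serialize(map_container(g3, rdf_blank("C"), "container_alt"),
                              "minified"),
               '{"rdf:type":"rdf:Alt"}')
})

test_that("a gap in the ordinal sequence is kept as-is with a warning", {
  g <- graph_of(
    tr_row("blank", "C", paste0(NS_RDF, "type"), "iri", paste0(NS_RDF, "Seq")),
    lit_row_b("C", paste0(NS_RDF, "_1"), "a"),
    lit_row_b("C", paste0(NS_RDF, "_3"), "c"))
  expect_warning(out <- map_container(g, rdf_blank("C"), "container_seq"),
                 "gap")
  expect_equal(names(out), c("rdf:type", "rdf:_1", "rdf:_3"))
})

test_that("map_collection preserves item order and handles rdf:nil", {
  g <- graph_of(
    tr_row("blank", "c1", paste0(NS_RDF, "first"), "literal", "x",
           paste0(NS_XSD, "string")),
    tr_row("blank", "c1", paste0(NS_RDF, "rest"), "blank", "c2"),
    tr_row("blank", "c2", paste0(NS_RDF, "first"), "literal", "y",
           paste0(NS_XSD, "string")),
    tr_row("blank", "c2", paste0(NS_RDF, "rest"), "iri", paste0(NS_RDF, "nil")))
  out <- map_collection(g, rdf_blank("c1"))
  expect_equal(json_serialize(out, "minified"),
    paste0('{"rdf:type":"rdf:List","items":[{"value":"x","datatype":"xsd:string"},',
           '{"value":"y","datatype":"xsd:string"}]}'))

  expect_equal(json_serialize(map_collection(g, rdf_iri(paste0(NS_RDF, "nil"))),
                              "minified"),
               '{"rdf:type":"rdf:List","items":[]}')

  # 3 IRI items stay in chain order even against canonical value order
  targets <- paste0(NS_EX, c("zz", "aa", "mm"))
  g3 <- graph_of(
    tr_row("blank", "k1", paste0(NS_RDF, "first"), "iri", targets[1L]),
    tr_row("blank", "k1", paste0(NS_RDF, "rest"), "blank", "k2"),
    tr_row("blank", "k2", paste0(NS_RDF, "first"), "iri", targets[2L]),
    tr_row("blank", "k2", paste0(NS_RDF, "rest"), "blank", "k3"),
    tr_row("blank", "k3", paste0(NS_RDF, "first"), "iri", targets[3L]),
    tr_row("blank", "k3", paste0(NS_RDF, "rest"), "iri", paste0(NS_RDF, "nil")))
  out3 <- map_collection(g3, rdf_blank("k1"))
  expect_equal(vapply(unclass(out3$items), function(v) v[["rdf:resource"]], ""),
               paste0("ex:", c("zz", "aa", "mm")))
})

test_that("broken collection chains truncate with a warning", {
  g <- graph_of(
    tr_row("blank", "c1", paste0(NS_RDF, "first"), "literal", "x",
           paste0(NS_XSD, "string")),
    tr_row("blank", "c1", paste0(NS_RDF, "rest"), "blank", "c2"),
    tr_row("blank", "c2", paste0(NS_RDF, "first"), "literal", "y",
           paste0(NS_XSD, "string")))
  expect_warning(out <- map_collection(g, rdf_blank("c1")), "not terminated")
  expect_length(out$items, 2L)

  gc <- graph_of(
    tr_row("blank", "c1", paste0(NS_RDF, "first"), "literal", "x",
           paste0(NS_XSD, "string")),
    tr_row("blank", "c1", paste0(NS_RDF, "rest"), "blank", "c2"),
    tr_row("blank", "c2", paste0(NS_RDF, "first"), "literal", "y",
           paste0(NS_XSD, "string")),
    tr_row("blank", "c2", paste0(NS_RDF, "rest"), "blank", "c1"))
  expect_warning(outc <- map_collection(gc, rdf_blank("c1")), "cyclic")
  expect_length(outc$items, 2L)
})

test_that("inject_schema_relations adds hierarchy and domain/range keys", {
  ns <- c(sbmlRdf = "http://sbml.org/sbmlRdf#", rdf = NS_RDF, rdfs = NS_RDFS)
  sb <- function(x) paste0("http://sbml.org/sbmlRdf#", x)
  g <- rdf_graph(as.data.frame(matrix(c(
    "iri", sb("kineticLaw"), paste0(NS_RDFS, "subPropertyOf"), "iri", sb("sbmlElement"), "", "",
    "iri", sb("kineticLaw"), paste0(NS_RDFS, "domain"), "iri", sb("Reaction"), "", "",
    "iri", sb("kineticLaw"), paste0(NS_RDFS, "range"), "iri", sb("KineticLaw"), "", "",
    "iri", sb("SBMLElement"), paste0(NS_RDFS, "subClassOf"), "iri", sb("Element"), "", ""),
    ncol = 7L, byrow = TRUE,
    dimnames = list(NULL, c("s_kind", "s", "p", "o_kind", "o", "o_dt", "o_lang")))),
    ns)
  out <- inject_schema_relations(jobj(), g, rdf_iri(sb("kineticLaw")), ns)
  expect_equal(json_serialize(out, "minified"),
    paste0('{"rdfs:subPropertyOf":"sbmlRdf:sbmlElement",',
           '"rdfs:domain":"sbmlRdf:Reaction","rdfs:range":"sbmlRdf:KineticLaw"}'))
  out2 <- inject_schema_relations(jobj(), g, rdf_iri(sb("SBMLElement")), ns)
  expect_equal(out2[["rdfs:subClassOf"]], "sbmlRdf:Element")
  # no schema triples: identity
  base <- jobj(k = "v")
  expect_identical(inject_schema_relations(base, g, rdf_iri(sb("absent")), ns),
                   base)
})

test_that("a literal-valued schema relation maps as a literal with a warning", {
  g <- graph_of(lit_row(paste0(NS_EX, "P"), paste0(NS_RDFS, "domain"), "oops"))
  expect_warning(
    out <- inject_schema_relations(jobj(), g, rdf_iri(paste0(NS_EX, "P")),
                                   g$namespaces),
    "literal")
  expect_equal(out[["rdfs:domain"]][["value"]], "oops")
})

test_that("every migrated value object has exactly one shape", {
  shape_count <- function(v) {
    if (!inherits(v, "json_obj")) return(NA_integer_)
    nm <- names(v)
    lit <- "value" %in% nm
    ref <- "rdf:resource" %in% nm && !lit
    col <- "items" %in% nm && identical(v[["rdf:type"]], "rdf:List")
    con <- !col && is.character(v[["rdf:type"]]) &&
      length(v[["rdf:type"]]) == 1L &&
      v[["rdf:type"]] %in% c("rdf:Bag", "rdf:Seq", "rdf:Alt")
    nested <- !lit && !ref && !col && !con
    sum(lit, ref, col, con, nested)
  }
  walk <- function(x) {
    if (inherits(x, "json_obj")) {
      expect_equal(shape_count(x), 1L)
      lapply(unclass(x), function(el) if (!is.character(el)) walk(el))
    } else if (inherits(x, "json_arr")) {
      lapply(unclass(x), function(el) if (!is.character(el)) walk(el))
    }
    invisible()
  }
  for (seed in 11:15) {
    doc <- migrate_graph(generate_graph(fixture_spec(seed = seed, n_subjects = 12)))
    for (res in unclass(doc[["resources"]])) walk(res)
  }
})

test_that("container member and collection item counts are conserved", {
  for (seed in 1:5) {
    g <- generate_graph(fixture_spec(seed = seed, n_subjects = 25,
                                     p_container = 0.5, p_collection = 0.5,
                                     p_literal = 0, p_reference = 0, p_blank = 0))
    man <- attr(g, "manifest")
    tr <- g$triples
    for (i in seq_len(nrow(man$containers))) {
      lab <- man$containers$label[i]
      out <- map_container(g, rdf_blank(lab), man$containers$kind[i])
      n_members <- sum(tr$s_kind == "blank" & tr$s == lab &
                       grepl(paste0("^", NS_RDF, "_[0-9]+$"), tr$p))
      expect_length(setdiff(names(out), "rdf:type"), n_members)
    }
    for (lab in man$collections) {
      out <- map_collection(g, rdf_blank(lab))
      len <- 0L; cur <- lab
      repeat {
        len <- len + 1L
        nxt <- tr$o[tr$s_kind == "blank" & tr$s == cur & tr$p == paste0(NS_RDF, "rest")]
        if (tr$o_kind[tr$s_kind == "blank" & tr$s == cur &
                      tr$p == paste0(NS_RDF, "rest")][1L] == "iri") break
        cur <- nxt
      }
      expect_length(out$items, len)
    }
  }
})
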