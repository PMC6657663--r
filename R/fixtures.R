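# Synthetic RDF generator. Emits graphs with controlled per-feature
# probabilities plus a manifest of what it actually emitted (container and
# collection nodes, cycles, repeated predicates, ...), so property tests
# can cross-check structure detection and round-trip preservation against
# ground truth without any external download.

FIX_DATA_NS <- "http://example.org/data/"
FIX_VOC_NS <- "http://example.org/vocab#"

#' Specification for a synthetic RDF graph
#'
#' The five kind probabilities control what each generated property value
#' is (any remainder falls back to a literal); `p_repeat` is the chance a
#' subject carries a repeated predicate (merged into an array by the
#' mapping), `p_cycle` the chance a blank-node value closes a 2-cycle,
#' `schema_depth` the length of the emitted class/property hierarchy
#' chains, and `lang_fraction` the fraction of string literals carrying a
#' language tag.
#'
#' @param seed Integer seed; identical spec + seed gives an identical graph.
#' @param n_subjects Number of top-level subjects.
#' @param p_literal,p_reference,p_blank,p_container,p_collection Value-kind
#'   probabilities (sum must be at most 1).
#' @param p_repeat Probability of a repeated predicate per subject.
#' @param p_cycle Probability a blank value closes a blank-node cycle.
#' @param schema_depth Depth of the class/property hierarchies (0 = none).
#' @param lang_fraction Fraction of plain literals carrying a language tag.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_subjects = 20L,
                         p_literal = 0.5, p_reference = 0.2, p_blank = 0.15,
                         p_container = 0.075, p_collection = 0.075,
                         p_repeat = 0.15, p_cycle = 0,
                         schema_depth = 2L, lang_fraction = 0.2) {
  probs <- c(p_literal, p_reference, p_blank, p_container, p_collection,
             p_repeat, p_cycle, lang_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    rdf2json_error("all probabilities must lie in [0, 1]", "rdf2json_validation_error")
  if (p_literal + p_reference + p_blank + p_container + p_collection > 1 + 1e-12)
    rdf2json_error("value-kind probabilities must sum to at most 1",
                   "rdf2json_validation_error")
  if (n_subjects < 0)
    rdf2json_error("n_subjects must be non-negative", "rdf2json_validation_error")
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 p_literal = p_literal, p_reference = p_reference,
                 p_blank = p_blank, p_container = p_container,
                 p_collection = p_collection, p_repeat = p_repeat,
                 p_cycle = p_cycle, schema_depth = as.integer(schema_depth),
                 lang_fraction = lang_fraction),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

rand_word <- function(len = NULL) {
  if (is.null(len)) len <- sample(3:10, 1L)
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic RDF graph
#'
#' @param spec A [fixture_spec].
#' @return An [rdf_graph]; attribute `"manifest"` records what was emitted:
#'   `containers` (data.frame of node label and detected kind),
#'   `collections` (head labels), `n_cycles`, `n_repeats`, `n_blank_values`,
#'   `n_lang_literals`, and `subject_iris`.
#' @export
generate_graph <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    acc <- new_acc()
    man <- list(containers = data.frame(label = character(0), kind = character(0)),
                collections = character(0), n_cycles = 0L, n_repeats = 0L,
                n_blank_values = 0L, n_lang_literals = 0L)
    bl <- local({
      n <- 0L
      function() { n <<- n + 1L; sprintf("b%05d", n) }
    })
    preds <- paste0(FIX_VOC_NS, sprintf("p%02d", 1:12))
    emit_literal <- function(s_kind, s, p) {
      r <- runif(1)
      if (r < spec$lang_fraction) {
        man$n_lang_literals <<- man$n_lang_literals + 1L
        acc_emit(acc, s_kind, s, p, "literal", rand_word(), RDF_LANGSTRING,
                 sample(c("en", "de", "fr"), 1L))
      } else if (r < spec$lang_fraction + 0.25) {
        acc_emit(acc, s_kind, s, p, "literal", as.character(sample.int(10000L, 1L)),
                 paste0(XSD_NS, "integer"))
      } else {
        acc_emit(acc, s_kind, s, p, "literal", rand_word(), XSD_STRING)
      }
    }
    emit_reference <- function(s_kind, s, p) {
      target <- if (runif(1) < 0.7)
        paste0(FIX_DATA_NS, sprintf("s%04d", sample.int(max(spec$n_subjects, 1L), 1L)))
      else paste0(FIX_VOC_NS, "Item", sample.int(5L, 1L))
      acc_emit(acc, s_kind, s, p, "iri", target)
    }
    emit_blank_value <- function(s_kind, s, p, depth) {
      b <- bl()
      man$n_blank_values <<- man$n_blank_values + 1L
      acc_emit(acc, s_kind, s, p, "blank", b)
      for (k in seq_len(sample(1:3, 1L)))
        emit_literal("blank", b, preds[k])
      if (spec$p_cycle > 0 && runif(1) < spec$p_cycle) {
        b2 <- bl()
        man$n_cycles <<- man$n_cycles + 1L
        acc_emit(acc, "blank", b, paste0(FIX_VOC_NS, "next"), "blank", b2)
        acc_emit(acc, "blank", b2, paste0(FIX_VOC_NS, "back"), "blank", b)
      } else if (depth < 3L && runif(1) < 0.3) {
        emit_blank_value("blank", b, paste0(FIX_VOC_NS, "child"), depth + 1L)
      }
    }
    emit_container <- function(s_kind, s, p) {
      c_lab <- bl()
      kind <- sample(c("container_bag", "container_seq", "container_alt"), 1L)
      man$containers <<- rbind(man$containers,
                               data.frame(label = c_lab, kind = kind))
      acc_emit(acc, s_kind, s, p, "blank", c_lab)
      acc_emit(acc, "blank", c_lab, RDF_TYPE, "iri", CONTAINER_CLASS_IRI[[kind]])
      for (k in seq_len(sample(1:4, 1L))) {
        pk <- paste0(RDF_NS, "_", k)
        if (runif(1) < 0.5) emit_literal("blank", c_lab, pk)
        else emit_reference("blank", c_lab, pk)
      }
    }
    emit_collection <- function(s_kind, s, p) {
      n_items <- sample(1:3, 1L)
      cells <- vapply(seq_len(n_items), function(.) bl(), "")
      man$collections <<- c(man$collections, cells[1L])
      acc_emit(acc, s_kind, s, p, "blank", cells[1L])
      for (k in seq_len(n_items)) {
        if (runif(1) < 0.6) emit_literal("blank", cells[k], RDF_FIRST)
        else emit_reference("blank", cells[k], RDF_FIRST)
        if (k < n_items)
          acc_emit(acc, "blank", cells[k], RDF_REST, "blank", cells[k + 1L])
        else
          acc_emit(acc, "blank", cells[k], RDF_REST, "iri", RDF_NIL)
      }
    }
    cuts <- cumsum(c(spec$p_literal, spec$p_reference, spec$p_blank,
                     spec$p_container, spec$p_collection))
    for (i in seq_len(spec$n_subjects)) {
      s <- paste0(FIX_DATA_NS, sprintf("s%04d", i))
      slots <- sample(preds, sample(2:5, 1L))
      for (p in slots) {
        r <- runif(1)
        if (r < cuts[1L]) emit_literal("iri", s, p)
        else if (r < cuts[2L]) emit_reference("iri", s, p)
        else if (r < cuts[3L]) emit_blank_value("iri", s, p, 1L)
        else if (r < cuts[4L]) emit_container("iri", s, p)
        else if (r < cuts[5L]) emit_collection("iri", s, p)
        else emit_literal("iri", s, p)
      }
      if (runif(1) < spec$p_repeat) {
        man$n_repeats <- man$n_repeats + 1L
        pr <- paste0(FIX_VOC_NS, "tag")
        for (v in paste0(rand_word(4L), seq_len(sample(2:3, 1L))))
          acc_emit(acc, "iri", s, pr, "literal", v, XSD_STRING)
      }
    }
    if (spec$schema_depth > 0L) {
      d <- spec$schema_depth
      cls <- paste0(FIX_VOC_NS, "Class", seq_len(d + 1L))
      prp <- paste0(FIX_VOC_NS, "prop", seq_len(d + 1L))
      for (k in seq_len(d)) {
        acc_emit(acc, "iri", cls[k], RDFS_SUBCLASSOF, "iri", cls[k + 1L])
        acc_emit(acc, "iri", prp[k], RDFS_SUBPROPERTYOF, "iri", prp[k + 1L])
      }
      for (k in seq_len(d + 1L)) {
        acc_emit(acc, "iri", cls[k], RDF_TYPE, "iri", paste0(RDFS_NS, "Class"))
        acc_emit(acc, "iri", prp[k], RDF_TYPE, "iri", paste0(RDF_NS, "Property"))
      }
      acc_emit(acc, "iri", prp[1L], RDFS_DOMAIN, "iri", cls[1L])
      acc_emit(acc, "iri", prp[1L], RDFS_RANGE, "iri", cls[2L])
    }
    g <- rdf_graph(acc_triples(acc),
                   c(ex = FIX_DATA_NS, voc = FIX_VOC_NS,
                     rdf = RDF_NS, rdfs = RDFS_NS, xsd = XSD_NS))
    man$subject_iris <- paste0(FIX_DATA_NS, sprintf("s%04d", seq_len(spec$n_subjects)))
    attr(g, "manifest") <- man
    g
  })
}

#' Schema-hierarchy fixture (synthetic)
#'
#' A small RDFS fragment in the style of an SBML vocabulary: classes
#' SBMLElement, SpeciesReference, KineticLaw, Reaction and Element;
#' KineticLaw and SpeciesReference are subclasses of SBMLElement, which is
#' a subclass of Element; the property kineticLaw has superproperty
#' sbmlElement, domain Reaction and range KineticLaw. The namespace IRI is
#' a synthetic placeholder.
#'
#' @return An [rdf_graph].
#' @export
generate_schema_fixture <- function() {
  ns <- "http://sbml.org/sbmlRdf#"
  acc <- new_acc()
  cls <- function(x) paste0(ns, x)
  rdfs_class <- paste0(RDFS_NS, "Class")
  rdf_prop <- paste0(RDF_NS, "Property")
  for (c in c("SBMLElement", "SpeciesReference", "KineticLaw", "Reaction", "Element"))
    acc_emit(acc, "iri", cls(c), RDF_TYPE, "iri", rdfs_class)
  acc_emit(acc, "iri", cls("KineticLaw"), RDFS_SUBCLASSOF, "iri", cls("SBMLElement"))
  acc_emit(acc, "iri", cls("SpeciesReference"), RDFS_SUBCLASSOF, "iri", cls("SBMLElement"))
  acc_emit(acc, "iri", cls("SBMLElement"), RDFS_SUBCLASSOF, "iri", cls("Element"))
  for (p in c("sbmlElement", "kineticLaw"))
    acc_emit(acc, "iri", cls(p), RDF_TYPE, "iri", rdf_prop)
  acc_emit(acc, "iri", cls("kineticLaw"), RDFS_SUBPROPERTYOF, "iri", cls("sbmlElement"))
  acc_emit(acc, "iri", cls("kineticLaw"), RDFS_DOMAIN, "iri", cls("Reaction"))
  acc_emit(acc, "iri", cls("kineticLaw"), RDFS_RANGE, "iri", cls("KineticLaw"))
  rdf_graph(acc_triples(acc), c(sbmlRdf = ns, rdf = RDF_NS, rdfs = RDFS_NS))
}

#' Write a doubling series of RDF/XML fixtures
#'
#' Files of `base_subjects`, `2 x`, `4 x`, ... subjects with a homogeneous
#' per-subject structure (4 literal and 2 reference triples each), for
#' empirical scaling checks.
#'
#' @param base_subjects Subjects in the smallest file.
#' @param doublings Number of files (sizes `base_subjects * 2^(0:(doublings-1))`).
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, ascending size.
#' @export
scaling_series <- function(base_subjects, doublings, seed, dir = tempfile("scaling")) {
  if (doublings < 1L)
    rdf2json_error("doublings must be at least 1", "rdf2json_validation_error")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    rdf2json_error(sprintf("cannot create directory '%s'", dir), "rdf2json_io_error")
  sizes <- base_subjects * 2^(seq_len(doublings) - 1L)
  with_seed(seed, {
    vapply(seq_along(sizes), function(k) {
      n <- sizes[k]
      acc <- new_acc()
      words <- replicate(26L, rand_word(8L))
      for (i in seq_len(n)) {
        s <- paste0(FIX_DATA_NS, sprintf("s%06d", i))
        for (j in 1:4)
          acc_emit(acc, "iri", s, paste0(FIX_VOC_NS, "p0", j), "literal",
                   words[(i + j) %% 26L + 1L], XSD_STRING)
        acc_emit(acc, "iri", s, paste0(FIX_VOC_NS, "ref1"), "iri",
                 paste0(FIX_DATA_NS, sprintf("s%06d", (i %% n) + 1L)))
        acc_emit(acc, "iri", s, paste0(FIX_VOC_NS, "ref2"), "iri",
                 paste0(FIX_VOC_NS, "Item", (i %% 5L) + 1L))
      }
      g <- rdf_graph(acc_triples(acc),
                     c(ex = FIX_DATA_NS, voc = FIX_VOC_NS, rdf = RDF_NS,
                       xsd = XSD_NS))
      path <- file.path(dir, sprintf("scale_%07d.rdf", n))
      write_rdfxml(g, path)
      path
    }, "")
  })
}
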