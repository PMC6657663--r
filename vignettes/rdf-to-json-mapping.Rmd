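---
title: "Migrating RDF graphs to JSON documents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migrating RDF graphs to JSON documents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdf2json)
```

## The problem

Biomedical resources such as UniProtKB and BioModels publish their records
as RDF: sets of subject–predicate–object triples, often serialized as
RDF/XML or Turtle, with RDFS supplying class and property hierarchies
(`rdfs:subClassOf`, `rdfs:subPropertyOf`) and property typing
(`rdfs:domain`, `rdfs:range`). Document stores and modern release
pipelines, on the other hand, consume JSON. rdf2json migrates one
representation into the other: it parses an RDF file into a triple/graph
model and rewrites it, rule by rule, into a single root JSON document that
a tool like `mongoimport` can load.

## The mapping

The conversion applies a fixed set of rules:

1. **Namespaces.** The prefix table of the document becomes the root
   object's `"namespaces"` member, `{prefix: namespace-IRI, ...}`.
2. **Property values.** A literal value becomes
   `{"value": lexical, "datatype": curie}` with `"lang"` added when a
   language tag is present; a URI reference becomes
   `{"rdf:resource": curie}`.
3. **Blank nodes.** A blank-node value is expanded in place: every triple
   whose subject is that blank node is mapped recursively and nested under
   the referring property.
4. **Containers.** A node typed `rdf:Bag`, `rdf:Seq` or `rdf:Alt` maps to
   an object that retains the container type under `"rdf:type"` and one
   `"rdf:_N"` key per member, in ordinal order.
5. **Collections.** An `rdf:first`/`rdf:rest` chain maps to
   `{"rdf:type": "rdf:List", "items": [...]}` with items in chain order;
   `rdf:nil` is the empty list.
6. **Class hierarchy.** `rdfs:subClassOf` triples add a
   `"rdfs:subClassOf"` key whose value is the superclass IRI as a plain
   string.
7. **Property hierarchy.** Likewise `"rdfs:subPropertyOf"` with the
   superproperty IRI.
8. **Domain and range.** `rdfs:domain` / `rdfs:range` triples add the
   corresponding keys with plain IRI string values on the property's
   object.
9. **Repeated properties.** Several values for one (subject, predicate)
   merge into an array; a single value is never wrapped.
10. **Empty values.** A property without content maps to the literal
    object with `"value": ""`.

Rules 6–8 deliberately produce plain strings rather than
`{"rdf:resource": ...}` objects: hierarchy and typing information is
schema metadata on the resource object, not another property value. This
distinction only applies to top-level resources; inside an expanded blank
node the RDFS predicates behave like ordinary URI-valued properties.

The driver is two nested loops: the outer loop walks every top-level
resource of the model, the inner loop walks the property groups of that
resource, so the worst-case cost is the product of the two. With the
per-subject hash index the observed cost is linear in the number of
triples for data-like inputs (see the scaling check below).

## Determinism and canonical order

Triple stores are unordered, so every emitted sequence is given one fixed,
reproducible order: nodes sort literals < blank nodes < IRIs, then
lexicographically (byte order) by lexical form/datatype/language, label,
or IRI; property keys within a resource sort lexicographically, with the
four schema keys (`rdfs:subClassOf`, `rdfs:subPropertyOf`, `rdfs:domain`,
`rdfs:range`) placed last in that fixed order; merged arrays inherit the
canonical value order; the resource table follows the canonical subject
order; container members sort by ordinal. Two conversions of the same
graph are therefore byte-identical, which the test suite asserts.

Plain literals are normalized to `xsd:string` and language-tagged ones to
`rdf:langString`, so every literal object carries a datatype. Datatype
IRIs and all other IRIs are abbreviated to CURIEs when a declared
namespace matches (the longest matching namespace wins and the remainder
must be a plain local name); otherwise the full IRI string is kept.

## Cycles and deep nesting

The recursion of rule 3 is not well defined on cyclic blank-node
structures, so the expander tracks the set of blank nodes on the current
branch; revisiting one emits the back-reference `{"rdf:nodeID": label}`
instead of recursing. The path set grows strictly along each branch, so
expansion terminates on every finite graph. A blank node referenced from
several places (but not cyclically) is inlined at every reference site;
the duplication is accepted, as resource keys must stay self-contained.

Both the expander and the JSON serializer run on explicit work stacks
rather than native recursion, so chains nested 10,000 levels deep convert
without exhausting the interpreter's call stack; the acceptance suite
exercises exactly that depth. (Pretty-printed output of such a document is
quadratic in its depth purely because of the indentation bytes; minified
output is linear.)

## Degenerate inputs

* A gap in a container's `rdf:_N` ordinals is kept as-is with a warning.
* A collection chain not terminated by `rdf:nil`, or with a cyclic
  `rdf:rest`, is collected up to the break with a warning.
* A schema relation whose object is a literal is mapped as a literal
  object with a warning (malformed schema).
* A blank node with no outgoing triples maps to `{}`.
* `rdf:type` on an ordinary resource has no special rule in the mapping
  and is kept as a normal URI-valued property.

## Reader scope

No RDF parser exists in this R stack, so the package ships its own
readers. The RDF/XML reader (built on xml2) covers the striped syntax:
`rdf:Description` and typed node elements, `rdf:about`/`rdf:nodeID`
subjects, `rdf:resource`/`rdf:nodeID` objects, nested node elements,
`rdf:parseType="Resource"/"Collection"/"Literal"`, `rdf:li` ordinals,
property attributes, datatyped and language-tagged literals, and empty
property elements. `rdf:ID` and relative IRIs (base-IRI resolution) are
not supported and raise a syntax error. The Turtle reader covers
directives, prefixed names, blank-node property lists, collections,
object/predicate-object lists, string escapes, `^^`/`@lang`, and
numeric/boolean shorthand; single-quoted and triple-quoted strings are
out of scope. Named graphs, reification and OWL constructs are not
interpreted — their triples pass through as plain statements.

## Serialization

The JSON writer is part of the contract, not plumbing: byte-for-byte
determinism with construction-order keys, the exact five value-object
shapes (including `{}` for empty descriptions), and stack safety at
extreme depth are all properties the surrounding ecosystem of generic
serializers does not guarantee, so the package implements its own. It
emits UTF-8, escapes control characters as `\uXXXX`, indents with two
spaces in `pretty` style and emits no insignificant whitespace in
`minified` style. (The op is exported as `json_serialize`; the natural
name `serialize` is taken by base R.)

## Document-store import

`mongoimport` field names may not contain `"."` or NUL and may not start
with `"$"`. `sanitize_field_name()` replaces `"."` with U+FF0E (fullwidth
full stop) and a leading `"$"` with U+FF04 (fullwidth dollar sign) —
fullwidth homoglyphs keep the keys readable and the mapping injective on
the forbidden characters — and `sanitize_document()` applies this to every
key at every depth, erroring if two distinct keys would collide. R
character vectors cannot carry an embedded NUL, so that rule is satisfied
by construction for any key this package produces. `write_import_file()`
then emits one minified JSON document per line (JSON Lines), each record
being the resource object with a leading `"uri"` field, optionally with
the namespace table embedded under `"@ns"`.

## The synthetic-data generator

No external download is required for testing: `generate_graph()` emits
graphs from a `fixture_spec()` whose fields control, per generated
property slot, the probability of each value kind — literal 0.5, URI
reference 0.2, blank node 0.15, container 0.075, collection 0.075 by
default — plus a 0.15 chance per subject of a repeated predicate, a 0.2
language-tag fraction, class/property hierarchy chains of depth 2, and an
optional blank-node cycle probability (0 by default, so the default
substrate is cycle-free). These defaults were chosen once as a structural
caricature of data-plus-schema RDF extracts: literal-heavy records with a
moderate amount of cross-referencing and occasional grouped values. The
generator records a manifest (which nodes are containers/collections, how
many cycles, repeats, language tags it emitted) that tests replay against
the structure detectors.

What the generator does *not* emulate is the statistical content of real
UniProtKB or BioModels records — IRI lengths, vocabulary sizes, text
distributions. Passing tests therefore demonstrate the structural
correctness and the qualitative storage behavior of the mapping, not the
exact compression percentages of any historical database release, which
also depend on serialization conventions the sources never state.

`scaling_series()` writes a doubling series (by default 1000, 2000, 4000,
8000 subjects; six triples per subject, homogeneous) used to check that
conversion time grows sub-quadratically: successive runtime ratios stay
below 4 and in practice sit near 2, i.e. close to linear. These problem
sizes were chosen so each conversion finishes in seconds while still
spanning an order of magnitude.

## Verification strategy

Beyond the golden fixtures (two hand-written cases per mapping rule,
compared byte-for-byte), two independent implementations back the main
property tests: a brute-force per-triple mapper (plain recursive code over
data-frame scans, serialized through jsonlite) must produce identical
canonical JSON on 500 random graphs, and an inverse interpreter must
reconstruct, from the JSON alone, a graph isomorphic modulo blank-node
relabeling to the input on 500 cycle-free graphs. A coverage counter
verifies that every input triple contributes to the output.

## Known limitations

* No base-IRI resolution: all IRIs must be absolute.
* No N-Triples/N-Quads/JSON-LD input, no SPARQL, no OWL reasoning, and no
  inference over `subClassOf` closures — the hierarchy keys record only
  asserted triples.
* Blank nodes referenced multiple times are duplicated at each reference
  site; the JSON form does not share them.
* The `{"rdf:nodeID": label}` back-reference keeps cycles recoverable but
  a consumer must resolve the label itself.
* Compression is purely representational (shorter syntax), not a
  byte-level compressor.
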