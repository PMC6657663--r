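# rdf2json

Biomedical databases — UniProtKB, BioModels, Ensembl and many others —
publish their records as RDF (subject–predicate–object triples, usually
serialized as RDF/XML or Turtle), while document stores such as MongoDB
and modern data-release pipelines consume JSON. rdf2json migrates one
world into the other: it parses an RDF file into a triple/graph model and
rewrites it into a single JSON document through a fixed set of mapping
rules, then optionally prepares that document for bulk import into a
document store.

The mapping, in brief:

* the document's prefix table becomes a root `"namespaces"` object;
* a literal value becomes `{"value": v, "datatype": d[, "lang": l]}`, a
  URI reference becomes `{"rdf:resource": iri}` (IRIs are abbreviated to
  `prefix:local` CURIEs whenever a declared namespace matches);
* blank nodes expand recursively in place, with `{"rdf:nodeID": label}`
  back-references breaking cycles;
* RDF containers (`rdf:Bag`/`rdf:Seq`/`rdf:Alt`) keep their type and
  their `rdf:_N` members; collections (`rdf:first`/`rdf:rest` lists)
  become `{"rdf:type": "rdf:List", "items": [...]}` in chain order;
* RDFS schema triples add `"rdfs:subClassOf"`, `"rdfs:subPropertyOf"`,
  `"rdfs:domain"`, `"rdfs:range"` keys whose values are plain IRI
  strings;
* repeated properties merge into arrays; valueless properties map to the
  empty string.

Output is deterministic byte-for-byte: every sequence (resources, keys,
merged values, container members) follows one canonical order, so the
same graph always serializes to the same bytes.

## Worked example

```r
library(rdf2json)

ttl <- tempfile(fileext = ".ttl")
writeLines(c(
  "@prefix up: <http://purl.uniprot.org/core/> .",
  "@prefix protein: <http://purl.uniprot.org/uniprot/> .",
  "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
  "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
  "protein:P12345 rdf:type up:Protein ;",
  "  up:mnemonic \"AATM_RABIT\" ;",
  "  up:reviewed true ;",
  "  up:encodedBy [ up:prefLabel \"GOT2\" ] ."
), ttl)

out <- migrate_file(ttl)   # writes the .json next to the source
cat(readLines(out), sep = "\n")
```

prints

```json
{
  "namespaces": {
    "protein": "http://purl.uniprot.org/uniprot/",
    "rdf": "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    "up": "http://purl.uniprot.org/core/",
    "xsd": "http://www.w3.org/2001/XMLSchema#"
  },
  "resources": {
    "protein:P12345": {
      "rdf:type": {
        "rdf:resource": "up:Protein"
      },
      "up:encodedBy": {
        "up:prefLabel": {
          "value": "GOT2",
          "datatype": "xsd:string"
        }
      },
      "up:mnemonic": {
        "value": "AATM_RABIT",
        "datatype": "xsd:string"
      },
      "up:reviewed": {
        "value": "true",
        "datatype": "xsd:boolean"
      }
    }
  }
}
```

Every top-level resource sits under its CURIE in `"resources"`; the blank
node behind `up:encodedBy` was inlined as a nested object; the Turtle
shorthand `true` arrived as an `xsd:boolean` literal. For a MongoDB
import:

```r
doc  <- sanitize_document(migrate_graph(load_graph(ttl)))  # "." / "$" safe keys
n    <- write_import_file(doc, "proteins.jsonl")           # one record per resource
build_import_command("bio", "proteins", "proteins.jsonl")
#> [1] "mongoimport -d bio -c proteins --file proteins.jsonl"
```

The same operations are available from a shell through the launcher in
`inst/cli/`:

```sh
rdf2json convert input.rdf --style minified --mongo-sanitize --report
rdf2json export-mongo input.json --embed-ns
rdf2json import-cmd --db bio --coll proteins --file input.jsonl
rdf2json gen --spec fixture.cfg --out fixtures/
```

`generate_graph()` / `fixture_spec()` produce seeded synthetic RDF graphs
(with a manifest of the emitted structure) so the whole pipeline is
testable without downloading any database extract; see the vignette for
what the generator does and does not emulate.

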