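Package: rdf2json
Title: Migrate RDF Graphs to JSON Documents for Document Stores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses RDF (RDF/XML and Turtle) into a triple/graph model and
    migrates it to JSON documents via a fixed set of mapping rules covering
    namespaces, literal and URI-reference values, recursive blank-node
    expansion with cycle handling, RDF containers (Bag/Seq/Alt) and
    collections (rdf:List), RDFS class/property hierarchies and
    domain/range, merging of repeated property values, and empty values.
    Includes deterministic canonical JSON serialization, a storage
    compression report, MongoDB-import-safe field-name sanitization with
    JSON Lines export, a synthetic RDF fixture generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'nodes.R'
    'graph.R'
    'json.R'
    'mapping.R'
    'expand.R'
    'read-rdfxml.R'
    'read-turtle.R'
    'write-rdf.R'
    'load.R'
    'migrate.R'
    'mongo.R'
    'fixtures.R'
    'cli.R'
    'rdf2json-package.R'
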