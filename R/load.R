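#' Load an RDF file into a graph model
#'
#' Parses an RDF/XML or Turtle document into an [rdf_graph]: the asserted
#' triples (set semantics) plus the namespace prefixes declared in the
#' document.
#'
#' @param path Path to the RDF file (UTF-8).
#' @param syntax `"rdfxml"`, `"turtle"`, or `"auto"` (the default), which
#'   selects by extension: `.rdf`/`.xml`/`.owl` are RDF/XML, `.ttl` is
#'   Turtle.
#' @return An [rdf_graph].
#' @examples
#' ttl <- tempfile(fileext = ".ttl")
#' writeLines(c("@prefix ex: <http://example.org/> .",
#'              'ex:a ex:p "v" .'), ttl)
#' g <- load_graph(ttl)
#' g$namespaces
#' @export
load_graph <- function(path, syntax = c("auto", "rdfxml", "turtle")) {
  syntax <- match.arg(syntax)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    rdf2json_error(sprintf("input file not found: '%s'", path),
                   "rdf2json_input_error")
  if (syntax == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    syntax <- switch(ext,
      rdf = , xml = , owl = "rdfxml",
      ttl = "turtle",
      rdf2json_error(
        sprintf("cannot infer RDF syntax from extension '.%s' of '%s'", ext, path),
        "rdf2json_config_error"))
  }
  switch(syntax, rdfxml = read_rdfxml(path), turtle = read_turtle(path))
}
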