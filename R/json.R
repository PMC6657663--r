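# JSON value model and deterministic serializer.
#
# Documents are built from three value kinds: character scalars, ordered
# objects (`jobj`), and arrays (`jarr`). The serializer is hand-rolled for
# two properties a generic one cannot guarantee: byte-for-byte determinism
# with construction-order keys, and stack safety on documents nested tens
# of thousands of levels deep (explicit work stack, no recursion).

#' Construct an ordered JSON object
#'
#' @param ... Named values (strings, `jobj`, `jarr`); insertion order is
#'   preserved in serialization.
#' @return A `json_obj`.
#' @export
jobj <- function(...) {
  x <- list(...)
  if (length(x) > 0L && (is.null(names(x)) || any(!nzchar(names(x)))))
    rdf2json_error("all jobj members must be named", "rdf2json_contract_error")
  if (is.null(names(x))) names(x) <- character(0)
  structure(x, class = "json_obj")
}

#' Construct a JSON array
#'
#' @param ... Unnamed values.
#' @return A `json_arr`.
#' @export
jarr <- function(...) structure(list(...), class = "json_arr")

jobj_from <- function(lst) {
  structure(as.list(lst), class = "json_obj")
}

jarr_from <- function(lst) {
  lst <- as.list(lst)
  names(lst) <- NULL
  structure(lst, class = "json_arr")
}

is_jobj <- function(x) inherits(x, "json_obj")
is_jarr <- function(x) inherits(x, "json_arr")

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s <- gsub("\b", "\\b", s, fixed = TRUE)
  s <- gsub("\f", "\\f", s, fixed = TRUE)
  if (grepl("[\x01-\x1f]", s)) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    ctrl <- chars %in% strsplit(rawToChar(as.raw(1:31)), "")[[1L]]
    chars[ctrl] <- sprintf("\\u%04x", utf8ToInt(paste(chars[ctrl], collapse = ""))[seq_len(sum(ctrl))])
    s <- paste(chars, collapse = "")
  }
  s
}

#' Serialize a JSON document deterministically
#'
#' Key order is the construction order (the package builds documents in
#' canonical order, so equal documents serialize to identical bytes).
#' `pretty` uses 2-space indentation; `minified` has no insignificant
#' whitespace. Handles arbitrarily deep nesting without recursion.
#'
#' @param doc A `jobj`, `jarr`, or character scalar.
#' @param style `"pretty"` or `"minified"`.
#' @return A UTF-8 JSON string.
#' @export
json_serialize <- function(doc, style = c("pretty", "minified")) {
  style <- match.arg(style)
  pretty <- style == "pretty"
  if (is.character(doc)) return(paste0("\"", json_escape(doc), "\""))
  if (!is_jobj(doc) && !is_jarr(doc))
    rdf2json_error("JSON values must be strings, jobj, or jarr",
                   "rdf2json_contract_error")
  # The token buffer and the frame stack are plain local variables with
  # inline subassignment: routing either through a helper function or an
  # environment field would copy the whole vector on every write.
  buf <- character(1024L); bn <- 0L
  new_ser_frame <- function(x, depth) {
    f <- new.env(parent = emptyenv())
    f$val <- x; f$n <- length(x); f$i <- 0L; f$depth <- depth
    f$keys <- if (is_jobj(x)) names(x) else NULL
    f
  }
  stack <- vector("list", 64L)
  bn <- bn + 1L; buf[bn] <- if (is_jobj(doc)) "{" else "["
  stack[[1L]] <- new_ser_frame(doc, 0L)
  sp <- 1L
  while (sp > 0L) {
    f <- stack[[sp]]
    if (f$i < f$n) {
      i <- f$i + 1L
      f$i <- i
      tok <- if (!is.null(f$keys)) {
        paste0(if (i > 1L) "," else "",
               if (pretty) paste0("\n", strrep("  ", f$depth + 1L)) else "",
               "\"", json_escape(f$keys[i]), "\":", if (pretty) " " else "")
      } else {
        paste0(if (i > 1L) "," else "",
               if (pretty) paste0("\n", strrep("  ", f$depth + 1L)) else "")
      }
      x <- f$val[[i]]
      if (is.character(x)) {
        tok <- paste0(tok, "\"", json_escape(x), "\"")
      } else if (is_jobj(x) || is_jarr(x)) {
        tok <- paste0(tok, if (is_jobj(x)) "{" else "[")
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[sp]] <- new_ser_frame(x, f$depth + 1L)
      } else {
        rdf2json_error("JSON values must be strings, jobj, or jarr",
                       "rdf2json_contract_error")
      }
      bn <- bn + 1L
      if (bn > length(buf)) buf <- c(buf, character(length(buf)))
      buf[bn] <- tok
    } else {
      tok <- paste0(if (f$n > 0L && pretty) paste0("\n", strrep("  ", f$depth)) else "",
                    if (is_jobj(f$val)) "}" else "]")
      bn <- bn + 1L
      if (bn > length(buf)) buf <- c(buf, character(length(buf)))
      buf[bn] <- tok
      stack[sp] <- list(NULL)
      sp <- sp - 1L
    }
  }
  paste(buf[seq_len(bn)], collapse = "")
}

# Write serialized JSON as UTF-8 bytes with no trailing newline mangling;
# byte-identical across runs and platforms.
write_json_bytes <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
  invisible(path)
}

#' Storage comparison between an RDF file and its JSON output
#'
#' Rate is `1 - json_bytes / rdf_bytes`: positive when the JSON document is
#' smaller than its RDF source.
#'
#' @param rdf_path Path to the RDF input file.
#' @param json_path Path to the JSON output file.
#' @return A `compression_report` with `rdf_bytes`, `json_bytes`, `rate`.
#' @export
compression_report <- function(rdf_path, json_path) {
  for (p in c(rdf_path, json_path))
    if (!file.exists(p))
      rdf2json_error(sprintf("file not found: '%s'", p), "rdf2json_input_error")
  rb <- file.size(rdf_path)
  jb <- file.size(json_path)
  if (rb == 0)
    rdf2json_error("RDF input has zero size; compression rate undefined",
                   "rdf2json_input_error")
  structure(list(rdf_bytes = rb, json_bytes = jb, rate = 1 - jb / rb),
            class = "compression_report")
}

#' @export
print.compression_report <- function(x, ...) {
  cat(sprintf("RDF size (MB): %.2f\nJSON size (MB): %.2f\ncompression rate: %.1f%%\n",
              x$rdf_bytes / 1e6, x$json_bytes / 1e6, 100 * x$rate))
  invisible(x)
}

report_as_json <- function(x) {
  sprintf('{"rdf_bytes":%d,"json_bytes":%d,"rdf_mb":%.2f,"json_mb":%.2f,"rate":%.4f}',
          as.integer(x$rdf_bytes), as.integer(x$json_bytes),
          x$rdf_bytes / 1e6, x$json_bytes / 1e6, x$rate)
}
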