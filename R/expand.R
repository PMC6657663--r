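# Expansion engine: turns one resource (and everything reachable through
# blank nodes, containers, and collections) into its JSON value structure.
#
# The engine runs a depth-first traversal with an explicit frame stack, so
# blank-node chains nested tens of thousands of levels deep expand without
# touching R's call stack. The set of blank nodes on the current branch is
# kept in a hash (pushed on frame entry, popped on exit); revisiting one is
# a cycle and yields a `{"rdf:nodeID": label}` back-reference instead of
# recursing forever.

CONTAINER_TYPE_KEY <- c(container_bag = "rdf:Bag",
                        container_seq = "rdf:Seq",
                        container_alt = "rdf:Alt")
CONTAINER_CLASS_IRI <- c(container_bag = RDF_BAG,
                         container_seq = RDF_SEQ,
                         container_alt = RDF_ALT)

new_expand_ctx <- function(graph, ns = graph$namespaces, track_used = FALSE) {
  e <- new.env(parent = emptyenv())
  e$graph <- graph
  e$ns <- ns
  # plain column vectors: row extraction from the data.frame is far too
  # slow on the per-frame path
  e$p <- graph$triples$p
  e$o_kind <- graph$triples$o_kind
  e$o <- graph$triples$o
  e$o_dt <- graph$triples$o_dt
  e$o_lang <- graph$triples$o_lang
  e$onpath <- new.env(parent = emptyenv())
  e$used <- if (track_used) rep(FALSE, nrow(graph$triples)) else NULL
  e$curies <- new.env(parent = emptyenv())  # predicate-IRI -> key cache
  e
}

# detect_special_node against the ctx column cache (hot path)
ctx_detect <- function(ctx, kind, value) {
  if (kind == "iri" && value == RDF_NIL) return("collection")
  idx <- subject_rows(ctx$graph, kind, value)
  if (length(idx) == 0L) return("plain")
  p <- ctx$p[idx]
  types <- ctx$o[idx][p == RDF_TYPE & ctx$o_kind[idx] == "iri"]
  if (RDF_BAG %in% types) return("container_bag")
  if (RDF_SEQ %in% types) return("container_seq")
  if (RDF_ALT %in% types) return("container_alt")
  if (any(p == RDF_FIRST)) return("collection")
  "plain"
}

ctx_mark_used <- function(ctx, idx) {
  if (!is.null(ctx$used) && length(idx) > 0L) ctx$used[idx] <- TRUE
}

ctx_key <- function(ctx, pred) {
  k <- get0(pred, envir = ctx$curies, inherits = FALSE)
  if (is.null(k)) {
    k <- compact_iri(pred, ctx$ns)
    assign(pred, k, envir = ctx$curies)
  }
  k
}

# Each accumulated value lives in its own environment binding: storing a
# deeply nested value into an env-held list via subassignment would
# duplicate it, making deep blank-node chains quadratic.
new_group <- function(key, schema = FALSE, item = FALSE) {
  g <- new.env(parent = emptyenv())
  g$key <- key; g$schema <- schema; g$item <- item
  g$nv <- 0L
  g
}

group_push <- function(g, v) {
  n <- g$nv + 1L
  assign(paste0("v", n), v, envir = g)
  g$nv <- n
}

group_values <- function(g) {
  lapply(seq_len(g$nv), function(i) get(paste0("v", i), envir = g))
}

# task fields: newgroup, key, schema, item, o_kind, o, o_dt, o_lang
task_list <- function(o_kind, o, o_dt, o_lang, keys, schema, newgroup,
                      item = FALSE) {
  lapply(seq_along(o_kind), function(i)
    list(newgroup = newgroup[i], key = keys[i], schema = schema[i], item = item,
         o_kind = o_kind[i], o = o[i], o_dt = o_dt[i], o_lang = o_lang[i]))
}

new_frame <- function(ftype, label = NA_character_) {
  f <- new.env(parent = emptyenv())
  f$ftype <- ftype; f$label <- label
  f$tasks <- list(); f$ti <- 0L
  f$groups <- list()
  f$typestr <- NA_character_
  f$n_items <- 0L
  f
}

make_resource_frame <- function(ctx, kind, value, top_schema) {
  f <- new_frame("resource", if (kind == "blank") value else NA_character_)
  idx <- subject_rows(ctx$graph, kind, value)
  ctx_mark_used(ctx, idx)
  if (length(idx) == 0L) return(f)
  p <- ctx$p[idx]; ok <- ctx$o_kind[idx]; o <- ctx$o[idx]
  dt <- ctx$o_dt[idx]; lg <- ctx$o_lang[idx]
  schema <- top_schema & p %in% SCHEMA_PREDICATES
  keys <- character(length(p))
  keys[schema] <- SCHEMA_KEYS[p[schema]]
  keys[!schema] <- vapply(p[!schema], function(pp) ctx_key(ctx, pp), "")
  # non-schema keys lexicographic, then schema keys in fixed order;
  # within a key, canonical object order
  key_rank <- ifelse(schema, sprintf("%02d", match(keys, SCHEMA_KEYS)), keys)
  ord <- order(schema, key_rank, node_rank(ok), o, dt, lg, method = "radix")
  keys <- keys[ord]; schema <- schema[ord]
  newgroup <- c(TRUE, keys[-1L] != keys[-length(keys)])
  f$tasks <- task_list(ok[ord], o[ord], dt[ord], lg[ord], keys, schema, newgroup)
  f
}

make_container_frame <- function(ctx, kind, value, ckind) {
  f <- new_frame("container", if (kind == "blank") value else NA_character_)
  f$typestr <- CONTAINER_TYPE_KEY[[ckind]]
  idx <- subject_rows(ctx$graph, kind, value)
  ctx_mark_used(ctx, idx)
  p <- ctx$p[idx]; ok <- ctx$o_kind[idx]; o <- ctx$o[idx]
  dt <- ctx$o_dt[idx]; lg <- ctx$o_lang[idx]
  n_ord <- ordinal_number(p)
  is_ord <- !is.na(n_ord)
  # the container-class rdf:type triple is retained as the "rdf:type" key
  type_i <- which(p == RDF_TYPE & ok == "iri" &
                  o == CONTAINER_CLASS_IRI[[ckind]])[1L]
  if (any(is_ord)) {
    u <- sort(unique(n_ord[is_ord]))
    if (!identical(u, seq_len(max(u))))
      warning(sprintf("container %s has a gap in its rdf:_N ordinals; members mapped as-is",
                      value), call. = FALSE)
    w <- which(is_ord)
    no <- n_ord[w]
    ord <- w[order(no, node_rank(ok[w]), o[w], dt[w], lg[w], method = "radix")]
    no <- n_ord[ord]
    keys <- sprintf("rdf:_%d", no)
    newgroup <- c(TRUE, no[-1L] != no[-length(no)])
    f$tasks <- task_list(ok[ord], o[ord], dt[ord], lg[ord], keys,
                         rep(FALSE, length(ord)), newgroup)
  }
  sib <- setdiff(which(!is_ord), type_i)
  if (length(sib) > 0L) {
    keys <- vapply(p[sib], function(pp) ctx_key(ctx, pp), "")
    ord <- sib[order(keys, node_rank(ok[sib]), o[sib], dt[sib], lg[sib],
                     method = "radix")]
    keys <- sort(keys, method = "radix")
    newgroup <- c(TRUE, keys[-1L] != keys[-length(keys)])
    f$tasks <- c(f$tasks, task_list(ok[ord], o[ord], dt[ord], lg[ord], keys,
                                    rep(FALSE, length(ord)), newgroup))
  }
  f
}

make_collection_frame <- function(ctx, kind, value) {
  f <- new_frame("collection", if (kind == "blank") value else NA_character_)
  item_tasks <- list()
  sib_tasks <- list()
  visited <- new.env(parent = emptyenv())
  cur_kind <- kind; cur_val <- value
  head_cell <- TRUE
  repeat {
    if (cur_kind == "iri" && cur_val == RDF_NIL) break
    ck <- subject_key(cur_kind, cur_val)
    if (!is.null(get0(ck, envir = visited, inherits = FALSE))) {
      warning(sprintf("cyclic rdf:rest chain at %s; collection truncated", cur_val),
              call. = FALSE)
      break
    }
    assign(ck, TRUE, envir = visited)
    idx <- subject_rows(ctx$graph, cur_kind, cur_val)
    p <- ctx$p[idx]; ok <- ctx$o_kind[idx]; o <- ctx$o[idx]
    dt <- ctx$o_dt[idx]; lg <- ctx$o_lang[idx]
    firsts <- which(p == RDF_FIRST)
    rests <- which(p == RDF_REST)
    ctx_mark_used(ctx, idx[c(firsts, rests)])
    if (length(firsts) > 0L) {
      ord <- firsts[order_objects(ok[firsts], o[firsts], dt[firsts], lg[firsts])]
      item_tasks <- c(item_tasks,
                      task_list(ok[ord], o[ord], dt[ord], lg[ord],
                                rep(NA_character_, length(ord)),
                                rep(FALSE, length(ord)),
                                rep(TRUE, length(ord)), item = TRUE))
    }
    extras <- setdiff(seq_along(idx), c(firsts, rests))
    if (length(extras) > 0L) {
      if (head_cell) {
        ctx_mark_used(ctx, idx[extras])
        keys <- vapply(p[extras], function(pp) ctx_key(ctx, pp), "")
        ord <- extras[order(keys, node_rank(ok[extras]), o[extras], dt[extras],
                            lg[extras], method = "radix")]
        keys <- sort(keys, method = "radix")
        newgroup <- c(TRUE, keys[-1L] != keys[-length(keys)])
        sib_tasks <- c(sib_tasks, task_list(ok[ord], o[ord], dt[ord], lg[ord],
                                            keys, rep(FALSE, length(ord)), newgroup))
      } else {
        warning(sprintf("extra properties on interior collection cell %s dropped",
                        cur_val), call. = FALSE)
      }
    }
    if (length(rests) == 0L) {
      warning(sprintf("rdf:rest chain at %s not terminated by rdf:nil", cur_val),
              call. = FALSE)
      break
    }
    if (length(rests) > 1L)
      warning(sprintf("multiple rdf:rest links at %s; following the canonical first",
                      cur_val), call. = FALSE)
    ro <- rests[order_objects(ok[rests], o[rests], dt[rests], lg[rests])]
    last <- ro[length(ro)]  # prefer a node-valued rest link
    if (ok[last] == "literal") {
      warning(sprintf("rdf:rest at %s points to a literal; chain truncated", cur_val),
              call. = FALSE)
      break
    }
    cur_kind <- ok[last]; cur_val <- o[last]
    head_cell <- FALSE
  }
  f$n_items <- length(item_tasks)
  f$tasks <- c(item_tasks, sib_tasks)
  f
}

make_frame_for <- function(ctx, kind, value, special, top_schema = FALSE) {
  if (special == "plain") make_resource_frame(ctx, kind, value, top_schema)
  else if (special == "collection") make_collection_frame(ctx, kind, value)
  else make_container_frame(ctx, kind, value, special)
}

# NOTE: values are assembled with list()/c()/lapply, never `out[[k]] <- v`:
# list subassignment duplicates an already-referenced RHS, which would make
# deep blank-node chains quadratic.
finalize_frame <- function(f) {
  groups <- f$groups
  if (f$ftype == "resource") {
    out <- lapply(groups, function(g) merge_values(group_values(g)))
    names(out) <- vapply(groups, function(g) g$key, "")
    return(jobj_from(out))
  }
  if (f$ftype == "collection") {
    items <- lapply(groups[seq_len(f$n_items)], function(g) get("v1", envir = g))
    sib <- groups[seq_len(length(groups) - f$n_items) + f$n_items]
    sv <- lapply(sib, function(g) merge_values(group_values(g)))
    names(sv) <- vapply(sib, function(g) g$key, "")
    return(jobj_from(c(list("rdf:type" = "rdf:List", "items" = jarr_from(items)),
                       sv)))
  }
  # container
  vals <- lapply(groups, function(g) merge_values(group_values(g)))
  keys <- vapply(groups, function(g) g$key, "")
  type_val <- f$typestr
  extra_t <- which(keys == "rdf:type")
  if (length(extra_t) > 0L) {
    # extra rdf:type statements merge with the retained container type
    vs <- unlist(lapply(vals[extra_t], function(v)
      if (is_jarr(v)) unclass(v) else list(v)), recursive = FALSE)
    type_val <- jarr_from(c(list(type_val), vs))
    vals <- vals[-extra_t]; keys <- keys[-extra_t]
  }
  names(vals) <- keys
  jobj_from(c(list("rdf:type" = type_val), vals))
}

# Run the engine for one root node; returns its JSON value structure.
# The frame stack is managed inline: routing it through a helper closure
# would force a copy of the stack list on every push.
run_expand <- function(ctx, kind, value, special, top_schema = FALSE) {
  stack <- vector("list", 32L)
  if (kind == "blank") assign(value, TRUE, envir = ctx$onpath)
  stack[[1L]] <- make_frame_for(ctx, kind, value, special, top_schema)
  sp <- 1L
  result <- NULL
  while (sp > 0L) {
    f <- stack[[sp]]
    if (f$ti < length(f$tasks)) {
      f$ti <- f$ti + 1L
      t <- f$tasks[[f$ti]]
      if (t$newgroup)
        f$groups[[length(f$groups) + 1L]] <- new_group(t$key, t$schema, t$item)
      g <- f$groups[[length(f$groups)]]
      if (t$o_kind == "literal") {
        if (t$schema)
          warning(sprintf("schema relation '%s' has a literal object (malformed schema)",
                          t$key), call. = FALSE)
        group_push(g, mk_literal_value(t$o, t$o_dt, t$o_lang, ctx$ns))
      } else if (t$o_kind == "iri") {
        if (t$schema) group_push(g, compact_iri(t$o, ctx$ns))
        else group_push(g, jobj("rdf:resource" = ctx_key(ctx, t$o)))
      } else {  # blank
        if (t$schema)
          warning(sprintf("schema relation '%s' has a blank-node object", t$key),
                  call. = FALSE)
        if (!is.null(get0(t$o, envir = ctx$onpath, inherits = FALSE))) {
          group_push(g, jobj("rdf:nodeID" = t$o))
        } else {
          assign(t$o, TRUE, envir = ctx$onpath)
          special_k <- ctx_detect(ctx, "blank", t$o)
          sp <- sp + 1L
          if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
          stack[[sp]] <- make_frame_for(ctx, "blank", t$o, special_k)
        }
      }
    } else {
      res <- finalize_frame(f)
      if (!is.na(f$label)) rm(list = f$label, envir = ctx$onpath)
      stack[sp] <- list(NULL)
      sp <- sp - 1L
      if (sp == 0L) {
        result <- res
      } else {
        parent <- stack[[sp]]
        group_push(parent$groups[[length(parent$groups)]], res)
      }
    }
  }
  result
}

#' Expand a blank node into its nested value object
#'
#' Every triple whose subject is `node` is mapped (literals, references,
#' further blank nodes, containers, collections, merged repeats). A blank
#' node already being expanded on the current branch (`path`) yields the
#' back-reference `{"rdf:nodeID": label}`, so arbitrary cycles terminate.
#'
#' @param graph An [rdf_graph].
#' @param node An `rdf_node` of kind `"blank"`.
#' @param path Character vector of blank labels on the current branch.
#' @param ns Namespace map (defaults to the graph's).
#' @return A `jobj`.
#' @export
expand_blank <- function(graph, node, path = character(0), ns = graph$namespaces) {
  if (!inherits(node, "rdf_node") || node$kind != "blank")
    rdf2json_error("expand_blank expects a blank node", "rdf2json_contract_error")
  if (node$value %in% path) return(jobj("rdf:nodeID" = node$value))
  ctx <- new_expand_ctx(graph, ns)
  for (p in path) assign(p, TRUE, envir = ctx$onpath)
  special <- detect_special_node(graph, node)
  run_expand(ctx, "blank", node$value, special)
}

#' Map a container node (Bag/Seq/Alt)
#'
#' Container-shape: `{"rdf:type": type, "rdf:_1": v1, ...}` with ordinal
#' keys ascending; the container type is retained under `"rdf:type"`.
#' Ordinal gaps are kept as-is with a warning; non-ordinal member
#' properties become sibling keys.
#'
#' @param graph An [rdf_graph].
#' @param node Container node (`rdf_node`, iri or blank).
#' @param kind One of `"container_bag"`, `"container_seq"`, `"container_alt"`
#'   (as returned by [detect_special_node]).
#' @param ns Namespace map.
#' @return A container-shape `jobj`.
#' @export
map_container <- function(graph, node, kind, ns = graph$namespaces) {
  if (!kind %in% names(CONTAINER_TYPE_KEY))
    rdf2json_error("kind must be a container kind", "rdf2json_contract_error")
  ctx <- new_expand_ctx(graph, ns)
  run_expand(ctx, node$kind, node$value, kind)
}

#' Map a collection (rdf:List)
#'
#' Collection-shape: `{"rdf:type": "rdf:List", "items": [...]}` with items
#' in chain order. `rdf:nil` maps to an empty item list. Chains not
#' terminated by `rdf:nil` are collected up to the break; cyclic chains
#' truncate at the revisit (both with a warning).
#'
#' @param graph An [rdf_graph].
#' @param head Chain head (`rdf_node`, iri or blank, possibly `rdf:nil`).
#' @param ns Namespace map.
#' @return A collection-shape `jobj`.
#' @export
map_collection <- function(graph, head, ns = graph$namespaces) {
  ctx <- new_expand_ctx(graph, ns)
  run_expand(ctx, head$kind, head$value, "collection")
}
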