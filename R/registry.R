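#' Decision-node registry and pathway specifications
#'
#' The preparation algorithm is organised as ten ordered decision nodes in
#' three steps: Step A cleans the raw quantity (`qty`), numeric daily dose
#' (`ndd`) and duration fields (nodes 1-5); Step B derives a stop date per
#' prescription and resolves missing stop dates (nodes 6-7); Step C collapses
#' same-day duplicates, resolves overlapping prescriptions and closes short
#' gaps between episodes (nodes 8-10). Each node offers a fixed menu of
#' assumption options; a complete choice of one option per node is a
#' *pathway*, i.e. one fully specified data-preparation recipe.
#'
#' Option tokens are `"<node><letter>"`, with a day parameter in parentheses
#' where the option is parameterised, e.g. `"6d(30)"` or `"10b(60)"`.
#'
#' @name decision_registry
NULL

.make_node <- function(node_id, step, label, options) {
  list(node_id = as.integer(node_id), step = step, label = label,
       options = options)
}

#' Default decision registry (10 nodes, 54 options)
#'
#' Returns the registry of the full decision framework:
#'
#' * Node 1: implausible `qty` — 1a leave; 1b set missing; 1c product
#'   population mean of plausible values; 1d patient mean of plausible values
#'   for that product; 1e cap at the nearest plausibility bound.
#' * Node 2: missing `qty` — 2a leave missing; 2b population mean; 2c patient
#'   mean; 2d carry the patient's previous value forward; 2e product default.
#' * Node 3: implausible `ndd` — 3a-3e, mirroring node 1.
#' * Node 4: missing `ndd` — 4a leave missing; 4b patient mean; 4c population
#'   mean; 4d carry forward; 4e product default.
#' * Node 5: implausible duration fields (`numdays`, `dose_duration`) —
#'   5a leave; 5b set missing; 5c cap; 5d population mean plausible duration;
#'   5e patient mean plausible duration.
#' * Node 6: stop-date source — 6a start + `numdays`; 6b start +
#'   `dose_duration`; 6c start + `qty`/`ndd`; 6d(x), x in {15, 30, 60, 90}:
#'   reconcile the available candidates (see [select_stop_date()]).
#' * Node 7: missing stop date — 7a keep missing (record dropped at the end
#'   of the node); 7b patient mean duration for that product; 7c population
#'   mean duration; 7d product default duration; 7e carry the duration of the
#'   patient's previous prescription for that product forward.
#' * Node 8: multiple same-product prescriptions on the same day — 8a keep
#'   longest; 8b keep shortest; 8c sum durations; 8d mean duration; 8e keep
#'   all and defer to node 9.
#' * Node 9: overlapping successive prescriptions in a class — 9a stockpile
#'   (delay the later, preserving duration); 9b truncate the earlier; 9c merge
#'   to the interval union; 9d sum durations from the earliest start; 9e drop
#'   the later record.
#' * Node 10: gaps between successive episodes — 10a never bridge; 10b(x),
#'   x in {7, 15, 30, 60, 90}: continuous when the gap is < x days; 10c
#'   continuously exposed from first start to last stop.
#'
#' @return an object of class `decision_registry`: a list with element
#'   `nodes`, an ordered list of ten nodes each holding `node_id`, `step`
#'   (`"A"`, `"B"` or `"C"`), `label` and the ordered character vector
#'   `options` of tokens.
#' @examples
#' reg <- default_registry()
#' length(reg$nodes)
#' sum(lengths(lapply(reg$nodes, `[[`, "options")))
#' count_pathways(reg)
#' @export
default_registry <- function() {
  nodes <- list(
    .make_node(1L, "A", "implausible quantity (qty)",
               paste0("1", letters[1:5])),
    .make_node(2L, "A", "missing quantity (qty)",
               paste0("2", letters[1:5])),
    .make_node(3L, "A", "implausible daily dose (ndd)",
               paste0("3", letters[1:5])),
    .make_node(4L, "A", "missing daily dose (ndd)",
               paste0("4", letters[1:5])),
    .make_node(5L, "A", "implausible duration fields",
               paste0("5", letters[1:5])),
    .make_node(6L, "B", "stop-date source",
               c("6a", "6b", "6c", "6d(15)", "6d(30)", "6d(60)", "6d(90)")),
    .make_node(7L, "B", "missing stop date",
               paste0("7", letters[1:5])),
    .make_node(8L, "C", "same-day duplicate prescriptions",
               paste0("8", letters[1:5])),
    .make_node(9L, "C", "overlapping prescriptions",
               paste0("9", letters[1:5])),
    .make_node(10L, "C", "gaps between successive episodes",
               c("10a", "10b(7)", "10b(15)", "10b(30)", "10b(60)",
                 "10b(90)", "10c"))
  )
  structure(list(nodes = nodes), class = "decision_registry")
}

#' @export
print.decision_registry <- function(x, ...) {
  cat("Decision registry:", length(x$nodes), "nodes,",
      sum(lengths(lapply(x$nodes, `[[`, "options"))), "options\n")
  for (nd in x$nodes) {
    cat(sprintf("  [%s] node %2d  %-38s %s\n", nd$step, nd$node_id, nd$label,
                paste(nd$options, collapse = " ")))
  }
  invisible(x)
}

# ---- option token helpers ----------------------------------------------

#' Parse option tokens
#'
#' `option_node()` extracts the node number, `option_base()` strips a day
#' parameter, and `option_param()` extracts it (NA when absent).
#'
#' @param token character vector of option tokens such as `"6d(30)"`
#' @return integer, character, or numeric vector respectively
#' @examples
#' option_node("10b(60)")
#' option_base("10b(60)")
#' option_param("10b(60)")
#' @export
option_node <- function(token) as.integer(sub("^([0-9]+).*$", "\\1", token))

#' @rdname option_node
#' @export
option_base <- function(token) sub("\\(.*$", "", token)

#' @rdname option_node
#' @export
option_param <- function(token) {
  out <- rep(NA_real_, length(token))
  has <- grepl("\\(", token)
  out[has] <- as.numeric(sub("^.*\\(([0-9]+)\\)$", "\\1", token[has]))
  out
}

# ---- pathway specs ------------------------------------------------------

#' Parse and format pathway specifications
#'
#' A pathway spec is a named character vector mapping node id (as the name,
#' `"1"` to `"10"`) to the chosen option token. The plain-text serialisation
#' is the comma-separated token list, e.g.
#' `"1b,2a,3b,4b,5b,6c,7b,8c,9a,10b(15)"`.
#'
#' @param x for `parse_pathway()`, a single comma-separated token string;
#'   for `format_pathway()`, a pathway spec
#' @return `parse_pathway()` returns a `pathway_spec`; `format_pathway()`
#'   returns the token string.
#' @examples
#' spec <- parse_pathway("1b,2a,3b,4b,5b,6c,7b,8c,9a,10b(15)")
#' format_pathway(spec)
#' @export
parse_pathway <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tokens <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  spec <- setNames(tokens, as.character(option_node(tokens)))
  class(spec) <- "pathway_spec"
  spec
}

#' @rdname parse_pathway
#' @export
format_pathway <- function(x) paste(unclass(x), collapse = ",")

#' @export
print.pathway_spec <- function(x, ...) {
  cat("Pathway:", format_pathway(x), "\n")
  invisible(x)
}

#' Default primary pathway
#'
#' The package's reference preparation recipe: set implausible values
#' missing (1b, 3b, 5b), leave missing `qty` (2a), impute missing `ndd` from
#' the patient's own plausible values (4b), derive stop dates from
#' `qty`/`ndd` (6c, the best-populated source), impute missing stop dates
#' from the patient's mean duration for the product (7b), sum same-day
#' duplicates (8c), stockpile overlaps (9a), and bridge gaps shorter than
#' 15 days (10b(15)).
#'
#' @return a `pathway_spec`
#' @examples
#' default_primary_pathway()
#' @export
default_primary_pathway <- function() {
  parse_pathway("1b,2a,3b,4b,5b,6c,7b,8c,9a,10b(15)")
}

#' Validate a pathway specification against a registry
#'
#' @param spec a `pathway_spec` (or named character vector / token string)
#' @param registry a `decision_registry`
#' @return `TRUE` iff `spec` chooses exactly one valid token for every node
#'   of the registry; otherwise `FALSE` (never an error).
#' @examples
#' validate_pathway(default_primary_pathway(), default_registry())
#' @export
validate_pathway <- function(spec, registry = default_registry()) {
  if (is.character(spec) && length(spec) == 1L && grepl(",", spec))
    spec <- tryCatch(parse_pathway(spec), error = function(e) NULL)
  if (is.null(spec)) return(FALSE)
  tokens <- unclass(spec)
  ids <- vapply(registry$nodes, `[[`, integer(1), "node_id")
  if (length(tokens) != length(ids)) return(FALSE)
  nms <- names(tokens) %||% as.character(option_node(tokens))
  if (anyNA(suppressWarnings(as.integer(nms)))) return(FALSE)
  if (!setequal(as.integer(nms), ids)) return(FALSE)
  if (anyDuplicated(nms)) return(FALSE)
  for (nd in registry$nodes) {
    tok <- tokens[[as.character(nd$node_id)]]
    if (!tok %in% nd$options) return(FALSE)
  }
  TRUE
}

# pull the chosen token for one node, with a validity check
.spec_token <- function(spec, node_id) {
  tok <- unclass(spec)[[as.character(node_id)]]
  if (is.null(tok) || is.na(tok))
    stop("pathway spec has no option for node ", node_id)
  if (option_node(tok) != node_id)
    stop("token '", tok, "' does not belong to node ", node_id)
  tok
}

# ---- registry serialisation --------------------------------------------

#' Read and write a registry as a YAML mapping
#'
#' @param registry a `decision_registry`
#' @param file path to a YAML file
#' @return `read_registry()` returns a `decision_registry`;
#'   `write_registry()` returns `file` invisibly.
#' @export
write_registry <- function(registry, file) {
  x <- lapply(registry$nodes, function(nd) {
    list(node_id = nd$node_id, step = nd$step, label = nd$label,
         options = as.list(nd$options))
  })
  yaml::write_yaml(list(nodes = x), file)
  invisible(file)
}

#' @rdname write_registry
#' @export
read_registry <- function(file) {
  x <- yaml::read_yaml(file)
  nodes <- lapply(x$nodes, function(nd) {
    .make_node(nd$node_id, nd$step, nd$label, unlist(nd$options))
  })
  reg <- structure(list(nodes = nodes), class = "decision_registry")
  .check_registry(reg)
  reg
}

.check_registry <- function(registry) {
  ids <- vapply(registry$nodes, `[[`, integer(1), "node_id")
  if (anyDuplicated(ids)) stop("duplicate node ids in registry")
  for (nd in registry$nodes) {
    if (anyDuplicated(nd$options))
      stop("duplicate option tokens in node ", nd$node_id)
    if (!all(option_node(nd$options) == nd$node_id))
      stop("option token assigned to wrong node ", nd$node_id)
  }
  invisible(registry)
}
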