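#' Pathway enumeration, sampling and execution
#'
#' A pathway is one complete recipe: one option at each of the ten decision
#' nodes. The pathway space is the Cartesian product of the per-node option
#' menus; [run_pathway()] executes one recipe end-to-end, strictly in node
#' order 1 to 10 (no option may inspect a later node's choice), and returns
#' the prepared exposure timeline together with the audit ledger.
#'
#' @name pathways
NULL

#' Number of distinct complete pathways
#'
#' @param registry a `decision_registry`
#' @return the product over nodes of their option counts
#' @examples
#' count_pathways(default_registry())
#' @export
count_pathways <- function(registry = default_registry()) {
  prod(lengths(lapply(registry$nodes, `[[`, "options")))
}

#' Exhaustively enumerate all pathways
#'
#' Intended for small registries (the full default registry has about
#' 19 million pathways and is refused above `max_n`).
#'
#' @param registry a `decision_registry`
#' @param max_n refuse enumeration beyond this many pathways
#' @return list of `pathway_spec` objects
#' @export
enumerate_pathways <- function(registry, max_n = 1e5) {
  n <- count_pathways(registry)
  if (n > max_n)
    stop("registry has ", n, " pathways; refusing to enumerate more than ",
         max_n)
  opts <- lapply(registry$nodes, `[[`, "options")
  ids <- vapply(registry$nodes, `[[`, integer(1), "node_id")
  grid <- do.call(CJ, c(rev(opts), list(sorted = FALSE)))
  setcolorder(grid, rev(names(grid)))
  lapply(seq_len(nrow(grid)), function(i) {
    spec <- setNames(as.character(unlist(grid[i])), as.character(ids))
    class(spec) <- "pathway_spec"
    spec
  })
}

#' Sample random pathways
#'
#' Draws `k` pathways uniformly and independently over the full pathway
#' space (duplicates permitted), reproducibly for a given seed.
#'
#' @param registry a `decision_registry`
#' @param k number of pathways
#' @param seed integer RNG seed
#' @return list of `k` `pathway_spec` objects
#' @examples
#' length(sample_random_pathways(default_registry(), 50, seed = 1))
#' @export
sample_random_pathways <- function(registry, k, seed) {
  stopifnot(k >= 1)
  opts <- lapply(registry$nodes, `[[`, "options")
  ids <- as.character(vapply(registry$nodes, `[[`, integer(1), "node_id"))
  with_seed(seed, {
    lapply(seq_len(k), function(i) {
      spec <- setNames(
        vapply(opts, function(o) o[sample.int(length(o), 1L)], character(1)),
        ids)
      class(spec) <- "pathway_spec"
      spec
    })
  })
}

#' One-at-a-time variants of a primary pathway
#'
#' Returns one variant per non-chosen option across all nodes; each variant
#' differs from the primary at exactly one node. For the default registry
#' (54 options, 10 nodes) there are 44 variants.
#'
#' @param primary a valid `pathway_spec`
#' @param registry a `decision_registry`
#' @return list of `pathway_spec` objects; each carries attributes
#'   `varied_node` and `varied_option`
#' @export
one_at_a_time_variants <- function(primary, registry = default_registry()) {
  if (!validate_pathway(primary, registry))
    stop("primary pathway is not valid for this registry")
  out <- list()
  for (nd in registry$nodes) {
    chosen <- unclass(primary)[[as.character(nd$node_id)]]
    for (opt in setdiff(nd$options, chosen)) {
      variant <- primary
      variant[[as.character(nd$node_id)]] <- opt
      attr(variant, "varied_node") <- nd$node_id
      attr(variant, "varied_option") <- opt
      out[[length(out) + 1L]] <- variant
    }
  }
  out
}

#' Execute one preparation pathway end-to-end
#'
#' Applies nodes 1-10 in order: quantity cleaning (1-2), daily-dose cleaning
#' (3-4), duration-field cleaning (5), stop-date assignment (6), missing
#' stop-date resolution with the footnoted drop rule (7), same-day collapse
#' (8), overlap resolution (9), gap closure (10), and finally clips the
#' episodes to follow-up when a follow-up table is given.
#'
#' @param raw therapy table of raw prescription records
#' @param spec a `pathway_spec` (or its token-string serialisation)
#' @param plausibility plausibility table
#' @param followup optional follow-up table (`patient_id`, `entry`, `exit`);
#'   when `NULL` the unclipped timeline is returned
#' @param registry registry used to validate `spec`
#' @return list with elements `episodes` (the final timeline) and `ledger`
#'   (the per-node audit table)
#' @examples
#' pl <- data.frame(product_code = "P1", drug_class = "drug",
#'                  qty_min = 1, qty_max = 500, ndd_min = 0.5, ndd_max = 12,
#'                  dur_min = 1, dur_max = 186, default_qty = 56,
#'                  default_ndd = 2, default_duration_days = 28)
#' rx <- data.frame(patient_id = 1, product_code = "P1", start_date = 10,
#'                  qty = 28, ndd = 1, numdays = NA, dose_duration = NA)
#' fu <- data.frame(patient_id = 1, entry = 0, exit = 100)
#' run_pathway(rx, default_primary_pathway(), pl, fu)$episodes
#' @export
run_pathway <- function(raw, spec, plausibility, followup = NULL,
                        registry = default_registry()) {
  if (!inherits(spec, "pathway_spec")) spec <- parse_pathway(spec)
  if (!validate_pathway(spec, registry))
    stop("invalid pathway spec: ", format_pathway(spec))
  ledger <- new_ledger()
  rx <- as_therapy(raw)
  if (nrow(rx) == 0L) {
    for (node in as.character(1:10)) ledger_add(ledger, node, 0L)
    ledger_add(ledger, "clip", 0L)
    return(list(
      episodes = data.table(patient_id = rx$patient_id[0],
                            drug_class = character(),
                            start = integer(), stop = integer()),
      ledger = ledger_table(ledger)))
  }
  rx <- clean_quantity(rx, .spec_token(spec, 1L), .spec_token(spec, 2L),
                       plausibility, ledger)
  rx <- clean_daily_dose(rx, .spec_token(spec, 3L), .spec_token(spec, 4L),
                         plausibility, ledger)
  rx <- clean_duration_fields(rx, .spec_token(spec, 5L), plausibility, ledger)
  rx <- assign_stop_dates(rx, .spec_token(spec, 6L), ledger)
  rx <- resolve_missing_stop(rx, .spec_token(spec, 7L), plausibility, ledger)
  if (nrow(rx)) {
    rx <- collapse_same_day(rx, .spec_token(spec, 8L), ledger)
    ep <- records_to_episodes(rx, plausibility)
    ep <- resolve_overlaps(ep, .spec_token(spec, 9L), ledger)
    ep <- close_gaps(ep, .spec_token(spec, 10L), ledger)
  } else {
    for (node in as.character(8:10)) ledger_add(ledger, node, 0L)
    ep <- data.table(patient_id = rx$patient_id[0], drug_class = character(),
                     start = integer(), stop = integer())
  }
  if (!is.null(followup)) {
    ep <- build_exposure_timeline(ep, followup, ledger)
  }
  list(episodes = ep, ledger = ledger_table(ledger))
}
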