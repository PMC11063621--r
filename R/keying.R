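#' Identification engines: strict matching and probability ranking
#'
#' A *selection* is the user's observations: a named list mapping group ids
#' to the state token(s) observed, e.g.
#' `list(corolla_shape = "tube", region = "Cape Peninsula")`. Both engines
#' accept the same selection.
#'
#' **Strict matching** ([strict_match()]) returns the taxa whose coding
#' intersects the selected states in *every* constrained group; a taxon with
#' missing coding in any constrained group is excluded.
#'
#' **Probability ranking** ([probability_rank()]) is tolerant of mismatches
#' and missing data. Each constrained group contributes `1 / n` where `n` is
#' the number of taxa in the ranking population carrying at least one of the
#' selected states in that group (the *carriers*); a taxon earns the group's
#' contribution iff it is a carrier, and its score is the sum of the earned
#' contributions. Rare states therefore weigh more than common ones, and
#' selecting several states in one group — expressing uncertainty — enlarges
#' the carrier set and dilutes the contribution. Taxa are listed in
#' descending score order; equal scores are broken alphabetically.
#'
#' @name keying
NULL

# validate a selection against a dataset's schema; returns the normalised
# selection (a named list of character vectors)
check_selection <- function(ds, selection) {
  if (!is.list(selection) || length(selection) == 0L) {
    stop("selection must constrain at least one character group",
         call. = FALSE)
  }
  if (is.null(names(selection)) || any(!nzchar(names(selection)))) {
    stop("selection must be a named list: list(group_id = states, ...)",
         call. = FALSE)
  }
  if (anyDuplicated(names(selection))) {
    stop("selection names a group more than once", call. = FALSE)
  }
  out <- list()
  for (gid in names(selection)) {
    g <- schema_group(ds$schema, gid)
    states <- unique(as.character(selection[[gid]]))
    if (length(states) == 0L) {
      stop("selection for group '", gid, "' is empty", call. = FALSE)
    }
    check_states(g, states)
    out[[gid]] <- states
  }
  out
}

#' Taxa carrying a selected state
#'
#' The carriers of a state set are the taxa of the ranking population whose
#' coding for the group includes *at least one* of the selected states
#' (union semantics — selecting several states can only enlarge the set,
#' never shrink it to the taxa carrying all of them).
#'
#' @param ds an `erica_dataset`.
#' @param group_id a group id of the dataset's schema.
#' @param states one or more state tokens of that group.
#' @param population see [ranking_population()].
#' @return sorted character vector of carrier taxon ids.
#' @export
state_carriers <- function(ds, group_id, states,
                           population = c("terminal", "species")) {
  stopifnot(inherits(ds, "erica_dataset"))
  g <- schema_group(ds$schema, group_id)
  states <- unique(as.character(states))
  if (!length(states)) stop("'states' must be nonempty", call. = FALSE)
  check_states(g, states)
  pop <- ranking_population(ds, population)
  cd <- ds$codings[ds$codings$group_id == group_id &
                   ds$codings$taxon_id %in% pop, , drop = FALSE]
  if (!nrow(cd)) return(character(0))
  carried <- vapply(strsplit(cd$states, "|", fixed = TRUE),
                    function(s) any(s %in% states), TRUE)
  sort(unique(cd$taxon_id[carried]))
}

#' Probability contribution of one constrained group
#'
#' The reciprocal-prevalence contribution: `1 / n` over the `n` carriers of
#' the selected state set, so that the carriers share exactly one unit of
#' probability between them. A state carried by a single taxon contributes
#' 1; a state carried by no taxon is degenerate (`1/0` is undefined) and
#' contributes 0 to everyone, with a warning naming the group, so that a
#' likely observation error surfaces without aborting the ranking.
#'
#' @inheritParams state_carriers
#' @return an object of class `erica_contribution`: list with `group_id`,
#'   `states`, `carrier_count`, `carriers` and `value`.
#' @examples
#' we <- worked_example()
#' group_contribution(we$dataset, "corolla_shape", "tube")
#' @export
group_contribution <- function(ds, group_id, states,
                               population = c("terminal", "species")) {
  carriers <- state_carriers(ds, group_id, states, population)
  n <- length(carriers)
  if (n == 0L) {
    warning("no taxon carries the selected state(s) in group '", group_id,
            "'; the group contributes 0", call. = FALSE)
  }
  structure(
    list(group_id = group_id, states = unique(as.character(states)),
         carrier_count = n, carriers = carriers,
         value = if (n > 0L) 1 / n else 0),
    class = "erica_contribution"
  )
}

#' @export
print.erica_contribution <- function(x, ...) {
  cat(sprintf("<group contribution> %s = {%s}: %d carriers, value %s\n",
              x$group_id, paste(x$states, collapse = ", "),
              x$carrier_count, format_probability(x$value)))
  invisible(x)
}

#' Probability-ranked identification
#'
#' Scores every taxon of the ranking population against a selection and
#' returns them in descending score order, ties broken alphabetically by
#' name (case-insensitive, accent-stripped). Taxa scoring zero are omitted
#' unless `include_zero = TRUE`.
#'
#' @param ds an `erica_dataset`.
#' @param selection named list mapping group ids to observed state token(s).
#' @param include_zero keep taxa earning no contribution at all.
#' @param population see [ranking_population()].
#' @return a data frame of class `erica_ranking`: columns `taxon_id`,
#'   `name`, `score`, `matched_groups`, then one earned-contribution column
#'   per constrained group, named `contrib_<group_id>`. The per-group
#'   contribution values are kept in `attr(, "contributions")`.
#' @examples
#' we <- worked_example()
#' top <- probability_rank(we$dataset, we$selection)
#' format_probability(top$score[1])
#' @export
probability_rank <- function(ds, selection, include_zero = FALSE,
                             population = c("terminal", "species")) {
  stopifnot(inherits(ds, "erica_dataset"))
  selection <- check_selection(ds, selection)
  pop <- ranking_population(ds, population)

  contribs <- lapply(names(selection), function(gid) {
    group_contribution(ds, gid, selection[[gid]], population)
  })
  names(contribs) <- names(selection)

  earned <- matrix(0, nrow = length(pop), ncol = length(selection),
                   dimnames = list(pop, names(selection)))
  for (ct in contribs) {
    earned[ct$carriers, ct$group_id] <- ct$value
  }
  carried <- matrix(FALSE, nrow = length(pop), ncol = length(selection),
                    dimnames = list(pop, names(selection)))
  for (ct in contribs) carried[ct$carriers, ct$group_id] <- TRUE

  out <- data.frame(
    taxon_id = pop,
    name = ds$taxa$name[match(pop, ds$taxa$taxon_id)],
    score = rowSums(earned),
    matched_groups = rowSums(carried),
    stringsAsFactors = FALSE
  )
  for (gid in names(selection)) {
    out[[paste0("contrib_", gid)]] <- earned[, gid]
  }
  if (!include_zero) out <- out[out$score > 0, , drop = FALSE]
  out <- out[order(-out$score, name_collation_key(out$name), out$taxon_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, contributions = contribs,
            class = c("erica_ranking", "data.frame"))
}

#' @export
print.erica_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<probability ranking> %d taxa\n", nrow(x)))
  m <- min(n, nrow(x))
  if (m > 0) {
    shown <- head(as.data.frame(x), m)
    shown$score <- format_probability(shown$score)
    for (cl in grep("^contrib_", names(shown), value = TRUE)) {
      shown[[cl]] <- format_probability(shown[[cl]])
    }
    print(shown)
    if (nrow(x) > m) cat("  ...", nrow(x) - m, "more\n")
  }
  invisible(x)
}

#' Strict identification
#'
#' Returns the taxa consistent with *every* constrained group: the coding of
#' the taxon must intersect the selected states in each group. Missing
#' coding counts as a mismatch — a taxon uncoded for a constrained group is
#' excluded, which is exactly where the probability ranking is more
#' forgiving.
#'
#' @inheritParams probability_rank
#' @return character vector of taxon ids, sorted by name.
#' @export
strict_match <- function(ds, selection,
                         population = c("terminal", "species")) {
  stopifnot(inherits(ds, "erica_dataset"))
  selection <- check_selection(ds, selection)
  hits <- NULL
  for (gid in names(selection)) {
    carriers <- state_carriers(ds, gid, selection[[gid]], population)
    hits <- if (is.null(hits)) carriers else intersect(hits, carriers)
    if (!length(hits)) return(character(0))
  }
  nm <- ds$taxa$name[match(hits, ds$taxa$taxon_id)]
  hits[order(name_collation_key(nm), hits)]
}

#' Compare the codings of two or more taxa
#'
#' Builds a side-by-side table of coded state sets, one row per character
#' group in schema order (or a requested subset), one column per taxon.
#' A taxon with no coding for a group shows `NA` ("missing"), which is
#' distinct from two taxa being coded with disjoint states.
#'
#' @param ds an `erica_dataset`.
#' @param taxon_ids two or more distinct accepted taxon ids.
#' @param group_ids optional subset of group ids; default all groups.
#' @return a data frame of class `erica_comparison`: columns `group_id`,
#'   `label`, then one pipe-joined state-set column per taxon (named by
#'   taxon id; taxon names in `attr(, "taxon_names")`).
#' @export
compare_taxa <- function(ds, taxon_ids, group_ids = NULL) {
  stopifnot(inherits(ds, "erica_dataset"))
  taxon_ids <- as.character(taxon_ids)
  if (anyDuplicated(taxon_ids)) {
    stop("taxon ids to compare must be distinct", call. = FALSE)
  }
  if (length(taxon_ids) < 2L) {
    stop("need at least two taxa to compare", call. = FALSE)
  }
  idx <- match(taxon_ids, ds$taxa$taxon_id)
  if (anyNA(idx)) {
    stop("unknown taxon id(s): ",
         paste0("'", taxon_ids[is.na(idx)], "'", collapse = ", "),
         call. = FALSE)
  }
  not_acc <- ds$taxa$status[idx] != "accepted"
  if (any(not_acc)) {
    stop("only accepted taxa can be compared; not accepted: ",
         paste0("'", taxon_ids[not_acc], "'", collapse = ", "),
         call. = FALSE)
  }
  if (is.null(group_ids)) {
    group_ids <- group_ids(ds$schema)
  } else {
    for (gid in group_ids) schema_group(ds$schema, gid)
  }
  out <- data.frame(
    group_id = group_ids,
    label = vapply(group_ids, function(g) ds$schema[[g]]$label, ""),
    stringsAsFactors = FALSE
  )
  for (tid in taxon_ids) {
    out[[tid]] <- vapply(group_ids, function(gid) {
      s <- coding_states(ds, tid, gid)
      if (length(s)) join_states(s) else NA_character_
    }, "")
  }
  rownames(out) <- NULL
  structure(out, taxon_names = ds$taxa$name[idx],
            class = c("erica_comparison", "data.frame"))
}

#' @export
print.erica_comparison <- function(x, ...) {
  cat("<taxon comparison>\n")
  df <- as.data.frame(x)
  tids <- setdiff(names(df), c("group_id", "label"))
  nms <- attr(x, "taxon_names")
  for (i in seq_along(tids)) {
    cat(sprintf("  %s = %s\n", tids[i], nms[i]))
  }
  df[is.na(df)] <- "(missing)"
  print(df[, c("group_id", tids)], right = FALSE)
  invisible(x)
}
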