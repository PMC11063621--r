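#' Assemble a key dataset
#'
#' A key dataset bundles everything an identification session needs: the
#' character schema, the taxon checklist (accepted species and subspecific
#' taxa, plus synonyms and unplaced names kept solely for name lookup), the
#' character-state codings, the quarter-degree-square (QDS) distribution
#' table, and curated occurrence points.
#'
#' `key_dataset()` only coerces the tables to their canonical columns; use
#' [validate_dataset()] to check referential integrity and vocabulary
#' membership, or [load_dataset()] which validates on read.
#'
#' @param schema an `erica_schema`, see [character_schema()].
#' @param taxa data frame with columns `taxon_id`, `name`, `rank`
#'   (`species`/`subspecies`/`variety`), `parent_id`, `status`
#'   (`accepted`/`synonym`/`unplaced`), `accepted_id`, `wfo_id`, `iucn`,
#'   `sort_schumann`, `sort_idno`. Missing optional fields are `NA`.
#' @param codings data frame with columns `taxon_id`, `group_id`, `states`
#'   (state tokens pipe-joined, e.g. `"pink|red"`; empty string = uncoded).
#' @param distributions data frame with columns `taxon_id`, `qds`, one row
#'   per taxon-square pair.
#' @param points data frame with columns `taxon_id`, `latitude`, `longitude`
#'   (decimal degrees WGS84), `source_label`, `source_url`.
#' @return an object of class `erica_dataset`.
#' @export
key_dataset <- function(schema,
                        taxa = empty_taxa(),
                        codings = empty_codings(),
                        distributions = empty_distributions(),
                        points = empty_points()) {
  stopifnot(inherits(schema, "erica_schema"))
  structure(
    list(
      schema = schema,
      taxa = canon_table(taxa, taxa_cols()),
      codings = canon_table(codings, codings_cols()),
      distributions = canon_table(distributions, dist_cols()),
      points = canon_table(points, points_cols(),
                           numeric_cols = c("latitude", "longitude"))
    ),
    class = "erica_dataset"
  )
}

taxa_cols <- function() c("taxon_id", "name", "rank", "parent_id", "status",
                          "accepted_id", "wfo_id", "iucn", "sort_schumann",
                          "sort_idno")
codings_cols <- function() c("taxon_id", "group_id", "states")
dist_cols <- function() c("taxon_id", "qds")
points_cols <- function() c("taxon_id", "latitude", "longitude",
                            "source_label", "source_url")

empty_taxa <- function() canon_table(NULL, taxa_cols())
empty_codings <- function() canon_table(NULL, codings_cols())
empty_distributions <- function() canon_table(NULL, dist_cols())
empty_points <- function() {
  canon_table(NULL, points_cols(), numeric_cols = c("latitude", "longitude"))
}

# coerce a table to the canonical column set/order and NA-for-blank encoding
canon_table <- function(df, cols, numeric_cols = character(0)) {
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  df <- as.data.frame(df)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, cols, drop = FALSE]
  for (cl in cols) {
    if (cl %in% numeric_cols) {
      df[[cl]] <- as.numeric(df[[cl]])
    } else {
      v <- as.character(df[[cl]])
      if (cl != "states") v[!is.na(v) & !nzchar(v)] <- NA_character_
      if (cl == "states") v[is.na(v)] <- ""
      df[[cl]] <- v
    }
  }
  rownames(df) <- NULL
  df
}

#' @export
print.erica_dataset <- function(x, ...) {
  acc <- sum(x$taxa$status == "accepted", na.rm = TRUE)
  cat("<key dataset>\n")
  cat(sprintf("  schema:        %d character groups\n", length(x$schema)))
  cat(sprintf("  taxa:          %d (%d accepted, %d synonyms, %d unplaced)\n",
              nrow(x$taxa), acc,
              sum(x$taxa$status == "synonym", na.rm = TRUE),
              sum(x$taxa$status == "unplaced", na.rm = TRUE)))
  cat(sprintf("  codings:       %d rows\n", nrow(x$codings)))
  cat(sprintf("  distributions: %d taxon-QDS pairs\n", nrow(x$distributions)))
  cat(sprintf("  points:        %d occurrence points\n", nrow(x$points)))
  invisible(x)
}

# states of one taxon in one group, character(0) when uncoded
coding_states <- function(ds, taxon_id, group_id) {
  hit <- ds$codings$taxon_id == taxon_id & ds$codings$group_id == group_id
  if (!any(hit)) return(character(0))
  split_states(ds$codings$states[which(hit)[1]])
}

#' The ranking population of a dataset
#'
#' Identification (both strict and probability mode) runs over a defined
#' population of codeable taxa. The default, `"terminal"`, is the finest
#' accepted level: accepted species that have no accepted subspecific taxa,
#' plus all accepted subspecies and varieties. The alternative `"species"`
#' restricts to accepted species only. Synonyms and unplaced names are never
#' part of the population.
#'
#' @param ds an `erica_dataset`.
#' @param population `"terminal"` (default) or `"species"`.
#' @return character vector of taxon ids.
#' @export
ranking_population <- function(ds, population = c("terminal", "species")) {
  population <- match.arg(population)
  tx <- ds$taxa
  acc <- tx[!is.na(tx$status) & tx$status == "accepted", , drop = FALSE]
  if (population == "species") {
    return(acc$taxon_id[acc$rank == "species"])
  }
  infra <- acc$rank %in% c("subspecies", "variety")
  parents_with_infra <- unique(acc$parent_id[infra])
  keep <- infra | !(acc$taxon_id %in% parents_with_infra)
  acc$taxon_id[keep]
}

# CSV I/O -------------------------------------------------------------------

#' Load a key dataset from its four canonical CSV tables
#'
#' The canonical dialect is UTF-8, comma-delimited, header row, RFC 4180
#' quoting. Multiple states within one coding cell are pipe-joined
#' (`"pink|red"`). The dataset is validated on load; any fatal finding
#' (unknown state tokens, dangling ids, duplicate codings, broken
#' synonym/parent links) aborts with a message locating the offending rows.
#'
#' @param taxa_path,codings_path,distributions_path,points_path CSV file
#'   paths. `distributions_path` and `points_path` may be `NULL` for
#'   datasets without geographic data.
#' @param schema an `erica_schema`; defaults to [default_schema()].
#' @return a validated `erica_dataset`.
#' @seealso [write_dataset()], [validate_dataset()]
#' @export
load_dataset <- function(taxa_path, codings_path,
                         distributions_path = NULL, points_path = NULL,
                         schema = default_schema()) {
  read1 <- function(path, what) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) {
      stop(what, " file not found: ", path, call. = FALSE)
    }
    tryCatch(
      read.csv(path, colClasses = "character", check.names = TRUE,
               fileEncoding = "UTF-8"),
      error = function(e) {
        stop("parse error in ", what, " file '", path, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  ds <- key_dataset(
    schema,
    taxa = read1(taxa_path, "taxa"),
    codings = read1(codings_path, "codings"),
    distributions = read1(distributions_path, "distributions") %||%
      empty_distributions(),
    points = read1(points_path, "points") %||% empty_points()
  )
  rep <- validate_dataset(ds)
  fatal <- rep$issues[rep$issues$severity == "fatal", , drop = FALSE]
  if (nrow(fatal)) {
    msgs <- sprintf("%s [%s]: %s", fatal$table, fatal$row, fatal$message)
    stop("dataset failed validation with ", nrow(fatal), " fatal error(s):\n",
         paste(" -", head(msgs, 20), collapse = "\n"),
         if (nrow(fatal) > 20) "\n - ..." else "", call. = FALSE)
  }
  ds
}

#' @param dir directory convenience wrapper: reads/writes `taxa.csv`,
#'   `codings.csv`, `distributions.csv`, `points.csv` (and for writing,
#'   `schema.json`) inside `dir`.
#' @rdname load_dataset
#' @export
load_dataset_dir <- function(dir, schema = NULL) {
  p <- function(f) file.path(dir, f)
  opt <- function(f) if (file.exists(p(f))) p(f) else NULL
  if (is.null(schema)) {
    schema <- if (file.exists(p("schema.json"))) read_schema(p("schema.json"))
              else default_schema()
  }
  load_dataset(p("taxa.csv"), p("codings.csv"),
               opt("distributions.csv"), opt("points.csv"), schema = schema)
}

#' Write a key dataset as canonical CSV tables
#'
#' Writes `taxa.csv`, `codings.csv`, `distributions.csv`, `points.csv` and
#' `schema.json` into `dir`. Writing then re-loading reproduces the dataset
#' field for field: optional fields round-trip `NA` as the empty string and
#' coordinates are written at six decimal places (the precision at which
#' points are stored).
#'
#' @param ds an `erica_dataset`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "erica_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blank <- function(df) {
    for (cl in names(df)) {
      if (is.character(df[[cl]])) df[[cl]][is.na(df[[cl]])] <- ""
    }
    df
  }
  w <- function(df, f) {
    write.csv(blank(df), file.path(dir, f), row.names = FALSE, na = "",
              fileEncoding = "UTF-8", quote = TRUE)
  }
  w(ds$taxa, "taxa.csv")
  w(ds$codings, "codings.csv")
  w(ds$distributions, "distributions.csv")
  pts <- ds$points
  pts$latitude <- sprintf("%.6f", pts$latitude)
  pts$longitude <- sprintf("%.6f", pts$longitude)
  if (!nrow(pts)) pts$latitude <- pts$longitude <- character(0)
  w(pts, "points.csv")
  write_schema(ds$schema, file.path(dir, "schema.json"))
  invisible(dir)
}

# validation ----------------------------------------------------------------

#' Validate a key dataset
#'
#' Checks every structural invariant of the data model and reports, rather
#' than raises: unknown group or state tokens, duplicate `(taxon, group)`
#' codings, ids that resolve to no taxon, codings attached to non-accepted
#' taxa, synonyms without an accepted name, subspecific taxa without a
#' species parent, coordinates out of range, malformed QDS codes.
#'
#' Incompleteness is expected in a key under active development, so an
#' accepted taxon with no codings or no distribution yields a *warning*, not
#' an error; only invariant violations are *fatal*.
#'
#' @param ds an `erica_dataset`.
#' @return an object of class `erica_validation`: a list with `issues` (data
#'   frame of `severity`, `table`, `row`, `message`) and `counts` (issues per
#'   severity). The dataset is sound iff `counts[["fatal"]] == 0`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "erica_dataset"))
  iss <- list()
  add <- function(severity, table, row, message) {
    iss[[length(iss) + 1L]] <<- data.frame(
      severity = severity, table = table, row = as.character(row),
      message = message, stringsAsFactors = FALSE)
  }

  tx <- ds$taxa
  ids <- tx$taxon_id
  dup <- duplicated(ids)
  for (i in which(dup)) {
    add("fatal", "taxa", i, paste0("duplicate taxon_id '", ids[i], "'"))
  }
  for (i in seq_len(nrow(tx))) {
    r <- tx[i, ]
    if (is.na(r$taxon_id)) {
      add("fatal", "taxa", i, "missing taxon_id"); next
    }
    if (is.na(r$name)) add("fatal", "taxa", i, "missing name")
    if (is.na(r$rank) || !r$rank %in% c("species", "subspecies", "variety")) {
      add("fatal", "taxa", i, paste0("invalid rank '", r$rank, "'"))
    }
    if (is.na(r$status) ||
        !r$status %in% c("accepted", "synonym", "unplaced")) {
      add("fatal", "taxa", i, paste0("invalid status '", r$status, "'"))
      next
    }
    if (r$status == "synonym") {
      if (is.na(r$accepted_id)) {
        add("fatal", "taxa", i,
            paste0("synonym '", r$name, "' has no accepted_id"))
      } else if (!r$accepted_id %in% ids) {
        add("fatal", "taxa", i,
            paste0("accepted_id '", r$accepted_id, "' resolves to no taxon"))
      } else if (tx$status[match(r$accepted_id, ids)] != "accepted") {
        add("fatal", "taxa", i,
            paste0("accepted_id '", r$accepted_id,
                   "' points to a non-accepted taxon"))
      }
    }
    if (r$status == "accepted" && !is.na(r$accepted_id)) {
      add("fatal", "taxa", i, "accepted taxon must not carry accepted_id")
    }
    if (r$status == "accepted" && r$rank %in% c("subspecies", "variety")) {
      if (is.na(r$parent_id)) {
        add("fatal", "taxa", i,
            paste0(r$rank, " '", r$name, "' has no parent_id"))
      } else if (!r$parent_id %in% ids) {
        add("fatal", "taxa", i,
            paste0("parent_id '", r$parent_id, "' resolves to no taxon"))
      } else if (tx$rank[match(r$parent_id, ids)] != "species") {
        add("fatal", "taxa", i,
            paste0("parent '", r$parent_id, "' is not of rank species"))
      }
    }
  }

  accepted <- ids[!is.na(tx$status) & tx$status == "accepted"]

  cd <- ds$codings
  seen <- character(0)
  for (i in seq_len(nrow(cd))) {
    r <- cd[i, ]
    if (is.na(r$taxon_id) || !r$taxon_id %in% ids) {
      add("fatal", "codings", i,
          paste0("taxon_id '", r$taxon_id, "' resolves to no taxon"))
      next
    }
    if (!r$taxon_id %in% accepted) {
      add("fatal", "codings", i,
          paste0("coding attached to non-accepted taxon '", r$taxon_id, "'"))
    }
    g <- if (is.na(r$group_id)) NULL else ds$schema[[r$group_id]]
    if (is.null(g)) {
      add("fatal", "codings", i,
          paste0("unknown group_id '", r$group_id, "'"))
      next
    }
    key <- paste(r$taxon_id, r$group_id, sep = "\r")
    if (key %in% seen) {
      add("fatal", "codings", i,
          paste0("duplicate coding for (", r$taxon_id, ", ", r$group_id, ")"))
    }
    seen <- c(seen, key)
    bad <- setdiff(split_states(r$states), g$states)
    if (length(bad)) {
      add("fatal", "codings", i,
          paste0("state(s) not in vocabulary of group '", r$group_id, "': ",
                 paste0("'", bad, "'", collapse = ", ")))
    }
  }

  dist <- ds$distributions
  for (i in seq_len(nrow(dist))) {
    r <- dist[i, ]
    if (is.na(r$taxon_id) || !r$taxon_id %in% ids) {
      add("fatal", "distributions", i,
          paste0("taxon_id '", r$taxon_id, "' resolves to no taxon"))
      next
    }
    if (is.na(r$qds)) {
      add("fatal", "distributions", i, "missing qds code")
    } else if (!is_qds_code(r$qds)) {
      add("warning", "distributions", i,
          paste0("'", r$qds, "' is not a canonical QDS code; ",
                 "carried as an opaque label"))
    }
  }

  pt <- ds$points
  for (i in seq_len(nrow(pt))) {
    r <- pt[i, ]
    if (is.na(r$taxon_id) || !r$taxon_id %in% ids) {
      add("fatal", "points", i,
          paste0("taxon_id '", r$taxon_id, "' resolves to no taxon"))
      next
    }
    if (is.na(r$latitude) || abs(r$latitude) > 90) {
      add("fatal", "points", i, "latitude outside [-90, 90]")
    }
    if (is.na(r$longitude) || abs(r$longitude) > 180) {
      add("fatal", "points", i, "longitude outside [-180, 180]")
    }
  }

  coded <- unique(cd$taxon_id)
  mapped <- unique(dist$taxon_id)
  for (id in accepted) {
    if (!id %in% coded) {
      add("warning", "taxa", match(id, ids),
          paste0("accepted taxon '", id, "' has no character codings"))
    }
    if (!id %in% mapped) {
      add("warning", "taxa", match(id, ids),
          paste0("accepted taxon '", id, "' has no QDS distribution"))
    }
  }

  issues <- if (length(iss)) do.call(rbind, iss) else
    data.frame(severity = character(0), table = character(0),
               row = character(0), message = character(0),
               stringsAsFactors = FALSE)
  counts <- c(fatal = sum(issues$severity == "fatal"),
              warning = sum(issues$severity == "warning"))
  structure(list(issues = issues, counts = counts),
            class = "erica_validation")
}

#' @export
print.erica_validation <- function(x, ...) {
  cat(sprintf("<validation report> %d fatal, %d warning\n",
              x$counts[["fatal"]], x$counts[["warning"]]))
  n <- nrow(x$issues)
  for (i in seq_len(min(n, 25))) {
    r <- x$issues[i, ]
    cat(sprintf("  [%s] %s row %s: %s\n", r$severity, r$table, r$row,
                r$message))
  }
  if (n > 25) cat("  ...", n - 25, "more\n")
  invisible(x)
}

# name lookup ---------------------------------------------------------------

#' Find taxa by name
#'
#' Case-insensitive substring search over all names in the checklist:
#' accepted names, synonyms and "unplaced" names (published names not
#' attributable to a known taxon, kept so that names met in the literature
#' can still be looked up). Synonym hits point at their accepted taxon.
#'
#' @param ds an `erica_dataset`.
#' @param query substring to search for (case-insensitive; fixed string, not
#'   a regular expression).
#' @return data frame with columns `taxon_id`, `name`, `rank`, `match_kind`
#'   (`"accepted"`, `"synonym-of-<accepted name>"` or `"unplaced"`),
#'   `wfo_id`, `accepted_id`; zero rows when nothing matches.
#' @examples
#' we <- worked_example()
#' nrow(find_name(we$dataset, "zzz-no-such-name"))
#' @export
find_name <- function(ds, query) {
  stopifnot(inherits(ds, "erica_dataset"), is.character(query),
            length(query) == 1L)
  tx <- ds$taxa
  hit <- grepl(tolower(query), tolower(tx$name), fixed = TRUE)
  tx <- tx[hit, , drop = FALSE]
  kind <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    kind[i] <- switch(tx$status[i],
      accepted = "accepted",
      synonym = paste0("synonym-of-",
                       ds$taxa$name[match(tx$accepted_id[i],
                                          ds$taxa$taxon_id)]),
      unplaced = "unplaced",
      tx$status[i])
  }
  out <- data.frame(taxon_id = tx$taxon_id, name = tx$name, rank = tx$rank,
                    match_kind = kind, wfo_id = tx$wfo_id,
                    accepted_id = tx$accepted_id, stringsAsFactors = FALSE)
  out[order(name_collation_key(out$name)), , drop = FALSE]
}
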