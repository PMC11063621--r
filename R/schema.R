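#' Character groups and schemas
#'
#' A multi-access key is organised as an ordered set of *character groups*
#' ("probability groups"): each group is one observable attribute — corolla
#' shape, flowering month, region of origin — with a controlled vocabulary of
#' state tokens. Taxa are coded with one or more states per group (OR
#' semantics, reflecting within-species variation), and identification
#' operates over these codings.
#'
#' `character_group()` builds a single validated group; `character_schema()`
#' an ordered collection of groups with unique ids.
#'
#' @param group_id short stable token identifying the group.
#' @param label human-readable name.
#' @param kind one of `"categorical"`, `"count"`, `"binary"`, `"month"`,
#'   `"region"`. A `month` group must have exactly the twelve states
#'   `Jan`..`Dec`.
#' @param states character vector of allowed state tokens, unique
#'   case-insensitively, in display order.
#' @return `character_group()` an object of class `erica_group`;
#'   `character_schema()` an object of class `erica_schema` (a list of
#'   groups, indexable by `group_id`).
#' @seealso [default_schema()], [read_schema()], [write_schema()]
#' @examples
#' g <- character_group("resprouting", "Resprouting after fire", "binary",
#'                      c("yes", "no"))
#' s <- character_schema(list(g))
#' s$resprouting$states
#' @export
character_group <- function(group_id, label, kind, states) {
  kinds <- c("categorical", "count", "binary", "month", "region")
  stopifnot(is.character(group_id), length(group_id) == 1L, nzchar(group_id))
  if (!kind %in% kinds) {
    stop("unknown group kind '", kind, "' (expected one of ",
         paste(kinds, collapse = ", "), ")", call. = FALSE)
  }
  states <- as.character(states)
  if (length(states) == 0L) {
    stop("group '", group_id, "': states must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(tolower(states))) {
    stop("group '", group_id, "': duplicate state tokens (case-insensitive)",
         call. = FALSE)
  }
  if (kind == "month" && !identical(states, month.abb)) {
    stop("group '", group_id, "': a month group must have exactly the states ",
         "Jan..Dec", call. = FALSE)
  }
  structure(
    list(group_id = group_id, label = label, kind = kind, states = states),
    class = "erica_group"
  )
}

#' @param groups list of `erica_group` objects, in display order.
#' @rdname character_group
#' @export
character_schema <- function(groups) {
  if (!length(groups) || !all(vapply(groups, inherits, TRUE, "erica_group"))) {
    stop("'groups' must be a nonempty list of character_group objects",
         call. = FALSE)
  }
  ids <- vapply(groups, `[[`, "", "group_id")
  if (anyDuplicated(ids)) {
    stop("duplicate group_id: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  }
  names(groups) <- ids
  structure(groups, class = "erica_schema")
}

#' @export
print.erica_schema <- function(x, ...) {
  cat("<character schema>", length(x), "groups\n")
  for (g in x) {
    cat(sprintf("  %-22s %-12s %d states\n", g$group_id, g$kind,
                length(g$states)))
  }
  invisible(x)
}

#' @export
print.erica_group <- function(x, ...) {
  cat(sprintf("<character group> %s (%s, %s)\n  states: %s\n",
              x$group_id, x$label, x$kind, paste(x$states, collapse = ", ")))
  invisible(x)
}

group_ids <- function(schema) vapply(schema, `[[`, "", "group_id")

# resolve a group by id; error names the offending token
schema_group <- function(schema, group_id) {
  g <- schema[[group_id]]
  if (is.null(g)) stop("unknown character group '", group_id, "'", call. = FALSE)
  g
}

# check state tokens against a group's vocabulary; error names the tokens
check_states <- function(group, states) {
  bad <- setdiff(states, group$states)
  if (length(bad)) {
    stop("unknown state(s) for group '", group$group_id, "': ",
         paste0("'", bad, "'", collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' The default 21-group identification schema
#'
#' The canonical schema of the heath identification aid: corolla size, shape
#' and colour; hairiness of stem, leaf, pedicel, sepal, corolla and ovary;
#' exsertion of style and anthers; anther appendages; numbers of stamens,
#' sepals, corolla lobes, leaves per whorl and bracts; sepal:corolla length
#' ratio; resprouting after fire; flowering month; and geographic region —
#' 21 groups in all. Phenology and geography carry much of the discriminating
#' power because regional endemism is high and flowering is spread across the
#' year.
#'
#' The state vocabularies are configuration, not ground truth: they are
#' shipped as a JSON schema file (`system.file("extdata",
#' "default_schema.json", package = "ericakey")`) and may be replaced with
#' [read_schema()].
#'
#' @return an `erica_schema` with exactly 21 groups.
#' @examples
#' s <- default_schema()
#' length(s)
#' s$corolla_shape$states
#' @export
default_schema <- function() {
  path <- system.file("extdata", "default_schema.json", package = "ericakey")
  read_schema(path)
}

#' Read or write a schema configuration file
#'
#' A schema is stored as a JSON array of objects with fields `group_id`,
#' `label`, `kind` and `states`; order in the file is display order.
#'
#' @param path file path of the JSON schema configuration.
#' @return `read_schema()` an `erica_schema`; `write_schema()` the path,
#'   invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  groups <- lapply(raw, function(r) {
    character_group(r$group_id, r$label, r$kind, unlist(r$states))
  })
  character_schema(groups)
}

#' @param schema an `erica_schema`.
#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "erica_schema"))
  raw <- lapply(unname(schema), function(g) {
    list(group_id = g$group_id, label = g$label, kind = g$kind,
         states = as.list(g$states))
  })
  jsonlite::write_json(raw, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
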