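#' Quarter-degree-square (QDS) geocoding
#'
#' Southern-African herbarium records are traditionally gridded at
#' quarter-degree-square resolution: 15 minutes of arc per side,
#' approximately 25 km. A code such as `"3318CD"` names a one-degree cell by
#' its degrees *south* (33) and *east* (18), then subdivides it twice with
#' the letters A-D laid out row-major from the cell's north-west corner
#' (A = NW, B = NE, C = SW, D = SE): the first letter picks the 30-minute
#' quadrant, the second the 15-minute quarter within it. `"3318CD"` is
#' therefore the square spanning 33.75-34.00 degrees S and 18.25-18.50
#' degrees E — Cape Town and the northern Cape Peninsula.
#'
#' The geocoder's domain is the southern/eastern hemisphere (negative
#' latitude, positive longitude), which covers the genus's African and
#' Malagasy range; codes found in data that do not parse are carried through
#' as opaque labels by the rest of the package.
#'
#' @name qds
NULL

QDS_LETTERS <- c("A", "B", "C", "D")

# TRUE where the string is a canonical QDS code (after trimming/upcasing)
is_qds_code <- function(x) {
  x <- toupper(trimws(x))
  ok <- grepl("^[0-9]{4}[A-D]{2}$", x)
  lat <- suppressWarnings(as.integer(substr(x, 1, 2)))
  ok & !is.na(lat) & lat <= 89
}

#' Parse a QDS code
#'
#' @param text a QDS code such as `"3318CD"`; surrounding whitespace and
#'   lower case are tolerated.
#' @return an object of class `qds_code`: list with integer `lat_deg` and
#'   `lon_deg` (degrees south / east of the cell's NW origin), `quadrant`
#'   and `quarter` (letters A-D) and the canonical `code`.
#' @examples
#' parse_qds(" 3318cd ")
#' @export
parse_qds <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- toupper(trimws(text))
  if (!grepl("^[0-9]{4}[A-D]{2}$", x)) {
    stop("malformed QDS code '", text,
         "' (expected 4 digits then two letters A-D, e.g. \"3318CD\")",
         call. = FALSE)
  }
  lat_deg <- as.integer(substr(x, 1, 2))
  lon_deg <- as.integer(substr(x, 3, 4))
  if (lat_deg > 89) {
    stop("QDS code '", text, "': degrees south must be at most 89",
         call. = FALSE)
  }
  structure(
    list(lat_deg = lat_deg, lon_deg = lon_deg,
         quadrant = substr(x, 5, 5), quarter = substr(x, 6, 6), code = x),
    class = "qds_code"
  )
}

#' @param qds a `qds_code` (or a code string, which is parsed first).
#' @rdname parse_qds
#' @export
format_qds <- function(qds) {
  qds <- as_qds(qds)
  sprintf("%02d%02d%s%s", qds$lat_deg, qds$lon_deg, qds$quadrant, qds$quarter)
}

as_qds <- function(x) {
  if (inherits(x, "qds_code")) x else parse_qds(x)
}

#' @export
print.qds_code <- function(x, ...) {
  cat(sprintf("<QDS> %s (%d S, %d E, quadrant %s, quarter %s)\n",
              x$code, x$lat_deg, x$lon_deg, x$quadrant, x$quarter))
  invisible(x)
}

# letter -> 0-based (row, col) within a 2x2 subdivision, rows running N -> S
letter_rowcol <- function(letter) {
  i <- match(letter, QDS_LETTERS) - 1L
  c(row = i %/% 2L, col = i %% 2L)
}

#' Bounding box of a QDS
#'
#' @inheritParams format_qds
#' @return list with `south`, `north` (degrees latitude, negative = S) and
#'   `west`, `east` (degrees longitude); the box is exactly 0.25 degrees per
#'   side.
#' @examples
#' qds_bbox("3318CD")  # 33.75-34.00 S, 18.25-18.50 E
#' @export
qds_bbox <- function(qds) {
  qds <- as_qds(qds)
  q1 <- letter_rowcol(qds$quadrant)
  q2 <- letter_rowcol(qds$quarter)
  southing_top <- qds$lat_deg + q1[["row"]] * 0.5 + q2[["row"]] * 0.25
  west <- qds$lon_deg + q1[["col"]] * 0.5 + q2[["col"]] * 0.25
  list(south = -(southing_top + 0.25), north = -southing_top,
       west = west, east = west + 0.25)
}

#' Assign a point to its QDS
#'
#' The inverse of [qds_bbox()]: maps a coordinate in the southern/eastern
#' hemisphere to the unique quarter-degree square containing it. Containment
#' is half-open so that the sixteen quarters of a degree cell tile it
#' exactly: a square contains the points with
#' `southing in [33.75, 34)` and `easting in [18.25, 18.5)` for `"3318CD"`,
#' i.e. the edge nearer the cell origin (geographic north and west) belongs
#' to the square.
#'
#' @param latitude degrees latitude, must be negative (southern hemisphere).
#' @param longitude degrees longitude, must be positive (eastern
#'   hemisphere).
#' @return a `qds_code`.
#' @examples
#' format_qds(point_to_qds(-33.80, 18.30))
#' @export
point_to_qds <- function(latitude, longitude) {
  stopifnot(is.numeric(latitude), is.numeric(longitude),
            length(latitude) == 1L, length(longitude) == 1L)
  if (is.na(latitude) || is.na(longitude) ||
      latitude >= 0 || longitude <= 0 ||
      latitude < -90 || longitude > 180) {
    stop("point (", latitude, ", ", longitude,
         ") is outside the QDS domain (southern latitude, ",
         "eastern longitude)", call. = FALSE)
  }
  s <- -latitude
  e <- longitude
  lat_deg <- floor(s)
  lon_deg <- floor(e)
  if (lat_deg > 89) stop("latitude too far south for a QDS", call. = FALSE)
  i4 <- min(floor((s - lat_deg) * 4), 3)  # 0..3, N -> S quarter-row index
  j4 <- min(floor((e - lon_deg) * 4), 3)
  quadrant <- QDS_LETTERS[(i4 %/% 2L) * 2L + (j4 %/% 2L) + 1L]
  quarter <- QDS_LETTERS[(i4 %% 2L) * 2L + (j4 %% 2L) + 1L]
  parse_qds(sprintf("%02d%02d%s%s", lat_deg, lon_deg, quadrant, quarter))
}

#' Taxa recorded in a QDS
#'
#' All taxa whose distribution contains the square, name-sorted. A
#' subspecies and its inclusive species are separate records and both
#' listed when both are coded for the square.
#'
#' @param ds an `erica_dataset`.
#' @param qds a QDS code (string or `qds_code`).
#' @return data frame of taxon records (possibly zero rows).
#' @export
taxa_per_qds <- function(ds, qds) {
  stopifnot(inherits(ds, "erica_dataset"))
  code <- if (inherits(qds, "qds_code")) qds$code
          else if (is_qds_code(qds)) format_qds(qds)
          else toupper(trimws(qds))
  have <- ds$distributions$qds
  have_canon <- ifelse(is_qds_code(have), toupper(trimws(have)), have)
  ids <- unique(ds$distributions$taxon_id[have_canon == code])
  out <- ds$taxa[ds$taxa$taxon_id %in% ids, , drop = FALSE]
  out <- out[order(name_collation_key(out$name)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Grid-versus-point coverage report
#'
#' Contrasts a taxon's gridded QDS distribution with its occurrence points:
#' squares in the distribution containing none of the taxon's points, and
#' points falling in no coded square. Either side can reveal errors or gaps
#' worth investigating — legacy grid records without modern observations,
#' or observations outside the historically recorded range.
#'
#' @param ds an `erica_dataset`.
#' @param taxon_id an accepted taxon id.
#' @return object of class `erica_coverage`: list with `taxon_id`,
#'   `qds_without_points` (character vector of codes) and
#'   `points_outside_coded_qds` (data frame of points).
#' @export
coverage_report <- function(ds, taxon_id) {
  stopifnot(inherits(ds, "erica_dataset"))
  if (!taxon_id %in% ds$taxa$taxon_id) {
    stop("unknown taxon id '", taxon_id, "'", call. = FALSE)
  }
  codes_raw <- unique(ds$distributions$qds[ds$distributions$taxon_id ==
                                           taxon_id])
  opaque <- codes_raw[!is_qds_code(codes_raw)]
  if (length(opaque)) {
    warning("ignoring non-canonical QDS label(s) for '", taxon_id, "': ",
            paste0("'", opaque, "'", collapse = ", "), call. = FALSE)
  }
  codes <- toupper(trimws(codes_raw[is_qds_code(codes_raw)]))
  pts <- ds$points[ds$points$taxon_id == taxon_id, , drop = FALSE]
  pt_codes <- rep(NA_character_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    pt_codes[i] <- tryCatch(
      point_to_qds(pts$latitude[i], pts$longitude[i])$code,
      error = function(e) NA_character_)  # out-of-domain: in no coded square
  }
  structure(
    list(taxon_id = taxon_id,
         qds_without_points = sort(setdiff(codes, pt_codes)),
         points_outside_coded_qds =
           pts[is.na(pt_codes) | !(pt_codes %in% codes), , drop = FALSE]),
    class = "erica_coverage"
  )
}

#' @export
print.erica_coverage <- function(x, ...) {
  cat(sprintf("<coverage report> %s\n", x$taxon_id))
  cat(sprintf("  QDS without any point: %d%s\n",
              length(x$qds_without_points),
              if (length(x$qds_without_points))
                paste0(" (", paste(x$qds_without_points, collapse = ", "), ")")
              else ""))
  cat(sprintf("  points outside coded QDS: %d\n",
              nrow(x$points_outside_coded_qds)))
  invisible(x)
}
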