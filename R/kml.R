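#' Options for KML export
#'
#' @param point_limit maximum number of occurrence placemarks written per
#'   export, default 5000 — enough to show all curated data for most taxa
#'   while keeping documents loadable on modest hardware. When there are
#'   more points, the first `point_limit` in table order are kept
#'   (deterministic, not a random subsample).
#' @param include_grid write the QDS grid polygons.
#' @param include_points write the occurrence-point placemarks.
#' @return list of class `kml_options`.
#' @export
kml_options <- function(point_limit = 5000, include_grid = TRUE,
                        include_points = TRUE) {
  point_limit <- as.integer(point_limit)
  if (is.na(point_limit) || point_limit < 1L) {
    stop("point_limit must be a positive integer", call. = FALSE)
  }
  structure(list(point_limit = point_limit,
                 include_grid = isTRUE(include_grid),
                 include_points = isTRUE(include_points)),
            class = "kml_options")
}

# fixed palette in KML aabbggrr order: red first (the inclusive species),
# then the subspecies colours of the aid's Google Earth view
KML_PALETTE <- c(
  red        = "ff0000ff",
  orange     = "ff00a5ff",
  green      = "ff00ff00",
  dark_blue  = "ff8b0000",
  purple     = "ff800080",
  light_blue = "ffe6d8ad",
  yellow     = "ff00ffff",
  magenta    = "ffff00ff",
  teal       = "ff808000",
  brown      = "ff13458b"
)

# deterministic colour assignment: species rank first (so the inclusive
# species is red), then infraspecific taxa, each block in name order
assign_colours <- function(ds, taxon_ids) {
  nm <- ds$taxa$name[match(taxon_ids, ds$taxa$taxon_id)]
  rk <- ds$taxa$rank[match(taxon_ids, ds$taxa$taxon_id)]
  ord <- order(rk != "species", name_collation_key(nm))
  ids <- taxon_ids[ord]
  setNames(KML_PALETTE[((seq_along(ids) - 1L) %% length(KML_PALETTE)) + 1L],
           ids)
}

#' Export distributions to KML
#'
#' Writes a Google-Earth-ready KML 2.2 document: one polygon per
#' (taxon, QDS) pair in a "QDS" folder, and one point placemark per
#' occurrence record in a folder per taxon, each point carrying its source
#' label and link in the description. Every taxon gets a distinct colour;
#' when an inclusive species is exported with its subspecies the species is
#' red and each subspecies a different colour. At most
#' `options$point_limit` points are written per export call (across the
#' whole document; default 5000).
#'
#' Distribution codes that are not canonical QDS codes cannot be drawn and
#' are skipped with a warning.
#'
#' @param ds an `erica_dataset`.
#' @param taxon_ids one or more taxon ids to map.
#' @param options a [kml_options()] list.
#' @param file optional path; when given the document is also written there.
#' @return an `xml2::xml_document` (invisibly when `file` is given).
#' @examples
#' we <- worked_example()
#' doc <- export_kml(we$dataset, we$dataset$taxa$taxon_id[1])
#' length(kml_check(doc)) == 0
#' @export
export_kml <- function(ds, taxon_ids, options = kml_options(), file = NULL) {
  stopifnot(inherits(ds, "erica_dataset"))
  if (!inherits(options, "kml_options")) {
    stop("'options' must be built with kml_options()", call. = FALSE)
  }
  taxon_ids <- as.character(taxon_ids)
  if (!length(taxon_ids)) stop("no taxa to map", call. = FALSE)
  idx <- match(taxon_ids, ds$taxa$taxon_id)
  if (anyNA(idx)) {
    stop("unknown taxon id(s): ",
         paste0("'", taxon_ids[is.na(idx)], "'", collapse = ", "),
         call. = FALSE)
  }

  doc <- xml2::xml_new_root("kml", xmlns = "http://www.opengis.net/kml/2.2")
  root <- xml2::xml_add_child(doc, "Document")
  xml2::xml_add_child(root, "name", "Distribution map")

  colours <- assign_colours(ds, taxon_ids)
  for (tid in taxon_ids) {
    st <- xml2::xml_add_child(root, "Style", id = paste0("style-", tid))
    ic <- xml2::xml_add_child(st, "IconStyle")
    xml2::xml_add_child(ic, "color", colours[[tid]])
    xml2::xml_add_child(ic, "scale", "0.8")
    ln <- xml2::xml_add_child(st, "LineStyle")
    xml2::xml_add_child(ln, "color", colours[[tid]])
    xml2::xml_add_child(ln, "width", "1.5")
    po <- xml2::xml_add_child(st, "PolyStyle")
    xml2::xml_add_child(po, "color", paste0("66", substr(colours[[tid]], 3, 8)))
  }

  dist <- ds$distributions[ds$distributions$taxon_id %in% taxon_ids, ,
                           drop = FALSE]
  pts <- ds$points[ds$points$taxon_id %in% taxon_ids, , drop = FALSE]
  n_grid <- 0L
  if (options$include_grid && nrow(dist)) {
    bad <- !is_qds_code(dist$qds)
    if (any(bad)) {
      warning("skipping non-canonical QDS label(s): ",
              paste0("'", unique(dist$qds[bad]), "'", collapse = ", "),
              call. = FALSE)
      dist <- dist[!bad, , drop = FALSE]
    }
    if (nrow(dist)) {
      grid_folder <- xml2::xml_add_child(root, "Folder")
      xml2::xml_add_child(grid_folder, "name", "QDS")
      for (i in seq_len(nrow(dist))) {
        tid <- dist$taxon_id[i]
        code <- format_qds(dist$qds[i])
        bb <- qds_bbox(code)
        pm <- xml2::xml_add_child(grid_folder, "Placemark")
        xml2::xml_add_child(pm, "name", paste0(taxon_name(ds, tid), " ", code))
        xml2::xml_add_child(pm, "styleUrl", paste0("#style-", tid))
        poly <- xml2::xml_add_child(pm, "Polygon")
        outer <- xml2::xml_add_child(poly, "outerBoundaryIs")
        ring <- xml2::xml_add_child(outer, "LinearRing")
        coords <- sprintf("%s,%s,0", # closed ring, first vertex repeated
          c(bb$west, bb$east, bb$east, bb$west, bb$west),
          c(bb$south, bb$south, bb$north, bb$north, bb$south))
        xml2::xml_add_child(ring, "coordinates", paste(coords, collapse = " "))
        n_grid <- n_grid + 1L
      }
    }
  }

  n_pts <- 0L
  if (options$include_points && nrow(pts)) {
    budget <- options$point_limit
    for (tid in taxon_ids) {
      tp <- pts[pts$taxon_id == tid, , drop = FALSE]
      if (!nrow(tp) || budget <= 0L) next
      tp <- head(tp, budget)
      budget <- budget - nrow(tp)
      folder <- xml2::xml_add_child(root, "Folder")
      xml2::xml_add_child(folder, "name", taxon_name(ds, tid))
      for (i in seq_len(nrow(tp))) {
        pm <- xml2::xml_add_child(folder, "Placemark")
        xml2::xml_add_child(pm, "name", taxon_name(ds, tid))
        desc <- tp$source_label[i]
        if (is.na(desc)) desc <- ""
        if (!is.na(tp$source_url[i])) {
          desc <- paste0(desc, if (nzchar(desc)) " — " else "",
                         tp$source_url[i])
        }
        xml2::xml_add_child(pm, "description", desc)
        xml2::xml_add_child(pm, "styleUrl", paste0("#style-", tid))
        pt <- xml2::xml_add_child(pm, "Point")
        xml2::xml_add_child(pt, "coordinates",
                            sprintf("%.6f,%.6f,0", tp$longitude[i],
                                    tp$latitude[i]))
        n_pts <- n_pts + 1L
      }
    }
  }

  if (n_grid + n_pts == 0L) {
    warning("no mappable data for the requested taxa; ",
            "writing an empty document", call. = FALSE)
  }
  # re-parse so every element is bound to the default KML namespace and the
  # returned document behaves exactly like one read from disk
  doc <- xml2::read_xml(as.character(doc))
  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}

taxon_name <- function(ds, taxon_id) {
  ds$taxa$name[match(taxon_id, ds$taxa$taxon_id)]
}

#' Structurally validate a KML document
#'
#' Checks the document against the structural rules of KML 2.2 that matter
#' for this package's output: the `kml` root in the KML 2.2 namespace with a
#' single `Document`; every `Placemark` carrying exactly one geometry;
#' every `LinearRing` closed (first vertex equal to the last) with at least
#' four vertices; all coordinates numeric `lon,lat[,alt]` tuples with
#' longitude in \[-180, 180\] and latitude in \[-90, 90\]; every `styleUrl`
#' resolving to a `Style` id in the document.
#'
#' @param doc an `xml2::xml_document`, or a path to a `.kml` file.
#' @return character vector of problems; `character(0)` when the document
#'   passes.
#' @export
kml_check <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  problems <- character(0)
  say <- function(...) problems <<- c(problems, paste0(...))

  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "kml") say("root element is not <kml>")
  ns <- xml2::xml_ns(doc)
  if (!"http://www.opengis.net/kml/2.2" %in% unlist(ns)) {
    say("KML 2.2 namespace missing")
  }
  docs <- xml2::xml_find_all(doc, "/d1:kml/d1:Document", ns)
  if (length(docs) != 1L) say("expected exactly one <Document>")

  style_ids <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//d1:Style", ns), "id")
  urls <- xml2::xml_text(xml2::xml_find_all(doc, ".//d1:styleUrl", ns))
  for (u in unique(urls)) {
    if (!startsWith(u, "#") || !substring(u, 2) %in% style_ids) {
      say("unresolved styleUrl '", u, "'")
    }
  }

  parse_coords <- function(text) {
    toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    parts <- strsplit(toks, ",", fixed = TRUE)
    if (!all(lengths(parts) %in% 2:3)) return(NULL)
    m <- suppressWarnings(
      matrix(as.numeric(unlist(lapply(parts, `[`, 1:2))), ncol = 2,
             byrow = TRUE))
    if (anyNA(m)) return(NULL)
    m
  }

  pms <- xml2::xml_find_all(doc, ".//d1:Placemark", ns)
  for (pm in pms) {
    geoms <- xml2::xml_find_all(
      pm, "./d1:Point | ./d1:Polygon | ./d1:LineString", ns)
    if (length(geoms) != 1L) {
      say("a Placemark has ", length(geoms), " geometries (expected 1)")
    }
  }

  for (node in xml2::xml_find_all(doc, ".//d1:coordinates", ns)) {
    m <- parse_coords(xml2::xml_text(node))
    if (is.null(m)) { say("unparseable <coordinates>"); next }
    if (any(abs(m[, 1]) > 180) || any(abs(m[, 2]) > 90)) {
      say("coordinates out of range")
    }
  }

  for (ring in xml2::xml_find_all(doc, ".//d1:LinearRing", ns)) {
    m <- parse_coords(
      xml2::xml_text(xml2::xml_find_first(ring, "./d1:coordinates", ns)))
    if (is.null(m) || nrow(m) < 4) { say("LinearRing with < 4 vertices"); next }
    if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) {
      say("LinearRing not closed")
    }
  }

  problems
}
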