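# a species with five subspecies, each mapped and with one point,
# mirroring the aid's flagship Google Earth view
plukenetii_style_fixture <- function() {
  schema <- default_schema()
  subs <- c("bredensis", "breviflora", "lineata", "penicillata",
            "plukenetii")
  taxa <- data.frame(
    taxon_id = c("sp", paste0("ssp", 1:5)),
    name = c("Erica plukenetii",
             paste("Erica plukenetii subsp.", subs)),
    rank = c("species", rep("subspecies", 5)),
    parent_id = c(NA, rep("sp", 5)),
    status = "accepted", accepted_id = NA, wfo_id = NA, iucn = NA,
    sort_schumann = NA, sort_idno = NA, stringsAsFactors = FALSE)
  dist <- data.frame(
    taxon_id = taxa$taxon_id,
    qds = c("3318CD", "3419BB", "3318DC", "3319AC", "3418AB", "3318CB"),
    stringsAsFactors = FALSE)
  points <- data.frame(
    taxon_id = taxa$taxon_id,
    latitude = c(-33.80, -34.30, -33.95, -33.10, -33.80, -33.30),
    longitude = c(18.30, 19.60, 18.60, 19.20, 18.10, 18.40),
    source_label = "curated GBIF record",
    source_url = c("https://example.org/obs/1", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  key_dataset(schema, taxa, distributions = dist, points = points)
}

kml_ns <- function(doc) xml2::xml_ns(doc)

count_nodes <- function(doc, xpath) {
  length(xml2::xml_find_all(doc, xpath, kml_ns(doc)))
}

test_that("an exported document is structurally valid KML with one polygon
          per taxon-square and one placemark per point", {
  ds <- plukenetii_style_fixture()
  doc <- export_kml(ds, ds$taxa$taxon_id)
  expect_length(kml_check(doc), 0L)
  expect_identical(count_nodes(doc, ".//d1:Placemark/d1:Polygon"), 6L)
  expect_identical(count_nodes(doc, ".//d1:Placemark/d1:Point"), 6L)
  # grid polygons live in a "QDS" folder
  folders <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//d1:Folder/d1:name", kml_ns(doc)))
  expect_true("QDS" %in% folders)
  # the point descriptions carry the source metadata
  descs <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//d1:description", kml_ns(doc)))
  expect_true(any(grepl("https://example.org/obs/1", descs)))
})

test_that("the species and each subspecies get distinct colours, species
          red", {
  ds <- plukenetii_style_fixture()
  doc <- export_kml(ds, ds$taxa$taxon_id)
  styles <- xml2::xml_find_all(doc, ".//d1:Style", kml_ns(doc))
  cols <- vapply(styles, function(s) {
    xml2::xml_text(xml2::xml_find_first(s, "./d1:IconStyle/d1:color",
                                        kml_ns(doc)))
  }, "")
  names(cols) <- sub("^style-", "", xml2::xml_attr(styles, "id"))
  expect_length(unique(cols), 6L)
  expect_identical(unname(cols["sp"]), "ff0000ff")  # aabbggrr red
})

test_that("the point budget caps placemarks at the configured limit", {
  schema <- default_schema()
  taxa <- data.frame(taxon_id = "big", name = "Erica multipunctata",
                     rank = "species", parent_id = NA, status = "accepted",
                     accepted_id = NA, wfo_id = NA, iucn = NA,
                     sort_schumann = NA, sort_idno = NA,
                     stringsAsFactors = FALSE)
  n <- 6000
  pts <- data.frame(
    taxon_id = "big",
    latitude = -34 + ((seq_len(n) - 1) %% 100) * 0.009,
    longitude = 18 + ((seq_len(n) - 1) %/% 100) * 0.015,
    source_label = sprintf("record %d", seq_len(n)),
    source_url = NA, stringsAsFactors = FALSE)
  ds <- key_dataset(schema, taxa, points = pts)

  doc <- export_kml(ds, "big")  # default options: limit 5000
  expect_identical(count_nodes(doc, ".//d1:Placemark/d1:Point"), 5000L)
  expect_length(kml_check(doc), 0L)
  # the subsample is the head of the table, deterministically
  descs <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//d1:description", kml_ns(doc)))
  expect_identical(descs[1], "record 1")
  expect_identical(descs[5000], "record 5000")

  small <- export_kml(ds, "big", kml_options(point_limit = 7))
  expect_identical(count_nodes(small, ".//d1:Placemark/d1:Point"), 7L)
  expect_error(kml_options(point_limit = 0), "positive")
})

test_that("grid and point layers can be toggled off independently", {
  ds <- plukenetii_style_fixture()
  no_pts <- export_kml(ds, ds$taxa$taxon_id,
                       kml_options(include_points = FALSE))
  expect_identical(count_nodes(no_pts, ".//d1:Placemark/d1:Point"), 0L)
  expect_gt(count_nodes(no_pts, ".//d1:Placemark/d1:Polygon"), 0L)
  expect_length(kml_check(no_pts), 0L)
  no_grid <- export_kml(ds, ds$taxa$taxon_id,
                        kml_options(include_grid = FALSE))
  expect_identical(count_nodes(no_grid, ".//d1:Placemark/d1:Polygon"), 0L)
  expect_length(kml_check(no_grid), 0L)
})

test_that("a taxon with no mappable data yields a valid empty document
          with a warning", {
  ds <- plukenetii_style_fixture()
  ds$distributions <- ds$distributions[0, , drop = FALSE]
  ds$points <- ds$points[0, , drop = FALSE]
  expect_warning(doc <- export_kml(ds, "sp"), "no mappable data")
  expect_length(kml_check(doc), 0L)
  expect_identical(count_nodes(doc, ".//d1:Placemark"), 0L)
  expect_error(export_kml(ds, "ghost"), "ghost")
})

test_that("export writes a well-formed file to disk", {
  ds <- plukenetii_style_fixture()
  path <- withr::local_tempfile(fileext = ".kml")
  export_kml(ds, c("sp", "ssp1"), file = path)
  expect_true(file.exists(path))
  expect_length(kml_check(path), 0L)
})
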