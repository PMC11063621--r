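# Independent brute-force oracles: plain loops over the coding table,
# sharing no code with the package's engines beyond the data container.

oracle_population <- function(ds) {
  tx <- ds$taxa
  acc <- tx[tx$status == "accepted", , drop = FALSE]
  infra <- acc$rank %in% c("subspecies", "variety")
  has_infra <- acc$taxon_id %in% unique(acc$parent_id[infra])
  acc$taxon_id[infra | !has_infra]
}

oracle_states_of <- function(ds, taxon, group) {
  hit <- which(ds$codings$taxon_id == taxon & ds$codings$group_id == group)
  if (!length(hit)) return(character(0))
  s <- ds$codings$states[hit[1]]
  if (!nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
}

oracle_carriers <- function(ds, group, states) {
  pop <- oracle_population(ds)
  hits <- character(0)
  for (t in pop) {
    if (length(intersect(oracle_states_of(ds, t, group), states))) {
      hits <- c(hits, t)
    }
  }
  sort(hits)
}

# full O(taxa x groups) recomputation of the probability ranking
oracle_rank <- function(ds, selection, include_zero = FALSE) {
  pop <- oracle_population(ds)
  values <- numeric(length(selection))
  carrier_sets <- list()
  for (k in seq_along(selection)) {
    cs <- oracle_carriers(ds, names(selection)[k], selection[[k]])
    carrier_sets[[k]] <- cs
    values[k] <- if (length(cs)) 1 / length(cs) else 0
  }
  score <- setNames(numeric(length(pop)), pop)
  for (t in pop) {
    for (k in seq_along(selection)) {
      if (t %in% carrier_sets[[k]]) score[t] <- score[t] + values[k]
    }
  }
  nm <- ds$taxa$name[match(pop, ds$taxa$taxon_id)]
  key <- tolower(iconv(nm, to = "ASCII//TRANSLIT"))
  df <- data.frame(taxon_id = pop, name = nm, score = unname(score),
                   stringsAsFactors = FALSE)
  if (!include_zero) df <- df[df$score > 0, , drop = FALSE]
  df[order(-df$score, key[match(df$taxon_id, pop)], df$taxon_id), ,
     drop = FALSE]
}

oracle_strict <- function(ds, selection) {
  pop <- oracle_population(ds)
  keep <- character(0)
  for (t in pop) {
    ok <- TRUE
    for (k in seq_along(selection)) {
      if (!length(intersect(oracle_states_of(ds, t, names(selection)[k]),
                            selection[[k]]))) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, t)
  }
  sort(keep)
}

point_in_box <- function(lat, lon, bb) {
  # half-open in (southing, easting): the edge nearer the cell origin
  # (geographic north/west) belongs to the box
  s <- -lat
  (-bb$north) <= s & s < (-bb$south) & bb$west <= lon & lon < bb$east
}

# a tiny handmade checklist exercising every status/rank combination
tiny_dataset <- function() {
  schema <- default_schema()
  taxa <- data.frame(
    taxon_id = c("sp1", "sp1a", "sp1b", "sp2", "sp3", "syn1", "unp1"),
    name = c("Erica abietina", "Erica abietina subsp. atrorosea",
             "Erica abietina subsp. constantiana", "Erica banksii",
             "Erica caffra", "Erica vestigialis", "Erica dubia"),
    rank = c("species", "subspecies", "subspecies", "species", "species",
             "species", "species"),
    parent_id = c(NA, "sp1", "sp1", NA, NA, NA, NA),
    status = c("accepted", "accepted", "accepted", "accepted", "accepted",
               "synonym", "unplaced"),
    accepted_id = c(NA, NA, NA, NA, NA, "sp2", NA),
    wfo_id = c("wfo-0001", NA, NA, "wfo-0002", "wfo-0003", NA, "wfo-0007"),
    iucn = c("LC", "EN", NA, "LC", "LC", NA, NA),
    sort_schumann = c("001", "001", "001", "002", "003", NA, NA),
    sort_idno = c("0001", "0002", "0003", "0004", "0005", NA, NA),
    stringsAsFactors = FALSE)
  codings <- data.frame(
    taxon_id = c("sp1a", "sp1a", "sp1b", "sp1b", "sp2", "sp2", "sp3",
                 "sp1a", "sp1b", "sp2"),
    group_id = c("corolla_shape", "region", "corolla_shape", "region",
                 "corolla_shape", "region", "corolla_shape",
                 "corolla_colour", "corolla_colour", "flowering_month"),
    states = c("tube", "Cape Peninsula", "tube", "SW Cape|Cape Peninsula",
               "cup|urn", "KZ-Natal", "tube", "red", "pink|red", "Jan"),
    stringsAsFactors = FALSE)
  distributions <- data.frame(
    taxon_id = c("sp1", "sp1a", "sp1a", "sp1b", "sp2"),
    qds = c("3318CD", "3318CD", "3418AB", "3318CD", "2930CB"),
    stringsAsFactors = FALSE)
  points <- data.frame(
    taxon_id = c("sp1a", "sp1a", "sp2"),
    latitude = c(-33.80, -33.95, -29.60),
    longitude = c(18.30, 18.40, 30.40),
    source_label = c("iNaturalist obs", "herbarium sheet", "GBIF record"),
    source_url = c("https://example.org/1", NA, "https://example.org/3"),
    stringsAsFactors = FALSE)
  key_dataset(schema, taxa, codings, distributions, points)
}

fatal_messages <- function(report) {
  iss <- report$issues
  iss$message[iss$severity == "fatal"]
}

# random selection over a dataset's coded groups, seeded by the caller
random_selection <- function(ds, n_groups = 2) {
  gids <- unique(ds$codings$group_id)
  gids <- sample(gids, min(n_groups, length(gids)))
  sel <- list()
  for (g in gids) {
    st <- ds$schema[[g]]$states
    sel[[g]] <- sample(st, sample(1:min(2, length(st)), 1))
  }
  sel
}
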