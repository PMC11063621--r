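#' Specification for a synthetic key dataset
#'
#' The generator emulates the statistical shape of a real identification
#' matrix: polymorphic codings (within-species variation coded with OR
#' semantics), incomplete coding, a checklist with subspecies and synonyms,
#' gridded QDS distributions drawn from a pool of squares, and occurrence
#' points inside coded squares. It does not emulate trait correlations or
#' realistic range shapes.
#'
#' @param n_taxa number of accepted taxa to generate.
#' @param schema an `erica_schema`; default [default_schema()].
#' @param prevalence target carrier fractions for chosen states: a named
#'   list, one entry per group, each a named numeric vector of fractions,
#'   e.g. `list(corolla_shape = c(tube = 0.5))`. States not listed share the
#'   remaining probability uniformly. The generator errors when a group's
#'   targets are unachievable (their sum exceeds the coded fraction
#'   `1 - missing_rate`).
#' @param polymorphism_rate probability that a coded taxon carries a second
#'   state in a group; default 0.15.
#' @param missing_rate probability that a (taxon, group) coding is empty;
#'   default 0.10 (coding of real keys is chronically incomplete).
#' @param subspecies_rate fraction of taxa generated as subspecies of an
#'   earlier species; default 0.05.
#' @param synonym_rate number of synonym records per accepted taxon, as a
#'   rate; default 0.10.
#' @param qds_pool character vector of QDS codes ranges are drawn from;
#'   default a 96-square grid over the south-western Cape.
#' @param points_per_taxon Poisson mean of occurrence points per accepted
#'   taxon; default 3.
#' @param seed integer seed; the seed fully determines the dataset.
#' @return list of class `erica_dataset_spec`.
#' @seealso [generate_dataset()]
#' @export
dataset_spec <- function(n_taxa,
                         schema = default_schema(),
                         prevalence = list(),
                         polymorphism_rate = 0.15,
                         missing_rate = 0.10,
                         subspecies_rate = 0.05,
                         synonym_rate = 0.10,
                         qds_pool = default_qds_pool(),
                         points_per_taxon = 3,
                         seed = 1L) {
  stopifnot(n_taxa >= 1, inherits(schema, "erica_schema"))
  rates <- c(polymorphism_rate, missing_rate, subspecies_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (synonym_rate < 0 || points_per_taxon < 0) {
    stop("synonym_rate and points_per_taxon must be nonnegative",
         call. = FALSE)
  }
  for (gid in names(prevalence)) {
    g <- schema_group(schema, gid)
    p <- prevalence[[gid]]
    if (is.null(names(p)) || any(p < 0) || any(p > 1)) {
      stop("prevalence for group '", gid,
           "' must be a named vector of fractions in [0, 1]", call. = FALSE)
    }
    check_states(g, names(p))
    if (sum(p) > 1 - missing_rate + 1e-12) {
      stop("prevalence targets for group '", gid, "' sum to ", sum(p),
           ", more than the coded fraction ", 1 - missing_rate,
           " allows", call. = FALSE)
    }
  }
  structure(
    list(n_taxa = as.integer(n_taxa), schema = schema,
         prevalence = prevalence, polymorphism_rate = polymorphism_rate,
         missing_rate = missing_rate, subspecies_rate = subspecies_rate,
         synonym_rate = synonym_rate, qds_pool = as.character(qds_pool),
         points_per_taxon = points_per_taxon, seed = as.integer(seed)),
    class = "erica_dataset_spec"
  )
}

#' @rdname dataset_spec
#' @export
default_qds_pool <- function() {
  cells <- c("3318", "3319", "3418", "3419", "3320", "3420")
  letters2 <- as.vector(outer(QDS_LETTERS, QDS_LETTERS,
                              function(a, b) paste0(a, b)))
  as.vector(outer(cells, letters2, paste0))
}

# run code with a private, seeded RNG stream, restoring the caller's state
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# n unique pseudo-Latin epithets, deterministically from the current RNG
random_epithets <- function(n) {
  syllables <- c("ba", "ca", "da", "fa", "la", "ma", "na", "ra", "sa", "ta",
                 "be", "ce", "de", "le", "me", "ne", "re", "se", "te", "ve",
                 "bi", "ci", "di", "li", "mi", "ni", "ri", "si", "ti", "vi",
                 "bo", "co", "do", "lo", "mo", "no", "ro", "so", "to", "vo")
  endings <- c("ana", "ensis", "oides", "ata", "osa", "ella", "ifolia",
               "iflora", "icola", "ina")
  ep <- paste0(
    sample(syllables, n, replace = TRUE),
    sample(syllables, n, replace = TRUE),
    sample(endings, n, replace = TRUE))
  # disambiguate collisions deterministically
  dup <- duplicated(ep)
  if (any(dup)) ep[dup] <- paste0(ep[dup], "-", cumsum(dup)[dup])
  ep
}

#' Generate a synthetic key dataset
#'
#' Deterministic under the spec's seed: the same spec serialises to
#' byte-identical CSVs on every run. Generated datasets always pass
#' [validate_dataset()] with zero fatal findings.
#'
#' @param spec an [dataset_spec()].
#' @return an `erica_dataset`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "erica_dataset_spec"))
  with_rng(spec$seed, {
    n <- spec$n_taxa
    schema <- spec$schema

    # checklist: species, some subspecies of earlier species, some synonyms
    ep <- random_epithets(n)
    is_sub <- runif(n) < spec$subspecies_rate
    is_sub[1] <- FALSE  # need at least one species before any subspecies
    taxon_id <- sprintf("T%04d", seq_len(n))
    rank <- ifelse(is_sub, "subspecies", "species")
    parent_id <- rep(NA_character_, n)
    name <- character(n)
    species_seen <- integer(0)
    for (i in seq_len(n)) {
      if (is_sub[i]) {
        p <- species_seen[sample.int(length(species_seen), 1L)]
        parent_id[i] <- taxon_id[p]
        name[i] <- paste0(name[p], " subsp. ", ep[i])
      } else {
        name[i] <- paste0("Erica ", ep[i])
        species_seen <- c(species_seen, i)
      }
    }
    taxa <- data.frame(
      taxon_id = taxon_id, name = name, rank = rank, parent_id = parent_id,
      status = "accepted", accepted_id = NA_character_,
      wfo_id = sprintf("wfo-%010d", seq_len(n)),
      iucn = sample(c("LC", "NT", "VU", "EN", "CR", NA), n, replace = TRUE),
      sort_schumann = sprintf("%03d", sample.int(999, n, replace = TRUE)),
      sort_idno = sprintf("%04d", seq_len(n)),
      stringsAsFactors = FALSE)

    n_syn <- rpois(1, spec$synonym_rate * n)
    if (n_syn > 0) {
      sep <- random_epithets(n_syn)
      target <- sample(taxon_id, n_syn, replace = TRUE)
      syn <- data.frame(
        taxon_id = sprintf("S%04d", seq_len(n_syn)),
        name = paste0("Erica ", sep),
        rank = "species", parent_id = NA_character_, status = "synonym",
        accepted_id = target, wfo_id = NA_character_, iucn = NA_character_,
        sort_schumann = NA_character_, sort_idno = NA_character_,
        stringsAsFactors = FALSE)
      taxa <- rbind(taxa, syn)
    }

    # codings, one group at a time, vectorised across taxa
    codings <- vector("list", length(schema))
    for (k in seq_along(schema)) {
      g <- schema[[k]]
      miss <- runif(n) < spec$missing_rate
      prev <- spec$prevalence[[g$group_id]]
      q <- rep(0, length(g$states))
      names(q) <- g$states
      if (!is.null(prev)) {
        # carriers of a target state arise only via the primary draw, so the
        # realised carrier fraction converges to the requested one
        q[names(prev)] <- prev / max(1 - spec$missing_rate, 1e-12)
      }
      rest <- setdiff(g$states, names(prev))
      if (length(rest)) q[rest] <- (1 - sum(q)) / length(rest)
      if (any(q < -1e-9)) {
        stop("infeasible prevalence for group '", g$group_id, "'",
             call. = FALSE)
      }
      q <- pmax(q, 0)
      primary <- sample(g$states, n, replace = TRUE, prob = q)
      secondary_pool <- if (length(rest) >= 1) rest else g$states
      secondary <- sample(secondary_pool, n, replace = TRUE)
      poly <- runif(n) < spec$polymorphism_rate & secondary != primary
      cell <- ifelse(poly,
                     paste(pmin(primary, secondary),
                           pmax(primary, secondary), sep = "|"),
                     primary)
      keep <- !miss
      codings[[k]] <- data.frame(
        taxon_id = taxon_id[keep], group_id = g$group_id,
        states = cell[keep], stringsAsFactors = FALSE)
    }
    codings <- do.call(rbind, codings)
    codings <- codings[order(codings$taxon_id,
                             match(codings$group_id, group_ids(schema))), ,
                       drop = FALSE]

    # distributions: 1 + Poisson(2) squares per accepted taxon
    n_qds <- pmin(1L + rpois(n, 2), length(spec$qds_pool))
    dist <- data.frame(
      taxon_id = rep(taxon_id, n_qds),
      qds = unlist(lapply(n_qds, function(k) sample(spec$qds_pool, k))),
      stringsAsFactors = FALSE)

    # points: Poisson(points_per_taxon) per taxon, inside its coded squares
    pts_n <- rpois(n, spec$points_per_taxon)
    pts <- list()
    for (i in seq_len(n)) {
      if (pts_n[i] == 0) next
      own <- dist$qds[dist$taxon_id == taxon_id[i]]
      codes <- sample(own, pts_n[i], replace = TRUE)
      ll <- t(vapply(codes, function(cc) {
        bb <- qds_bbox(cc)
        c(round(runif(1, bb$south, bb$north), 6),
          round(runif(1, bb$west, bb$east), 6))
      }, c(0, 0)))
      pts[[length(pts) + 1L]] <- data.frame(
        taxon_id = taxon_id[i], latitude = ll[, 1], longitude = ll[, 2],
        source_label = "synthetic occurrence", source_url = NA_character_,
        stringsAsFactors = FALSE)
    }
    points <- if (length(pts)) do.call(rbind, pts) else empty_points()

    key_dataset(schema, taxa, codings, dist, points)
  })
}

#' The tube-on-the-Peninsula worked example
#'
#' A deterministic fixture reproducing the canonical worked identification:
#' a dataset in which exactly 361 taxa are coded corolla shape `"tube"` and
#' exactly 115 are coded region `"Cape Peninsula"`, so that the two groups
#' contribute `1/361 = 0.0027700` and `1/115 = 0.0086956` respectively.
#' Twenty taxa carry both states (a fixture choice — only the two carrier
#' counts are anchored), for 456 taxa in all, and those twenty share the top
#' rank with score `1/361 + 1/115`.
#'
#' @return list with `dataset` (an `erica_dataset`) and `selection` (the
#'   observation `list(corolla_shape = "tube", region = "Cape Peninsula")`).
#' @examples
#' we <- worked_example()
#' length(state_carriers(we$dataset, "corolla_shape", "tube"))
#' @export
worked_example <- function() {
  schema <- default_schema()
  n <- 456L  # 341 tube-only + 20 both + 95 Peninsula-only
  taxon_id <- sprintf("WE%03d", seq_len(n))
  taxa <- data.frame(
    taxon_id = taxon_id,
    name = sprintf("Erica exemplaris-%03d", seq_len(n)),
    rank = "species", parent_id = NA_character_, status = "accepted",
    accepted_id = NA_character_, wfo_id = NA_character_,
    iucn = NA_character_, sort_schumann = NA_character_,
    sort_idno = sprintf("%04d", seq_len(n)), stringsAsFactors = FALSE)

  tube <- seq_len(361L)            # carriers of corolla shape "tube"
  peninsula <- 342:456             # carriers of region "Cape Peninsula"
  codings <- rbind(
    data.frame(taxon_id = taxon_id, group_id = "corolla_shape",
               states = ifelse(seq_len(n) %in% tube, "tube", "cup"),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = taxon_id, group_id = "region",
               states = ifelse(seq_len(n) %in% peninsula,
                               "Cape Peninsula", "SW Cape"),
               stringsAsFactors = FALSE))

  pool <- c("3318CD", "3418AB", "3418AD", "3418BC")
  dist <- data.frame(taxon_id = taxon_id,
                     qds = pool[(seq_len(n) - 1L) %% length(pool) + 1L],
                     stringsAsFactors = FALSE)

  list(
    dataset = key_dataset(schema, taxa, codings, dist),
    selection = list(corolla_shape = "tube", region = "Cape Peninsula")
  )
}

#' Generate occurrence points for a dataset's distributions
#'
#' Samples points uniformly inside each coded QDS box, with an optional
#' fraction of "strays" displaced into an adjacent square that the taxon is
#' *not* coded for — exercising exactly the grid-versus-point discrepancies
#' that [coverage_report()] surfaces.
#'
#' @param ds an `erica_dataset` with distributions.
#' @param points_per_coded_qds Poisson mean of points per (taxon, square).
#' @param stray_rate fraction of points displaced into an adjacent uncoded
#'   square.
#' @param seed integer seed.
#' @return data frame of occurrence points (canonical `points` columns).
#' @export
generate_points <- function(ds, points_per_coded_qds, stray_rate = 0,
                            seed = 1L) {
  stopifnot(inherits(ds, "erica_dataset"),
            points_per_coded_qds >= 0, stray_rate >= 0, stray_rate <= 1)
  with_rng(seed, {
    dist <- ds$distributions[is_qds_code(ds$distributions$qds), ,
                             drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(dist))) {
      tid <- dist$taxon_id[i]
      code <- format_qds(dist$qds[i])
      k <- rpois(1, points_per_coded_qds)
      if (k == 0) next
      coded <- toupper(trimws(
        dist$qds[dist$taxon_id == tid]))
      for (j in seq_len(k)) {
        bb <- qds_bbox(code)
        if (runif(1) < stray_rate) {
          bb <- adjacent_uncoded_box(code, coded) %||% bb
        }
        out[[length(out) + 1L]] <- data.frame(
          taxon_id = tid,
          latitude = round(runif(1, bb$south, bb$north - 1e-6), 6),
          longitude = round(runif(1, bb$west, bb$east - 1e-6), 6),
          source_label = "synthetic occurrence",
          source_url = NA_character_, stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else empty_points()
  })
}

# the box of the first E/W/N/S neighbour of `code` not in `coded`;
# NULL when every neighbour is coded
adjacent_uncoded_box <- function(code, coded) {
  bb <- qds_bbox(code)
  cx <- (bb$west + bb$east) / 2
  cy <- (bb$south + bb$north) / 2
  for (d in list(c(0, 0.25), c(0, -0.25), c(0.25, 0), c(-0.25, 0))) {
    lat <- cy + d[1]
    lon <- cx + d[2]
    nb <- tryCatch(point_to_qds(lat, lon)$code, error = function(e) NULL)
    if (!is.null(nb) && !(nb %in% coded)) return(qds_bbox(nb))
  }
  NULL
}
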