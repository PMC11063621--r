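test_that("the worked example reproduces the printed reciprocals", {
  we <- worked_example()
  ds <- we$dataset

  expect_length(state_carriers(ds, "corolla_shape", "tube"), 361L)
  expect_length(state_carriers(ds, "region", "Cape Peninsula"), 115L)

  c1 <- group_contribution(ds, "corolla_shape", "tube")
  c2 <- group_contribution(ds, "region", "Cape Peninsula")
  expect_identical(format_probability(c1$value), "0.0027700")
  expect_identical(format_probability(c2$value), "0.0086956")
  expect_equal(c1$value, 1 / 361)
  expect_equal(c2$value, 1 / 115)

  rk <- probability_rank(ds, we$selection)
  # the 20 taxa coded both tube and Cape Peninsula share the top rank
  expect_equal(rk$score[1:20], rep(1 / 361 + 1 / 115, 20))
  expect_lt(rk$score[21], rk$score[20])
  expect_setequal(rk$taxon_id[1:20], strict_match(ds, we$selection))
})

test_that("carriers use union semantics and reject unknown tokens", {
  ds <- tiny_dataset()
  # polymorphic coding: sp1b is "SW Cape|Cape Peninsula", an OR
  expect_setequal(state_carriers(ds, "region", "Cape Peninsula"),
                  c("sp1a", "sp1b"))
  expect_setequal(state_carriers(ds, "region", "SW Cape"), "sp1b")
  # selecting several states unions the carrier sets
  expect_setequal(state_carriers(ds, "region",
                                 c("Cape Peninsula", "KZ-Natal")),
                  c("sp1a", "sp1b", "sp2"))
  # the full vocabulary selects every taxon coded for the group
  expect_setequal(state_carriers(ds, "region", ds$schema$region$states),
                  unique(ds$codings$taxon_id[ds$codings$group_id ==
                                             "region"]))
  expect_error(state_carriers(ds, "no_such_group", "tube"),
               "unknown character group 'no_such_group'")
  expect_error(state_carriers(ds, "corolla_shape", "tubee"), "'tubee'")
})

test_that("a single-carrier state contributes 1 and ranks its taxon first", {
  ds <- tiny_dataset()
  ct <- group_contribution(ds, "flowering_month", "Jan")
  expect_identical(ct$carrier_count, 1L)
  expect_identical(ct$value, 1)
  rk <- probability_rank(ds, list(flowering_month = "Jan"))
  expect_identical(rk$taxon_id[1], "sp2")
  expect_identical(rk$score[1], 1)
})

test_that("a zero-carrier state warns and contributes 0 to everyone", {
  ds <- tiny_dataset()
  expect_warning(ct <- group_contribution(ds, "corolla_shape", "globose"),
                 "corolla_shape")
  expect_identical(ct$carrier_count, 0L)
  expect_identical(ct$value, 0)
  # ranking stays total: the other constrained group still scores
  expect_warning(
    rk <- probability_rank(ds, list(corolla_shape = "globose",
                                    region = "KZ-Natal")),
    "corolla_shape")
  expect_identical(rk$taxon_id[1], "sp2")
  # strict matching over the same selection is simply empty
  expect_length(strict_match(ds, list(corolla_shape = "globose")), 0L)
})

test_that("ties are broken alphabetically and zero scores are opt-in", {
  ds <- tiny_dataset()
  rk <- probability_rank(ds, list(corolla_shape = "tube"))
  # sp1a, sp1b, sp3 all carry tube: equal scores, names in order
  expect_equal(rk$score, rep(1 / 3, 3))
  expect_identical(rk$name, sort(rk$name))
  expect_false("sp2" %in% rk$taxon_id)
  rk_all <- probability_rank(ds, list(corolla_shape = "tube"),
                             include_zero = TRUE)
  expect_setequal(rk_all$taxon_id, ranking_population(ds))
  expect_identical(rk_all$score[rk_all$taxon_id == "sp2"], 0)
})

test_that("selection validation rejects degenerate input", {
  ds <- tiny_dataset()
  expect_error(strict_match(ds, list()), "at least one")
  expect_error(probability_rank(ds, list()), "at least one")
  expect_error(probability_rank(ds, list(corolla_shape = character(0))),
               "empty")
  expect_error(probability_rank(ds, list("x")), "named list")
})

test_that("blanking a coded group drops a taxon from strict matching but
          only dents its probability score", {
  we <- worked_example()
  ds <- we$dataset
  target <- "WE342"  # carries both selected states

  before <- probability_rank(ds, we$selection, include_zero = TRUE)
  c_shape <- group_contribution(ds, "corolla_shape", "tube")
  expect_true(target %in% strict_match(ds, we$selection))

  blanked <- ds
  drop <- blanked$codings$taxon_id == target &
          blanked$codings$group_id == "corolla_shape"
  blanked$codings <- blanked$codings[!drop, , drop = FALSE]

  expect_false(target %in% strict_match(blanked, we$selection))
  after <- probability_rank(blanked, we$selection)
  expect_true(target %in% after$taxon_id)
  # the score drops by exactly the blanked group's (original) contribution
  expect_equal(after$score[after$taxon_id == target],
               before$score[before$taxon_id == target] - c_shape$value)
})

test_that("comparison tables isolate differing characters", {
  ds <- tiny_dataset()
  # sp1a and sp1b share corolla_shape; differ in colour and region coding
  cmp <- compare_taxa(ds, c("sp1a", "sp1b"),
                      c("corolla_shape", "corolla_colour"))
  expect_identical(cmp$group_id, c("corolla_shape", "corolla_colour"))
  expect_identical(cmp$sp1a[1], cmp$sp1b[1])     # both "tube"
  expect_false(identical(cmp$sp1a[2], cmp$sp1b[2]))
  # missing coding is NA, distinct from disjoint coded states
  full <- compare_taxa(ds, c("sp1a", "sp2"))
  expect_true(is.na(full$sp1a[full$group_id == "flowering_month"]))
  expect_identical(full$sp2[full$group_id == "flowering_month"], "Jan")
  # all 21 groups by default, in schema order
  expect_identical(full$group_id, unname(vapply(ds$schema, `[[`, "",
                                                "group_id")))
  # three taxa, one group: one row, three taxon columns
  one <- compare_taxa(ds, c("sp1a", "sp1b", "sp2"), "flowering_month")
  expect_identical(nrow(one), 1L)
  expect_identical(ncol(one), 5L)  # group_id, label, 3 taxa
  expect_error(compare_taxa(ds, c("sp1a", "sp1a")), "distinct")
  expect_error(compare_taxa(ds, "sp1a"), "at least two")
  expect_error(compare_taxa(ds, c("sp1a", "ghost")), "ghost")
  expect_error(compare_taxa(ds, c("sp1a", "syn1")), "accepted")
})

test_that("ranking invariants hold on seeded random datasets", {
  set.seed(42)
  for (rep in 1:30) {
    spec <- dataset_spec(n_taxa = sample(8:60, 1),
                         seed = sample.int(1e6, 1))
    ds <- generate_dataset(spec)
    sel <- random_selection(ds, n_groups = sample(1:3, 1))

    contribs <- suppressWarnings(
      lapply(names(sel), function(g) group_contribution(ds, g, sel[[g]])))
    for (ct in contribs) {
      if (ct$carrier_count > 0) {
        # normalization: the n carriers share exactly one unit
        expect_equal(ct$carrier_count * ct$value, 1)
        # uncertainty: adding a state never increases the contribution
        g <- ds$schema[[ct$group_id]]
        extra <- setdiff(g$states, ct$states)
        if (length(extra)) {
          wider <- suppressWarnings(
            group_contribution(ds, ct$group_id, c(ct$states, extra[1])))
          expect_lte(wider$value, ct$value)
        }
      }
    }

    # rarity reward across single states of one group
    g1 <- names(sel)[1]
    counts <- vapply(ds$schema[[g1]]$states, function(s) {
      length(suppressWarnings(state_carriers(ds, g1, s)))
    }, 0L)
    counts <- counts[counts > 0]
    if (length(counts) >= 2) {
      o <- order(counts)
      expect_true(all(diff((1 / counts)[o]) <= 1e-15))
    }

    # oracle agreement, and strict as the argmax of the ranking
    rk <- suppressWarnings(probability_rank(ds, sel, include_zero = TRUE))
    ora <- oracle_rank(ds, sel, include_zero = TRUE)
    expect_identical(rk$taxon_id, ora$taxon_id)
    expect_equal(rk$score, ora$score, tolerance = 1e-12)

    strict <- suppressWarnings(strict_match(ds, sel))
    expect_identical(sort(strict), oracle_strict(ds, sel))
    if (length(strict)) {
      max_score <- sum(vapply(contribs, `[[`, 0, "value"))
      expect_setequal(strict,
                      rk$taxon_id[abs(rk$score - max_score) < 1e-12])
    }
  }
})
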