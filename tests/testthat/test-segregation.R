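test_that("dosage deviations of the translocation pair map to the three modes", {
  co <- kary_cohort(
    c("46,XY",            # balanced/normal
      "47,XX,+14",        # trisomy of the higher translocation chromosome
      "45,XX,-13",        # monosomy of the lower one
      "48,XX,+13,+14",    # double disomy gamete
      "44,XY,-13,-14",    # double nullisomy gamete
      "46,XX,+14,-13",    # complex pattern, not an enumerated product
      "47,XY,+16"),       # only a non-translocation chromosome abnormal
    translocation = "rob(13;14)(q10;q10)"
  )
  cs <- classify_segregation(co)
  expect_equal(
    as.character(cs$segregation),
    c("alternate", "adjacent", "adjacent", "three_to_zero_other",
      "three_to_zero_other", "three_to_zero_other", "alternate")
  )
  expect_equal(cs$seg_product[1:5],
               c("normal_or_balanced", "disomy_14", "nullisomy_13",
                 "double_disomy", "double_nullisomy"))
  expect_true(is.na(cs$seg_product[6]))
  expect_match(cs$seg_reason[6], "complex pattern")
  expect_equal(cs$seg_d_a[2], 0L)
  expect_equal(cs$seg_d_b[2], 1L)
})

test_that("mosaic- or segmental-only translocation imbalance is unclassifiable", {
  cs <- classify_segregation(kary_cohort(
    c("46,XX,mos+13(0.40)", "46,XY,seg-14", "47,XX,+14,mos+13(0.30)"),
    translocation = "rob(13;14)"
  ))
  expect_equal(as.character(cs$segregation),
               c("unclassifiable", "unclassifiable", "adjacent"))
  expect_match(cs$seg_reason[1], "mosaic/segmental-only")
})

test_that("tabulation reports percentages over classifiable embryos only", {
  cs <- classify_segregation(seg_cohort(7, 3, 0))
  tab <- tabulate_segregation(cs)
  expect_equal(tab$n[tab$segregation == "alternate"], 7L)
  expect_equal(tab$percent[tab$segregation == "alternate"], 70)
  expect_equal(tab$percent[tab$segregation == "adjacent"], 30)

  # an unclassifiable embryo is shown but shrinks no denominator
  cs2 <- classify_segregation(dplyr::bind_rows(
    seg_cohort(7, 3, 0), kary_cohort("46,XX,mos+13(0.40)", "rob(13;14)",
                                     gender = "male", age = 30)
  ))
  tab2 <- tabulate_segregation(cs2)
  expect_equal(unique(tab2$total), 10L)
  expect_equal(tab2$n[tab2$segregation == "unclassifiable"], 1L)
  expect_true(is.na(tab2$percent[tab2$segregation == "unclassifiable"]))
})

test_that("empty strata are emitted with zero counts and absent percentages", {
  cs <- classify_segregation(seg_cohort(4, 1, 0))
  cs$gender <- factor(cs$gender, levels = c("male", "female"))
  tab <- tabulate_segregation(cs, gender)
  fem <- tab[tab$gender == "female", ]
  expect_equal(nrow(fem), 4L)
  expect_true(all(fem$n == 0))
  expect_true(all(is.na(fem$percent)))
})

test_that("category counts partition every stratum", {
  cfg <- sim_config(n_carrier_embryos = 400, n_control_embryos = 0, seed = 5,
                    unclassifiable_rate = 0.05)
  cs <- classify_segregation(simulate_cohort(cfg))
  tab <- tabulate_segregation(cs, gender)
  sums <- dplyr::summarise(
    dplyr::group_by(tab, gender),
    classifiable = sum(n[segregation != "unclassifiable"]),
    total = dplyr::first(total)
  )
  expect_equal(sums$classifiable, sums$total)
  expect_equal(sum(tab$n), 400L)
})

test_that("two-level comparison gives the cross-product OR and is symmetric", {
  common <- dplyr::bind_rows(
    seg_cohort(443, 130, 2, "rob(13;14)"),
    seg_cohort(87, 42, 3, "rob(14;21)")
  )
  cs <- classify_segregation(common)
  alt <- compare_segregation(cs, translocation, "alternate")
  adj <- compare_segregation(cs, translocation, "adjacent")
  expect_equal(round(alt$odds_ratio, 2), 1.74)
  expect_equal(round(adj$odds_ratio, 2), 0.63)

  flipped <- dplyr::mutate(
    cs, translocation = factor(translocation,
                               levels = c("rob(14;21)", "rob(13;14)"))
  )
  alt_rev <- compare_segregation(flipped, translocation, "alternate")
  expect_equal(alt_rev$odds_ratio, 1 / alt$odds_ratio, tolerance = 1e-12)
  expect_equal(alt_rev$p_value, alt$p_value)

  # no-association case
  null <- classify_segregation(dplyr::bind_rows(
    seg_cohort(30, 10, 0, gender = "male"),
    seg_cohort(30, 10, 0, gender = "female")
  ))
  ht <- compare_segregation(null, gender, "alternate")
  expect_equal(ht$odds_ratio, 1)
  expect_equal(ht$statistic, 0)

  expect_error(compare_segregation(cs, gender), "2 observed levels")
})

test_that("classification recovers the simulator's configured mode mix", {
  cfg <- sim_config(n_carrier_embryos = 1500, n_control_embryos = 0,
                    male_patient_fraction = 1, seed = 8)
  cs <- classify_segregation(simulate_cohort(cfg))
  probs <- dplyr::filter(cfg$mode_probs, gender == "male")
  obs <- prop.table(table(cs$segregation))[1:3]
  for (i in seq_along(obs)) {
    p <- c(probs$p_alt, probs$p_adj, probs$p_30)[i]
    expect_lt(abs(obs[[i]] - p), 3 * sqrt(p * (1 - p) / 1500) + 1e-9)
  }
})
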