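test_that("parser handles identity, trisomy and mosaic examples", {
  p <- parse_karyotype(c("46,XY", "47,XX,+21", "46,XY,mos+16(0.35)"))
  expect_equal(p$karyotype, c("46,XY", "47,XX,+21", "46,XY,mos+16(0.35)"))
  expect_equal(p$sex, c("XY", "XX", "XY"))
  expect_equal(vapply(p$calls, nrow, 0L), c(0L, 1L, 1L))

  tri21 <- p$calls[[2]]
  expect_equal(as.character(tri21$chromosome), "21")
  expect_equal(tri21$copies, 3L)
  expect_true(is.na(tri21$mosaic_fraction))

  mos16 <- p$calls[[3]]
  expect_equal(as.character(mos16$chromosome), "16")
  expect_equal(mos16$copies, 3L)
  expect_equal(mos16$mosaic_fraction, 0.35)
  expect_false(mos16$segmental)
})

test_that("malformed and inconsistent karyotypes are rejected, never dropped", {
  expect_error(parse_karyotype("46,XQ"), "sex token 'XQ' at position 2")
  expect_error(parse_karyotype("46,XY,foo"), "token 'foo' at position 3")
  expect_error(parse_karyotype("46,XY,+23"), "token '\\+23' at position 3")
  expect_error(parse_karyotype("48,XX,+21,+21"), "duplicate constitutional")
  expect_error(parse_karyotype("47,XX"), "modal count 47 inconsistent")
  expect_error(parse_karyotype("46,XY,mos+16"), "token 'mos\\+16' at position 3")
  expect_error(parse_karyotype("45,XX,-Y"), "negative copy number")
  expect_error(parse_karyotype(c("46,XY", "46,XX,+1"), where = c("row 1", "row 2")),
               "row 2")
})

test_that("writer is canonical and modal counts follow the dosage arithmetic", {
  k <- parse_karyotype(c("46,XX", "46,XY,-14,+21", "46,XX,mos-22(0.50)"))
  expect_equal(format_karyotype(k),
               c("46,XX", "46,XY,-14,+21", "46,XX,mos-22(0.50)"))

  # unsorted input is re-ordered: chromosome order, constitutional first
  k2 <- parse_karyotype("47,XY,mos+16(0.30),+21,-14,+13")
  expect_equal(k2$karyotype, "47,XY,+13,-14,mos+16(0.30),+21")
  expect_equal(k2$modal_count, 46L + (1L - 1L + 1L))

  # sex-chromosome loss is representable
  expect_equal(parse_karyotype("45,XY,-X")$modal_count, 45L)
})

test_that("parser and writer round-trip randomly generated karyotypes", {
  set.seed(42)
  for (i in 1:200) {
    sex <- sample(c("XX", "XY"), 1)
    auto <- sample(as.character(1:22), sample(0:3, 1))
    const <- if (length(auto)) {
      tibble::tibble(
        chromosome = factor(auto, levels = chromosome_levels()),
        copies = 2L + sample(c(-1L, 1L), length(auto), replace = TRUE),
        mosaic_fraction = NA_real_, segmental = FALSE
      )
    } else NULL
    mos_chr <- sample(as.character(1:22), sample(0:2, 1))
    mos <- if (length(mos_chr)) {
      tibble::tibble(
        chromosome = factor(mos_chr, levels = chromosome_levels()),
        copies = 2L + sample(c(-1L, 1L), length(mos_chr), replace = TRUE),
        mosaic_fraction = round(stats::runif(length(mos_chr), 0.05, 0.95), 2),
        segmental = FALSE
      )
    } else NULL
    calls <- dplyr::bind_rows(const, mos)
    if (ncol(calls) == 0) calls <- parse_karyotype("46,XX")$calls[[1]]
    text <- format_karyotype(tibble::tibble(sex = sex, calls = list(calls)))
    back <- parse_karyotype(text)
    expect_identical(back$karyotype, text)
    expect_identical(format_karyotype(back), text)
  }
})

test_that("translocation labels parse in all accepted spellings", {
  t <- rob_translocation(c("rob(13;14)(q10;q10)", "rob(14;13)", "21;14"))
  expect_equal(t$translocation, c("rob(13;14)", "rob(13;14)", "rob(14;21)"))
  expect_equal(t$chr_a, c("13", "13", "14"))
  expect_error(rob_translocation("rob(13;13)"), "invalid")
  expect_error(rob_translocation("rob(13;16)"), "invalid")
  expect_error(rob_translocation("t(11;22)"), "invalid")
})

test_that("every trivalent yields 8 distinct products split 2/4/2", {
  for (tr in rob_translocations()) {
    g <- gamete_products(tr)
    expect_equal(nrow(g), 8)
    expect_equal(anyDuplicated(g$product), 0)
    expect_equal(unname(table(g$mode)[c("alternate", "adjacent", "three_to_zero")]),
                 c(2L, 4L, 2L), ignore_attr = TRUE)
    # alternate products carry no imbalance; 3:0 products are double +/-
    expect_true(all(g$d_a[g$mode == "alternate"] == 0 &
                      g$d_b[g$mode == "alternate"] == 0))
    expect_setequal(paste(g$d_a[g$mode == "three_to_zero"],
                          g$d_b[g$mode == "three_to_zero"]),
                    c("1 1", "-1 -1"))
  }
})

test_that("adjacent products cover each single-chromosome imbalance once", {
  g <- gamete_products("rob(13;14)")
  adj <- g[g$mode == "adjacent", ]
  expect_setequal(paste(adj$d_a, adj$d_b), c("1 0", "-1 0", "0 1", "0 -1"))
  expect_setequal(adj$product,
                  c("disomy_13", "nullisomy_13", "disomy_14", "nullisomy_14"))
})
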