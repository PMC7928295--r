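seg_levels <- function() {
  c("alternate", "adjacent", "three_to_zero_other", "unclassifiable")
}

#' Maternal-age bands
#'
#' Dichotomises the carrier's age at the conventional advanced-maternal-age
#' boundary of 35 completed years.
#'
#' @param age Numeric vector of ages in completed years.
#' @param boundary Band boundary; ages strictly below it fall in the young
#'   band.
#' @return Factor with levels `"<35"` and `">=35"` (labels follow `boundary`).
#' @export
age_band <- function(age, boundary = 35) {
  labs <- c(paste0("<", boundary), paste0(">=", boundary))
  factor(ifelse(age < boundary, labs[1], labs[2]), levels = labs)
}

# constitutional dosage deviation of one chromosome, plus whether any
# mosaic/segmental call touches it
tchrom_state <- function(calls, sex, chrom) {
  hit <- as.character(calls$chromosome) == chrom
  const <- hit & is.na(calls$mosaic_fraction) & !calls$segmental
  d <- if (any(const)) {
    sum(calls$copies[const] - baseline_copies(chrom, sex))
  } else 0L
  list(d = as.integer(d), noisy = any(hit & !const))
}

#' Classify embryos into trivalent segregation products
#'
#' Maps each carrier embryo's molecular karyotype onto the meiotic
#' segregation mode of the Robertsonian trivalent, using only the
#' constitutional dosage deviations (dA, dB) of the two translocation
#' chromosomes:
#'
#' * (0, 0) — alternate (normal or balanced; the two are indistinguishable by
#'   copy number);
#' * exactly one deviation of +/-1 — adjacent (trisomy or monosomy of one
#'   translocation chromosome);
#' * both +1 or both -1 — 3:0 segregation (double disomy/nullisomy gamete);
#' * any other nonzero pattern (e.g. +1/-1) — binned with 3:0 in the
#'   `three_to_zero_other` bucket, with the pattern recorded.
#'
#' Embryos whose translocation chromosomes carry only mosaic or segmental
#' abnormalities are flagged `unclassifiable` (a mitotic origin cannot be
#' excluded) and are dropped from segregation denominators downstream.
#' Abnormalities of non-translocation chromosomes are ignored here; they are
#' the business of [classify_ice()].
#'
#' @param data A data frame of carrier embryos.
#' @param karyotype,translocation Columns of `data` (tidy-eval) holding the
#'   embryo karyotype string and the carrier's translocation label.
#' @return `data` with columns added: `segregation` (factor `alternate`,
#'   `adjacent`, `three_to_zero_other`, `unclassifiable`), `seg_product`
#'   (specific gamete product label, `NA` when not one of the eight
#'   enumerated), `seg_d_a`, `seg_d_b` (the dosage deviations) and
#'   `seg_reason` (free text for unclassifiable embryos).
#' @examples
#' cohort <- tibble::tibble(
#'   karyotype = c("46,XY", "47,XX,+14", "48,XX,+13,+14"),
#'   translocation = "rob(13;14)(q10;q10)"
#' )
#' classify_segregation(cohort)
#' @export
classify_segregation <- function(data, karyotype = karyotype,
                                 translocation = translocation) {
  kary <- dplyr::pull(data, {{ karyotype }})
  trans <- dplyr::pull(data, {{ translocation }})
  t <- rob_translocation(trans)
  parsed <- parse_karyotype(kary)

  st <- purrr::pmap(
    list(parsed$calls, parsed$sex, t$chr_a, t$chr_b),
    function(calls, sex, a, b) {
      sa <- tchrom_state(calls, sex, a)
      sb <- tchrom_state(calls, sex, b)
      list(da = sa$d, db = sb$d, noisy = sa$noisy || sb$noisy)
    }
  )
  da <- purrr::map_int(st, "da")
  db <- purrr::map_int(st, "db")
  noisy <- purrr::map_lgl(st, "noisy")

  balanced <- da == 0L & db == 0L
  category <- dplyr::case_when(
    balanced & noisy ~ "unclassifiable",
    balanced ~ "alternate",
    xor(da != 0L, db != 0L) & abs(da + db) == 1L ~ "adjacent",
    TRUE ~ "three_to_zero_other"
  )
  enum <- purrr::pmap_chr(list(t$chr_a, t$chr_b, da, db), function(a, b, da, db) {
    if (da == 0L && db == 0L) return("normal_or_balanced")
    if (da == 1L && db == 0L) return(paste0("disomy_", a))
    if (da == -1L && db == 0L) return(paste0("nullisomy_", a))
    if (da == 0L && db == 1L) return(paste0("disomy_", b))
    if (da == 0L && db == -1L) return(paste0("nullisomy_", b))
    if (da == 1L && db == 1L) return("double_disomy")
    if (da == -1L && db == -1L) return("double_nullisomy")
    NA_character_
  })
  dplyr::mutate(
    data,
    segregation = factor(category, levels = seg_levels()),
    seg_product = dplyr::if_else(category == "unclassifiable", NA_character_, enum),
    seg_d_a = da,
    seg_d_b = db,
    seg_reason = dplyr::case_when(
      category == "unclassifiable" ~
        "mosaic/segmental-only imbalance on a translocation chromosome",
      category == "three_to_zero_other" & is.na(enum) ~
        sprintf("complex pattern (%+d,%+d)", da, db),
      TRUE ~ NA_character_
    )
  )
}

#' Tabulate segregation products by stratum
#'
#' Counts embryos per segregation category within strata, with percentages
#' computed against classifiable embryos only (unclassifiable embryos are
#' reported but excluded from the denominator and carry no percentage).
#'
#' @param data A data frame already carrying a `segregation` column (see
#'   [classify_segregation()]).
#' @param ... Optional grouping columns (tidy-eval), e.g. `gender` or
#'   `age_band(age)`.
#' @return A tibble of class `rob_seg_table`: one row per stratum x category
#'   with `n`, `total` (classifiable embryos in the stratum) and `percent`
#'   (2-decimal, `NA` for empty strata and for the unclassifiable row).
#' @examples
#' cohort <- tibble::tibble(
#'   karyotype = rep(c("46,XY", "47,XX,+14"), c(7, 3)),
#'   translocation = "rob(13;14)"
#' )
#' tabulate_segregation(classify_segregation(cohort))
#' @export
tabulate_segregation <- function(data, ...) {
  grouped <- dplyr::group_by(data, ..., .drop = FALSE)
  out <- dplyr::count(grouped, segregation = .data$segregation, name = "n",
                      .drop = FALSE)
  out <- dplyr::mutate(
    out,
    total = sum(.data$n[.data$segregation != "unclassifiable"]),
    percent = dplyr::if_else(
      .data$segregation == "unclassifiable" | .data$total == 0L,
      NA_real_,
      round(100 * .data$n / .data$total, 2)
    )
  )
  out <- dplyr::ungroup(out)
  class(out) <- c("rob_seg_table", class(out))
  out
}

#' Compare a segregation category between two strata
#'
#' Builds the 2x2 table (category vs all other classifiable categories, by
#' the two levels of `factor`) and runs [contingency_test()]: cross-product
#' odds ratio, chi-square or Fisher's exact test by Cochran's rule, two-sided
#' p-value. Unclassifiable embryos are excluded.
#'
#' @param data A data frame with a `segregation` column.
#' @param factor A column of `data` (tidy-eval) with exactly two observed
#'   levels, e.g. carrier gender or `age_band(age)`.
#' @param category Segregation category to compare (`"alternate"`,
#'   `"adjacent"` or `"three_to_zero_other"`).
#' @param yates Passed to [contingency_test()].
#' @return A `rob_test` object; `tidy()` it for a one-row tibble.
#' @examples
#' cohort <- tibble::tibble(
#'   gender = rep(c("male", "female"), c(10, 10)),
#'   karyotype = rep(c("46,XY", "47,XX,+14", "46,XX", "47,XY,+13"), c(8, 2, 6, 4)),
#'   translocation = "rob(13;14)"
#' )
#' compare_segregation(classify_segregation(cohort), gender)
#' @export
compare_segregation <- function(data, factor, category = "alternate",
                                yates = FALSE) {
  quo <- rlang::enquo(factor)
  category <- match.arg(category, seg_levels()[1:3])
  data <- dplyr::filter(data, .data$segregation != "unclassifiable")
  lev <- rlang::eval_tidy(quo, data)
  lev <- if (is.factor(lev)) droplevels(lev) else
    base::factor(lev, levels = unique(lev))
  if (nlevels(lev) != 2) {
    stop("`factor` must have exactly 2 observed levels, got ", nlevels(lev),
         call. = FALSE)
  }
  hit <- data$segregation == category
  tab <- rbind(
    c(sum(hit & lev == levels(lev)[1]), sum(!hit & lev == levels(lev)[1])),
    c(sum(hit & lev == levels(lev)[2]), sum(!hit & lev == levels(lev)[2]))
  )
  if (any(rowSums(tab) == 0)) {
    stop("no classifiable embryos in level '",
         levels(lev)[rowSums(tab) == 0][1], "'", call. = FALSE)
  }
  contingency_test(tab, yates = yates, labels = levels(lev))
}
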