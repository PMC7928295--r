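ice_levels <- function() c("normal", "aneuploid", "mosaic")

#' Classify non-translocation chromosome status per embryo
#'
#' Interchromosomal-effect (ICE) categorisation: each embryo receives exactly
#' one label from the abnormalities of its non-excluded chromosomes, with
#' precedence aneuploid > mosaic > normal so the three categories partition
#' any cohort:
#'
#' * `aneuploid` — any constitutional whole-chromosome gain/loss or segmental
#'   imbalance;
#' * `mosaic` — otherwise, any mosaic call whose aneuploid-cell fraction
#'   exceeds `mosaic_threshold` (strictly greater);
#' * `normal` — otherwise. Mosaic calls at or below the threshold are treated
#'   as amplification/biopsy noise and ignored.
#'
#' For carrier embryos the two translocation chromosomes are excluded (their
#' imbalances are segregation products, not ICE); pass `translocation = NULL`
#' or an `NA` label for control embryos so that every chromosome, including
#' the acrocentrics and X/Y, is eligible.
#'
#' @param data A data frame of embryos.
#' @param karyotype Column of `data` (tidy-eval) with the karyotype string.
#' @param translocation Column of `data` with the carrier's translocation
#'   label (`NA` for controls), or `NULL` when the whole table is controls.
#' @param mosaic_threshold Aneuploid-cell fraction above which a mosaic call
#'   counts, default 0.20.
#' @return `data` with columns added: `ice_status` (factor `normal`,
#'   `aneuploid`, `mosaic`) and `ice_chromosomes`, a list-column of
#'   per-contributing-chromosome tibbles (`chromosome`, `sign`, `mosaic`).
#' @examples
#' classify_ice(
#'   tibble::tibble(karyotype = c("47,XX,+16", "47,XX,+13", "46,XY,mos+16(0.35)"),
#'                  translocation = "rob(13;14)")
#' )
#' @export
classify_ice <- function(data, karyotype = karyotype, translocation = NULL,
                         mosaic_threshold = 0.20) {
  stopifnot(mosaic_threshold > 0, mosaic_threshold < 1)
  kary <- dplyr::pull(data, {{ karyotype }})
  trans <- if (rlang::quo_is_null(rlang::enquo(translocation))) {
    rep(NA_character_, nrow(data))
  } else {
    as.character(dplyr::pull(data, {{ translocation }}))
  }
  excl <- purrr::map(trans, function(tr) {
    if (is.na(tr) || !nzchar(tr)) character() else {
      t <- rob_translocation(tr)
      c(t$chr_a, t$chr_b)
    }
  })
  parsed <- parse_karyotype(kary)
  res <- purrr::pmap(list(parsed$calls, excl, parsed$sex), function(calls, ex, sex) {
    calls <- calls[!(as.character(calls$chromosome) %in% ex), , drop = FALSE]
    const_or_seg <- is.na(calls$mosaic_fraction)
    mosaic_hit <- !is.na(calls$mosaic_fraction) &
      calls$mosaic_fraction > mosaic_threshold
    if (any(const_or_seg)) {
      keep <- const_or_seg
      status <- "aneuploid"
    } else if (any(mosaic_hit)) {
      keep <- mosaic_hit
      status <- "mosaic"
    } else {
      keep <- rep(FALSE, nrow(calls))
      status <- "normal"
    }
    contrib <- calls[keep, , drop = FALSE]
    list(
      status = status,
      contrib = tibble::tibble(
        chromosome = contrib$chromosome,
        sign = ifelse(contrib$copies >= baseline_copies(
          as.character(contrib$chromosome), sex
        ), 1L, -1L),
        mosaic = !is.na(contrib$mosaic_fraction)
      )
    )
  })
  dplyr::mutate(
    data,
    ice_status = factor(purrr::map_chr(res, "status"), levels = ice_levels()),
    ice_chromosomes = purrr::map(res, "contrib")
  )
}

#' Carrier-vs-control comparison of non-translocation abnormalities
#'
#' For each stratum and each ICE category (normal, aneuploid, mosaic) builds
#' the 2x2 table category-vs-rest by carrier-vs-control and runs
#' [contingency_test()]. Strata are defined on the carrier arm by gender and
#' age band; the control arm is stratified by age band only, so the same
#' control column is reused against male and female carriers (controls have
#' no carrier gender).
#'
#' @param carriers,controls Data frames already carrying `ice_status` (see
#'   [classify_ice()]); `carriers` also needs `gender` and `age` columns when
#'   the corresponding strata are requested.
#' @param strata Character vector of stratifiers drawn from `"gender"` and
#'   `"age"`; the default crosses overall/male/female with overall/young/old,
#'   giving the nine strata of the standard report.
#' @param mosaic_threshold,yates Passed through to the tests for labelling
#'   and correction choice.
#' @return A tibble of class `rob_ice_table`: one row per stratum x category
#'   with carrier/control counts and percentages, odds ratio, 95% CI, p-value
#'   and test used.
#' @export
ice_contingency <- function(carriers, controls, strata = c("gender", "age"),
                            mosaic_threshold = 0.20, yates = FALSE) {
  if (nrow(carriers) == 0) stop("carrier arm is empty", call. = FALSE)
  if (nrow(controls) == 0) stop("control arm is empty", call. = FALSE)
  strata <- match.arg(strata, c("gender", "age"), several.ok = TRUE)

  genders <- if ("gender" %in% strata) c(NA, "male", "female") else NA
  bands <- if ("age" %in% strata) c(NA, levels(age_band(0))) else NA
  grid <- tidyr::expand_grid(g = genders, b = bands)

  purrr::pmap_dfr(grid, function(g, b) {
    ca <- carriers
    co <- controls
    if (!is.na(g)) ca <- dplyr::filter(ca, .data$gender == g)
    if (!is.na(b)) {
      ca <- dplyr::filter(ca, age_band(.data$age) == b)
      co <- dplyr::filter(co, age_band(.data$age) == b)
    }
    # strata unpopulated in either arm are dropped rather than reported
    if (nrow(ca) == 0 || nrow(co) == 0) return(NULL)
    purrr::map_dfr(ice_levels(), function(cat) {
      a <- sum(ca$ice_status == cat)
      c_ <- sum(co$ice_status == cat)
      tab2 <- rbind(c(a, nrow(ca) - a), c(c_, nrow(co) - c_))
      # a category absent from (or saturating) both arms has no defined OR
      ht <- if (any(colSums(tab2) == 0)) {
        list(odds_ratio = NA_real_, or_ci95 = c(NA_real_, NA_real_),
             p_value = NA_real_, test_used = NA_character_)
      } else {
        contingency_test(tab2, yates = yates, labels = c("carrier", "control"))
      }
      tibble::tibble(
        gender = ifelse(is.na(g), "all", g),
        age_band = ifelse(is.na(b), "all", as.character(b)),
        category = cat,
        carrier_n = a,
        carrier_total = nrow(ca),
        carrier_percent = round(100 * a / nrow(ca), 2),
        control_n = c_,
        control_total = nrow(co),
        control_percent = round(100 * c_ / nrow(co), 2),
        odds_ratio = ht$odds_ratio,
        or_low = ht$or_ci95[1],
        or_high = ht$or_ci95[2],
        p_value = ht$p_value,
        test_used = ht$test_used
      )
    })
  }) -> out
  class(out) <- c("rob_ice_table", class(out))
  out
}

#' Per-chromosome abnormality spectrum
#'
#' Counts, chromosome by chromosome (1-22, X, Y), how many embryos in the
#' cohort contribute a constitutional/segmental (aneuploid) or
#' supra-threshold mosaic abnormality on that chromosome, with proportions
#' over the number of embryos in the cohort. Translocation chromosomes of
#' carrier embryos are excluded per embryo, exactly as in [classify_ice()],
#' so for a carrier cohort they contribute zero by construction.
#'
#' Unlike the single-label ICE status, the spectrum counts every abnormal
#' chromosome of an embryo (an embryo with two trisomies contributes twice).
#'
#' @inheritParams classify_ice
#' @return A tibble of class `rob_spectrum`: chromosome x class
#'   (`aneuploid`, `mosaic`) with `n`, `n_embryos` and `proportion`.
#' @export
chromosome_spectrum <- function(data, karyotype = karyotype,
                                translocation = NULL,
                                mosaic_threshold = 0.20) {
  stopifnot(nrow(data) > 0)
  kary <- dplyr::pull(data, {{ karyotype }})
  trans <- if (rlang::quo_is_null(rlang::enquo(translocation))) {
    rep(NA_character_, nrow(data))
  } else {
    as.character(dplyr::pull(data, {{ translocation }}))
  }
  parsed <- parse_karyotype(kary)
  contrib <- purrr::map2_dfr(parsed$calls, trans, function(calls, tr) {
    ex <- if (is.na(tr) || !nzchar(tr)) character() else {
      t <- rob_translocation(tr)
      c(t$chr_a, t$chr_b)
    }
    calls <- calls[!(as.character(calls$chromosome) %in% ex), , drop = FALSE]
    keep <- is.na(calls$mosaic_fraction) | calls$mosaic_fraction > mosaic_threshold
    calls <- calls[keep, , drop = FALSE]
    tibble::tibble(
      chromosome = calls$chromosome,
      class = as.character(ifelse(is.na(calls$mosaic_fraction), "aneuploid", "mosaic"))
    )
  })
  grid <- tidyr::expand_grid(
    chromosome = factor(chromosome_levels(), levels = chromosome_levels()),
    class = c("aneuploid", "mosaic")
  )
  counts <- dplyr::count(contrib, .data$chromosome, .data$class, name = "n")
  out <- dplyr::left_join(grid, counts, by = c("chromosome", "class"))
  out <- dplyr::mutate(
    out,
    n = tidyr::replace_na(.data$n, 0L),
    n_embryos = nrow(data),
    proportion = .data$n / nrow(data)
  )
  class(out) <- c("rob_spectrum", class(out))
  out
}
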