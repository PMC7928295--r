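cohort_columns <- function() {
  c("embryo_id", "patient_id", "arm", "gender", "age", "translocation",
    "karyotype")
}

#' Read a cohort file
#'
#' Cohort files are UTF-8 tab-separated tables with a mandatory header and
#' the fixed columns `embryo_id`, `patient_id`, `arm` (`carrier` or
#' `control`), `gender`, `age`, `translocation`, `karyotype`; extra columns
#' (e.g. the simulator's truth labels) are kept. Validation: embryo ids must
#' be unique, every `arm` value known, every carrier row must carry a
#' parseable translocation, and every karyotype string must parse — errors
#' name the offending row.
#'
#' @param path Path to a TSV file, e.g. one written by [write_cohort()].
#' @return A validated tibble of embryo records.
#' @export
read_cohort <- function(path) {
  data <- readr::read_tsv(
    path,
    col_types = readr::cols(
      age = readr::col_integer(),
      .default = readr::col_character()
    ),
    na = "", progress = FALSE
  )
  missing <- setdiff(cohort_columns(), names(data))
  if (length(missing)) {
    stop("cohort file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_cohort(data)
}

#' @rdname read_cohort
#' @param data A cohort data frame (validated in-memory the same way a file
#'   would be).
#' @export
validate_cohort <- function(data) {
  rows <- paste0("row ", seq_len(nrow(data)))
  if (anyDuplicated(data$embryo_id)) {
    stop("duplicate embryo_id: ",
         data$embryo_id[duplicated(data$embryo_id)][1], call. = FALSE)
  }
  bad_arm <- !data$arm %in% c("carrier", "control")
  if (any(bad_arm)) {
    stop("unknown arm value '", data$arm[bad_arm][1], "' at ",
         rows[bad_arm][1], call. = FALSE)
  }
  carrier <- data$arm == "carrier"
  no_trans <- carrier & (is.na(data$translocation) | !nzchar(data$translocation))
  if (any(no_trans)) {
    stop("carrier row without a translocation at ", rows[no_trans][1],
         call. = FALSE)
  }
  if (any(carrier)) rob_translocation(data$translocation[carrier])
  parse_karyotype(data$karyotype, where = rows)
  data
}

#' Write a cohort file
#'
#' @param data A cohort data frame.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_tsv(data, path, na = "", progress = FALSE)
  invisible(data)
}

#' Summarise a cohort
#'
#' Embryo counts per arm, per carrier gender and per age band, plus
#' patient-level translocation-type frequencies for the carrier arm. When an
#' attempted-biopsy count is supplied the diagnosis rate (diagnosed / attempted)
#' is reported as a percentage with two decimals.
#'
#' @param data A cohort data frame.
#' @param attempted Optional number of biopsied embryos before diagnosis
#'   failures; the cohort rows are the successfully diagnosed ones.
#' @return A long tibble: `stat`, `level`, `n`, `percent`.
#' @export
summarize_cohort <- function(data, attempted = NULL) {
  stopifnot(nrow(data) > 0)
  out <- list()
  arm_n <- vapply(c("carrier", "control"), function(a) sum(data$arm == a), 0L)
  out$arms <- tibble::tibble(
    stat = "embryos", level = names(arm_n), n = unname(arm_n),
    percent = round(100 * unname(arm_n) / nrow(data), 2)
  )
  carrier <- dplyr::filter(data, .data$arm == "carrier")
  if (nrow(carrier) > 0) {
    out$gender <- dplyr::summarise(
      dplyr::group_by(carrier, level = .data$gender),
      n = dplyr::n(), .groups = "drop"
    )
    out$gender <- dplyr::mutate(
      out$gender, stat = "carrier_embryos_by_gender",
      percent = round(100 * .data$n / nrow(carrier), 2)
    )
    out$age <- dplyr::summarise(
      dplyr::group_by(carrier, level = as.character(age_band(.data$age))),
      n = dplyr::n(), .groups = "drop"
    )
    out$age <- dplyr::mutate(
      out$age, stat = "carrier_embryos_by_age",
      percent = round(100 * .data$n / nrow(carrier), 2)
    )
    patients <- dplyr::distinct(carrier, .data$patient_id, .data$translocation)
    out$trans <- dplyr::count(patients, level = .data$translocation, name = "n")
    out$trans <- dplyr::mutate(
      out$trans, stat = "carrier_patients_by_translocation",
      percent = round(100 * .data$n / nrow(patients), 2)
    )
  }
  if (!is.null(attempted)) {
    out$diag <- tibble::tibble(
      stat = "diagnosis_rate", level = "diagnosed/attempted",
      n = nrow(data), percent = round(100 * nrow(data) / attempted, 2)
    )
  }
  dplyr::bind_rows(out)[, c("stat", "level", "n", "percent")]
}

# long-format segregation report: counts per stratum level plus the 2x2
# comparison of each category between the two levels
seg_comparison_long <- function(data, factor, yates = FALSE) {
  quo <- rlang::enquo(factor)
  tab <- tabulate_segregation(data, !!quo)
  names(tab)[1] <- "level"
  cmp <- purrr::map_dfr(seg_levels()[1:3], function(cat) {
    ht <- tidy(compare_segregation(data, !!quo, category = cat,
                                   yates = yates))
    tibble::tibble(segregation = cat, odds_ratio = ht$estimate,
                   p_value = ht$p.value, test_used = ht$method)
  })
  tab$segregation <- as.character(tab$segregation)
  dplyr::left_join(tab, cmp, by = "segregation")
}

#' Run the full analysis pipeline
#'
#' Classifies segregation products for the carrier arm, tabulates them by
#' carrier gender, age band and (when both are present) rob(13;14) versus
#' rob(14;21), runs the carrier-vs-control interchromosomal-effect
#' contingency table and the per-chromosome abnormality spectra, and writes
#' every report as TSV together with a run log.
#'
#' @param cohort A cohort data frame or a path readable by [read_cohort()].
#' @param output_dir Directory for the report bundle (created if needed).
#' @param mosaic_threshold Mosaic calling threshold, default 0.20.
#' @param yates Use the Yates-corrected chi-square where the chi-square
#'   branch applies? Off by default.
#' @param ice Run the carrier-vs-control comparison? Requires both arms.
#' @return Invisibly, a named list of the report tibbles.
#' @export
run_pipeline <- function(cohort, output_dir, mosaic_threshold = 0.20,
                         yates = FALSE, ice = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort) else
    cohort <- validate_cohort(cohort)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  carriers <- dplyr::filter(cohort, .data$arm == "carrier")
  controls <- dplyr::filter(cohort, .data$arm == "control")
  if (nrow(carriers) == 0) stop("segregation analysis: carrier arm required",
                                call. = FALSE)
  if (ice && nrow(controls) == 0) {
    stop("interchromosomal-effect analysis: control arm required", call. = FALSE)
  }

  carriers <- classify_segregation(carriers)
  reports <- list()
  reports$segregation_by_gender <-
    seg_comparison_long(carriers, gender, yates = yates)
  reports$segregation_by_age <-
    seg_comparison_long(dplyr::mutate(carriers, band = age_band(.data$age)),
                        band, yates = yates)
  common <- dplyr::filter(carriers,
                          .data$translocation %in% c("rob(13;14)", "rob(14;21)"))
  if (length(unique(common$translocation)) == 2) {
    reports$segregation_by_type <-
      seg_comparison_long(common, .data$translocation, yates = yates)
  }
  reports$segregation_overall <- tabulate_segregation(carriers)

  carriers <- classify_ice(carriers, translocation = translocation,
                           mosaic_threshold = mosaic_threshold)
  reports$spectrum_carrier <- chromosome_spectrum(
    carriers, translocation = translocation, mosaic_threshold = mosaic_threshold
  )
  if (ice) {
    controls <- classify_ice(controls, mosaic_threshold = mosaic_threshold)
    reports$ice_table <- ice_contingency(carriers, controls,
                                         mosaic_threshold = mosaic_threshold,
                                         yates = yates)
    reports$spectrum_control <- chromosome_spectrum(
      controls, mosaic_threshold = mosaic_threshold
    )
  }
  reports$cohort_summary <- summarize_cohort(cohort)

  for (nm in names(reports)) {
    readr::write_tsv(tibble::as_tibble(reports[[nm]]),
                     file.path(output_dir, paste0(nm, ".tsv")),
                     na = "", progress = FALSE)
  }
  log_lines <- c(
    paste0("robseg version: ", as.character(utils::packageVersion("robseg"))),
    paste0("R version: ", R.version.string),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("embryos: ", nrow(cohort), " (carrier ", sum(cohort$arm == "carrier"),
           ", control ", sum(cohort$arm == "control"), ")"),
    paste0("mosaic_threshold: ", mosaic_threshold, " (strictly greater than)"),
    paste0("yates: ", yates),
    "test selection: Cochran rule (Fisher if any expected < 5 or total < 40)",
    "odds ratio: cross-product, Haldane-Anscombe on zero cells, Woolf 95% CI",
    "unclassifiable embryos (mosaic/segmental-only on translocation chromosomes) excluded from segregation denominators",
    "segmental imbalances on non-translocation chromosomes counted as aneuploid"
  )
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(reports)
}
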