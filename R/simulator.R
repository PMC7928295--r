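#' Simulation configuration for synthetic PGT cohorts
#'
#' Bundles every probability and rate the cohort simulator uses. Defaults
#' describe a two-arm PGT cohort: 217 Robertsonian translocation carriers
#' contributing 977 informative blastocysts and 134 monogenic-disorder
#' control patients contributing 785, with gender-specific trivalent
#' segregation-mode probabilities, a translocation mix dominated by
#' rob(13;14) and rob(14;21), and background (non-translocation) aneuploidy
#' and mosaicism rates per arm.
#'
#' Background whole-chromosome errors are placed independently per eligible
#' chromosome with a per-chromosome rate derived from the per-embryo target:
#' `lambda = 1 - (1 - target)^(1/K)` where K is the number of eligible
#' chromosomes (20 autosomes for carrier embryos, whose translocation pair is
#' never hit; 22 autosomes plus the constitutional sex chromosomes for
#' controls). Mosaic events are single-chromosome with the aneuploid-cell
#' fraction drawn uniformly from `mosaic_fraction_range`; the per-embryo
#' event rate is derived as `target_mosaic / (1 - target_aneuploidy)` so the
#' observed mosaic-category proportion (which requires no constitutional hit)
#' matches the target.
#'
#' @param n_carrier_embryos,n_control_embryos Embryos per arm.
#' @param n_carrier_patients,n_control_patients Patients per arm.
#' @param male_patient_fraction Fraction of carrier patients who are male.
#' @param age_mean,age_sd Carrier/control age distribution (years, normal,
#'   rounded and clamped to 20-45).
#' @param translocation_weights Named numeric vector of sampling weights over
#'   the ten `rob(a;b)` labels (normalised internally).
#' @param mode_probs Tibble with columns `gender`, `p_alt`, `p_adj`, `p_30`;
#'   rows are normalised to sum to 1.
#' @param carrier_aneuploidy,control_aneuploidy Per-embryo probability of at
#'   least one constitutional background aneuploidy on eligible chromosomes.
#' @param carrier_mosaic,control_mosaic Target per-embryo proportion of the
#'   mosaic ICE category.
#' @param mosaic_fraction_range Range of the uniform law for mosaic
#'   aneuploid-cell fractions.
#' @param mosaic_threshold Calling threshold used when truth labels are
#'   assigned, default 0.20.
#' @param sex_chromosome_errors_controls Allow background errors on the sex
#'   chromosomes of control embryos?
#' @param unclassifiable_rate Probability that a carrier embryo's
#'   translocation-chromosome imbalance is rendered as a mosaic-only call
#'   (yielding an unclassifiable segregation truth label).
#' @param seed Optional integer seed; [simulate_cohort()] sets it before
#'   drawing anything, so equal configs give byte-identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_carrier_embryos = 977,
                       n_control_embryos = 785,
                       n_carrier_patients = 217,
                       n_control_patients = 134,
                       male_patient_fraction = 99 / 217,
                       age_mean = 30.6,
                       age_sd = 4.1,
                       translocation_weights = default_translocation_weights(),
                       mode_probs = default_mode_probs(),
                       carrier_aneuploidy = 0.2477,
                       control_aneuploidy = 0.2025,
                       carrier_mosaic = 0.0655,
                       control_mosaic = 0.0535,
                       mosaic_fraction_range = c(0.2, 0.8),
                       mosaic_threshold = 0.20,
                       sex_chromosome_errors_controls = TRUE,
                       unclassifiable_rate = 0,
                       seed = NULL) {
  probs <- c(male_patient_fraction, carrier_aneuploidy, control_aneuploidy,
             carrier_mosaic, control_mosaic, unclassifiable_rate)
  stopifnot(
    n_carrier_embryos >= 0, n_control_embryos >= 0,
    n_carrier_patients > 0, n_control_patients > 0,
    all(probs >= 0), all(probs <= 1),
    length(mosaic_fraction_range) == 2,
    mosaic_fraction_range[1] >= 0, mosaic_fraction_range[2] <= 1,
    mosaic_fraction_range[1] < mosaic_fraction_range[2],
    all(translocation_weights >= 0), sum(translocation_weights) > 0,
    all(names(translocation_weights) %in% rob_translocations()),
    all(c("gender", "p_alt", "p_adj", "p_30") %in% names(mode_probs))
  )
  rows <- mode_probs$p_alt + mode_probs$p_adj + mode_probs$p_30
  if (any(abs(rows - 1) > 1e-9)) {
    mode_probs$p_alt <- mode_probs$p_alt / rows
    mode_probs$p_adj <- mode_probs$p_adj / rows
    mode_probs$p_30 <- mode_probs$p_30 / rows
  }
  structure(
    list(
      n_carrier_embryos = as.integer(n_carrier_embryos),
      n_control_embryos = as.integer(n_control_embryos),
      n_carrier_patients = as.integer(n_carrier_patients),
      n_control_patients = as.integer(n_control_patients),
      male_patient_fraction = male_patient_fraction,
      age_mean = age_mean,
      age_sd = age_sd,
      translocation_weights = translocation_weights / sum(translocation_weights),
      mode_probs = mode_probs,
      carrier_aneuploidy = carrier_aneuploidy,
      control_aneuploidy = control_aneuploidy,
      carrier_mosaic = carrier_mosaic,
      control_mosaic = control_mosaic,
      mosaic_fraction_range = mosaic_fraction_range,
      mosaic_threshold = mosaic_threshold,
      sex_chromosome_errors_controls = sex_chromosome_errors_controls,
      unclassifiable_rate = unclassifiable_rate,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_sim_config <- function(seed = NULL) sim_config(seed = seed)

#' Default gender-specific segregation-mode probabilities
#'
#' Male carriers produce blastocysts from alternate / adjacent / 3:0-other
#' segregation at 82.45% / 17.12% / 0.42%; female carriers at 63.10% /
#' 36.11% / 0.79% (rows are renormalised to sum to exactly 1).
#'
#' @return Tibble with columns `gender`, `p_alt`, `p_adj`, `p_30`.
#' @export
default_mode_probs <- function() {
  tibble::tibble(
    gender = c("male", "female"),
    p_alt = c(0.8245, 0.6310),
    p_adj = c(0.1712, 0.3611),
    p_30 = c(0.0042, 0.0079)
  )
}

#' Default translocation-type mix
#'
#' rob(13;14) at 55.3% and rob(14;21) at 10.6% of carriers, the remaining
#' 34.1% spread uniformly over the other eight acrocentric pairs.
#'
#' @return Named numeric vector over the ten translocations, summing to 1.
#' @export
default_translocation_weights <- function() {
  w <- stats::setNames(rep((1 - 0.553 - 0.106) / 8, 10), rob_translocations())
  w["rob(13;14)"] <- 0.553
  w["rob(14;21)"] <- 0.106
  w
}

#' Sample gamete products of a trivalent
#'
#' Draws the segregation mode with the given probabilities, then one of that
#' mode's enumerated products uniformly (2 alternate, 4 adjacent, 2
#' three-to-zero). Draws come from R's global random number generator;
#' `set.seed()` beforehand for reproducibility.
#'
#' @param translocation A single translocation label.
#' @param n Number of gametes.
#' @param probs Numeric length-3 vector `(p_alt, p_adj, p_30)`, summing to 1.
#' @return A tibble of `n` rows sampled from [gamete_products()].
#' @examples
#' set.seed(1)
#' simulate_gametes("rob(13;14)", 5, c(0.72, 0.27, 0.01))
#' @export
simulate_gametes <- function(translocation, n, probs) {
  stopifnot(length(probs) == 3, all(probs >= 0), abs(sum(probs) - 1) < 1e-9)
  products <- gamete_products(translocation)
  mode <- sample(c("alternate", "adjacent", "three_to_zero"), n,
                 replace = TRUE, prob = probs)
  idx <- vapply(mode, function(m) {
    rows <- which(products$mode == m)
    rows[sample.int(length(rows), 1)]
  }, integer(1))
  products[idx, ]
}

# eligible background chromosomes for one embryo
eligible_background <- function(sex, exclude, sex_chrom) {
  chroms <- setdiff(as.character(1:22), exclude)
  if (sex_chrom) chroms <- c(chroms, if (sex == "XX") "X" else c("X", "Y"))
  chroms
}

# assemble one embryo's karyotype string and truth labels
simulate_embryo_one <- function(d_a, d_b, chr_a, chr_b, cfg, arm, sex,
                                lambda, mosaic_event_rate, sex_chrom) {
  exclude <- if (arm == "carrier") c(chr_a, chr_b) else character()
  chroms <- eligible_background(sex, exclude, sex_chrom)

  calls <- list()
  true_seg <- NA_character_
  if (arm == "carrier") {
    unclass <- cfg$unclassifiable_rate > 0 &&
      stats::runif(1) < cfg$unclassifiable_rate
    if (unclass) {
      frac <- round(stats::runif(1, cfg$mosaic_fraction_range[1],
                                 cfg$mosaic_fraction_range[2]), 2)
      calls[[length(calls) + 1]] <- tibble::tibble(
        chromosome = factor(chr_a, levels = chromosome_levels()),
        copies = 3L, mosaic_fraction = frac, segmental = FALSE
      )
      true_seg <- "unclassifiable"
    } else {
      true_seg <- if (d_a == 0L && d_b == 0L) "alternate"
        else if (xor(d_a != 0L, d_b != 0L)) "adjacent"
        else "three_to_zero_other"
      for (dd in list(c(chr_a, d_a), c(chr_b, d_b))) {
        d <- as.integer(dd[2])
        if (d != 0L) {
          calls[[length(calls) + 1]] <- tibble::tibble(
            chromosome = factor(dd[1], levels = chromosome_levels()),
            copies = 2L + d, mosaic_fraction = NA_real_, segmental = FALSE
          )
        }
      }
    }
  }

  hit <- chroms[stats::runif(length(chroms)) < lambda]
  for (ch in hit) {
    base <- baseline_copies(ch, sex)
    sign <- if (base == 0L) 1L else sample(c(-1L, 1L), 1)
    calls[[length(calls) + 1]] <- tibble::tibble(
      chromosome = factor(ch, levels = chromosome_levels()),
      copies = base + sign, mosaic_fraction = NA_real_, segmental = FALSE
    )
  }

  mosaic_called <- FALSE
  if (stats::runif(1) < mosaic_event_rate) {
    ch <- chroms[sample.int(length(chroms), 1)]
    base <- baseline_copies(ch, sex)
    sign <- if (base == 0L) 1L else sample(c(-1L, 1L), 1)
    # round to the two decimals the karyotype dialect prints, so the truth
    # label and the re-parsed fraction agree at the calling threshold
    frac <- round(stats::runif(1, cfg$mosaic_fraction_range[1],
                               cfg$mosaic_fraction_range[2]), 2)
    calls[[length(calls) + 1]] <- tibble::tibble(
      chromosome = factor(ch, levels = chromosome_levels()),
      copies = base + sign, mosaic_fraction = frac, segmental = FALSE
    )
    mosaic_called <- frac > cfg$mosaic_threshold
  }

  true_ice <- if (length(hit) > 0) "aneuploid"
    else if (mosaic_called) "mosaic" else "normal"

  calls <- if (length(calls)) dplyr::bind_rows(calls) else empty_calls()
  list(
    karyotype = format_karyotype(tibble::tibble(sex = sex, calls = list(calls))),
    true_segregation = true_seg,
    true_ice = true_ice
  )
}

#' Simulate a two-arm synthetic PGT cohort
#'
#' Generates carrier and control patients with their covariates, assigns
#' embryos to patients, draws each carrier embryo's trivalent segregation
#' product from the gender-specific mode probabilities (fertilisation is by a
#' euploid gamete, so the gamete's dosage deviations carry into the embryo),
#' superimposes background constitutional aneuploidies and single-chromosome
#' mosaic events on non-translocation chromosomes, and writes each embryo's
#' karyotype string together with its ground-truth labels.
#'
#' Background events are never placed on a carrier embryo's translocation
#' chromosomes, so the segregation truth label is always recoverable by
#' [classify_segregation()].
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per embryo: `embryo_id`, `patient_id`,
#'   `arm` (`"carrier"`/`"control"`), `gender` (carrier's gender, `NA` for
#'   controls), `age`, `translocation` (`NA` for controls), `karyotype`,
#'   `true_segregation` and `true_ice`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_carrier_embryos = 20,
#'                                      n_control_embryos = 10, seed = 1))
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n_male <- round(config$male_patient_fraction * config$n_carrier_patients)
  carrier_patients <- tibble::tibble(
    patient_id = sprintf("RT%03d", seq_len(config$n_carrier_patients)),
    gender = rep(c("male", "female"),
                 c(n_male, config$n_carrier_patients - n_male)),
    age = pmin(pmax(round(stats::rnorm(config$n_carrier_patients,
                                       config$age_mean, config$age_sd)), 20), 45),
    translocation = sample(names(config$translocation_weights),
                           config$n_carrier_patients, replace = TRUE,
                           prob = config$translocation_weights)
  )
  control_patients <- tibble::tibble(
    patient_id = sprintf("MD%03d", seq_len(config$n_control_patients)),
    gender = NA_character_,
    age = pmin(pmax(round(stats::rnorm(config$n_control_patients,
                                       config$age_mean, config$age_sd)), 20), 45),
    translocation = NA_character_
  )

  one_arm <- function(patients, n_embryos, arm) {
    if (n_embryos == 0) {
      return(tibble::tibble(
        embryo_id = character(), patient_id = character(), arm = character(),
        gender = character(), age = integer(), translocation = character(),
        karyotype = character(), true_segregation = character(),
        true_ice = character()
      ))
    }
    pick <- sort(sample.int(nrow(patients), n_embryos, replace = TRUE))
    emb <- patients[pick, ]
    emb$arm <- arm
    emb$embryo_id <- sprintf("%s-E%04d", arm, seq_len(n_embryos))
    emb$sex <- sample(c("XX", "XY"), n_embryos, replace = TRUE)

    if (arm == "carrier") {
      lambda <- 1 - (1 - config$carrier_aneuploidy)^(1 / 20)
      mosaic_rate <- config$carrier_mosaic / (1 - config$carrier_aneuploidy)
      sex_chrom <- FALSE
      mp <- config$mode_probs
      t <- rob_translocation(emb$translocation)
      emb$chr_a <- t$chr_a
      emb$chr_b <- t$chr_b
      gam <- purrr::map2_dfr(emb$translocation, emb$gender, function(tr, g) {
        row <- mp[mp$gender == g, ]
        simulate_gametes(tr, 1, c(row$p_alt, row$p_adj, row$p_30))
      })
      emb$d_a <- gam$d_a
      emb$d_b <- gam$d_b
    } else {
      # controls average ~23.5 eligible chromosomes (X only for XX embryos)
      k <- if (config$sex_chromosome_errors_controls) 23.5 else 22
      lambda <- 1 - (1 - config$control_aneuploidy)^(1 / k)
      mosaic_rate <- config$control_mosaic / (1 - config$control_aneuploidy)
      sex_chrom <- config$sex_chromosome_errors_controls
      emb$chr_a <- NA_character_
      emb$chr_b <- NA_character_
      emb$d_a <- 0L
      emb$d_b <- 0L
    }

    sim <- purrr::pmap(
      list(emb$d_a, emb$d_b, emb$chr_a, emb$chr_b, emb$sex),
      function(d_a, d_b, chr_a, chr_b, sex) {
        simulate_embryo_one(d_a, d_b, chr_a, chr_b, config, arm, sex,
                            lambda, mosaic_rate, sex_chrom)
      }
    )
    emb$karyotype <- purrr::map_chr(sim, "karyotype")
    emb$true_segregation <- purrr::map_chr(sim, "true_segregation")
    emb$true_ice <- purrr::map_chr(sim, "true_ice")
    emb[, c("embryo_id", "patient_id", "arm", "gender", "age",
            "translocation", "karyotype", "true_segregation", "true_ice")]
  }

  dplyr::bind_rows(
    one_arm(carrier_patients, config$n_carrier_embryos, "carrier"),
    one_arm(control_patients, config$n_control_embryos, "control")
  )
}
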