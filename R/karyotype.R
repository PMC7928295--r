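#' Chromosome labels in canonical order
#'
#' All tabulations in the package order chromosomes 1-22 followed by X and Y.
#'
#' @return Character vector of the 24 chromosome labels.
#' @export
chromosome_levels <- function() c(as.character(1:22), "X", "Y")

# the five human acrocentric chromosomes eligible for Robertsonian fusion
acrocentric_levels <- function() c("13", "14", "15", "21", "22")

#' Parse Robertsonian translocation labels
#'
#' Accepts full ISCN-style labels such as `"rob(13;14)(q10;q10)"` as well as
#' the short forms `"rob(13;14)"` and `"13;14"`. Both chromosomes must be
#' acrocentric (13, 14, 15, 21 or 22) and distinct; the pair is stored in
#' ascending numeric order.
#'
#' @param x Character vector of translocation labels.
#' @return A tibble with one row per input: `translocation` (canonical
#'   `"rob(13;14)"` label), `chr_a`, `chr_b` (character chromosome labels,
#'   `chr_a < chr_b` numerically).
#' @examples
#' rob_translocation(c("rob(13;14)(q10;q10)", "21;14"))
#' @export
rob_translocation <- function(x) {
  x_chr <- as.character(x)
  m <- stringr::str_match(
    x_chr,
    "^(?:rob\\((\\d{1,2});(\\d{1,2})\\)(?:\\(q10;q10\\))?|(\\d{1,2});(\\d{1,2}))$"
  )
  a <- dplyr::coalesce(m[, 2], m[, 4])
  b <- dplyr::coalesce(m[, 3], m[, 5])
  bad <- is.na(a) | is.na(b) | !(a %in% acrocentric_levels()) |
    !(b %in% acrocentric_levels()) | a == b
  if (any(bad)) {
    stop("invalid Robertsonian translocation label: ",
         paste(unique(x_chr[bad]), collapse = ", "),
         " (expected two distinct acrocentric chromosomes, e.g. 'rob(13;14)(q10;q10)')",
         call. = FALSE)
  }
  swap <- as.integer(a) > as.integer(b)
  chr_a <- ifelse(swap, b, a)
  chr_b <- ifelse(swap, a, b)
  tibble::tibble(
    translocation = sprintf("rob(%s;%s)", chr_a, chr_b),
    chr_a = chr_a,
    chr_b = chr_b
  )
}

#' All ten Robertsonian translocations
#'
#' @return Character vector of the 10 distinct D;G acrocentric pairs in
#'   canonical `"rob(a;b)"` form.
#' @export
rob_translocations <- function() {
  pairs <- utils::combn(acrocentric_levels(), 2)
  sprintf("rob(%s;%s)", pairs[1, ], pairs[2, ])
}

# baseline copy number of each chromosome given the sex constitution
baseline_copies <- function(chromosome, sex) {
  ifelse(chromosome %in% as.character(1:22), 2L,
         ifelse(chromosome == "X", ifelse(sex == "XX", 2L, 1L),
                ifelse(sex == "XY", 1L, 0L)))
}

empty_calls <- function() {
  tibble::tibble(
    chromosome = factor(character(), levels = chromosome_levels()),
    copies = integer(),
    mosaic_fraction = double(),
    segmental = logical()
  )
}

# scalar worker behind parse_karyotype(); `where` feeds error messages
parse_karyotype_one <- function(text, where = NULL) {
  ctx <- if (is.null(where)) sprintf(" in '%s'", text) else
    sprintf(" in '%s' (%s)", text, where)
  if (is.na(text) || !nzchar(trimws(text))) {
    stop("empty karyotype string", ctx, call. = FALSE)
  }
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  if (length(tokens) < 2) {
    stop("karyotype must have at least '<modal count>,<sex>'", ctx, call. = FALSE)
  }
  if (!grepl("^\\d{2}$", tokens[1])) {
    stop("malformed modal count token '", tokens[1], "' at position 1", ctx,
         call. = FALSE)
  }
  modal <- as.integer(tokens[1])
  sex <- tokens[2]
  if (!sex %in% c("XX", "XY")) {
    stop("malformed sex token '", sex, "' at position 2", ctx, call. = FALSE)
  }
  abn <- tokens[-(1:2)]
  n <- length(abn)
  if (n == 0) {
    calls <- empty_calls()
  } else {
    m <- stringr::str_match(
      abn, "^(mos|seg)?([+-])(\\d{1,2}|X|Y)(?:\\((\\d\\.\\d{2})\\))?$"
    )
    kind <- dplyr::coalesce(m[, 2], "const")
    sign <- ifelse(m[, 3] == "+", 1L, -1L)
    chrom <- m[, 4]
    frac <- suppressWarnings(as.numeric(m[, 5]))
    bad <- is.na(m[, 1]) | !(chrom %in% chromosome_levels()) |
      (kind == "mos" & (is.na(frac) | frac <= 0 | frac > 1)) |
      (kind != "mos" & !is.na(frac))
    if (any(bad)) {
      i <- which(bad)[1]
      stop("malformed abnormality token '", abn[i], "' at position ", i + 2L,
           ctx, call. = FALSE)
    }
    copies <- baseline_copies(chrom, sex) + sign
    if (any(copies < 0)) {
      i <- which(copies < 0)[1]
      stop("abnormality token '", abn[i], "' at position ", i + 2L,
           " implies a negative copy number", ctx, call. = FALSE)
    }
    dup <- duplicated(paste(kind, chrom)) & kind != "mos"
    if (any(duplicated(chrom[kind == "const"]))) {
      stop("duplicate constitutional call for chromosome ",
           chrom[kind == "const"][duplicated(chrom[kind == "const"])][1],
           ctx, call. = FALSE)
    }
    if (any(dup)) {
      stop("duplicate ", kind[dup][1], " call for chromosome ",
           chrom[dup][1], ctx, call. = FALSE)
    }
    calls <- tibble::tibble(
      chromosome = factor(chrom, levels = chromosome_levels()),
      copies = as.integer(copies),
      mosaic_fraction = ifelse(kind == "mos", frac, NA_real_),
      segmental = kind == "seg"
    )
  }
  const <- is.na(calls$mosaic_fraction) & !calls$segmental
  dev_sum <- sum(calls$copies[const] -
                   baseline_copies(as.character(calls$chromosome[const]), sex))
  if (modal != 46L + dev_sum) {
    stop("modal count ", modal, " inconsistent with constitutional calls (expected ",
         46L + dev_sum, ")", ctx, call. = FALSE)
  }
  list(sex = sex, calls = calls)
}

#' Parse molecular karyotype strings
#'
#' The dialect is `"<modal count>,<sex>[,<abn>...]"` with `<sex>` one of
#' `XX`/`XY` and each `<abn>` one of:
#' * `+N` / `-N` — constitutional whole-chromosome gain or loss,
#' * `mos+N(f)` / `mos-N(f)` — mosaic gain or loss at aneuploid-cell
#'   fraction `f` (decimal, two digits, e.g. `(0.35)`),
#' * `seg+N` / `seg-N` — segmental (partial-chromosome) imbalance.
#'
#' `N` is `1`-`22`, `X` or `Y`. Chromosomes without a call are disomic
#' (autosomes) or at the sex-constitution baseline. The modal count must equal
#' 46 plus the summed constitutional dosage deviations; unknown or duplicate
#' tokens are errors, never silently dropped.
#'
#' @param text Character vector of karyotype strings.
#' @param where Optional character vector the same length as `text` used to
#'   locate errors (e.g. `"row 12"`).
#' @return A tibble with one row per input string: `karyotype` (canonical
#'   re-formatted string), `sex`, `modal_count`, and `calls`, a list-column of
#'   per-abnormality tibbles (`chromosome`, `copies`, `mosaic_fraction`,
#'   `segmental`).
#' @examples
#' parse_karyotype(c("46,XY", "47,XX,+21", "46,XY,mos+16(0.35)"))
#' @seealso [format_karyotype()] for the inverse operation.
#' @export
parse_karyotype <- function(text, where = NULL) {
  text <- as.character(text)
  parsed <- purrr::map2(
    text, if (is.null(where)) list(NULL) else as.list(where),
    function(x, w) parse_karyotype_one(x, w)
  )
  out <- tibble::tibble(
    sex = purrr::map_chr(parsed, "sex"),
    calls = purrr::map(parsed, "calls")
  )
  out$modal_count <- purrr::map2_int(out$calls, out$sex, function(calls, sex) {
    const <- is.na(calls$mosaic_fraction) & !calls$segmental
    46L + sum(calls$copies[const] -
                baseline_copies(as.character(calls$chromosome[const]), sex))
  })
  out$karyotype <- format_karyotype(out)
  out[, c("karyotype", "sex", "modal_count", "calls")]
}

#' Format molecular karyotypes canonically
#'
#' Writes the compact karyotype dialect accepted by [parse_karyotype()].
#' Abnormalities are ordered by chromosome (1-22, X, Y), then constitutional
#' before mosaic before segmental; mosaic fractions always print two decimals,
#' so `format_karyotype(parse_karyotype(x))` is the canonical form of `x` and
#' round-trips exactly.
#'
#' @param k A tibble as returned by [parse_karyotype()] (columns `sex` and
#'   `calls`).
#' @return Character vector of canonical karyotype strings.
#' @export
format_karyotype <- function(k) {
  purrr::map2_chr(k$calls, k$sex, function(calls, sex) {
    kind <- ifelse(!is.na(calls$mosaic_fraction), 1L, ifelse(calls$segmental, 2L, 0L))
    ord <- order(as.integer(calls$chromosome), kind)
    calls <- calls[ord, ]
    kind <- kind[ord]
    dev <- calls$copies - baseline_copies(as.character(calls$chromosome), sex)
    if (any(abs(dev) != 1)) {
      stop("copy number deviation of magnitude ", max(abs(dev)),
           " is not representable in the karyotype dialect", call. = FALSE)
    }
    tok <- paste0(
      c("", "mos", "seg")[kind + 1L],
      ifelse(dev > 0, "+", "-"),
      as.character(calls$chromosome),
      ifelse(kind == 1L, sprintf("(%.2f)", calls$mosaic_fraction), "")
    )
    modal <- 46L + sum(dev[kind == 0L])
    paste(c(modal, sex, tok), collapse = ",")
  })
}

#' Enumerate the eight gamete products of a Robertsonian trivalent
#'
#' At anaphase I the trivalent (derivative chromosome plus the two normal
#' homologues) can segregate three ways: alternate (both normal chromosomes to
#' one pole, the derivative to the other), adjacent (derivative plus one
#' normal chromosome together), or 3:0 (all three elements to one pole).
#' Counting both complementary poles this yields exactly eight gamete
#' karyotypes: 2 alternate (normal and balanced, both with zero dosage
#' deviation), 4 adjacent (disomy or nullisomy of one translocation
#' chromosome) and 2 three-to-zero (double disomy or double nullisomy).
#'
#' @param translocation A single translocation label accepted by
#'   [rob_translocation()].
#' @return A tibble of 8 rows: `translocation`, `mode` (factor `alternate`,
#'   `adjacent`, `three_to_zero`), `product` (descriptive label), `d_a`, `d_b`
#'   (signed dosage deviation of the lower- and higher-numbered translocation
#'   chromosome, each in -1/0/+1).
#' @examples
#' gamete_products("rob(13;14)")
#' @export
gamete_products <- function(translocation) {
  t <- rob_translocation(translocation)
  if (nrow(t) != 1) stop("`translocation` must be a single label", call. = FALSE)
  tibble::tibble(
    translocation = t$translocation,
    mode = factor(
      c("alternate", "alternate", "adjacent", "adjacent", "adjacent",
        "adjacent", "three_to_zero", "three_to_zero"),
      levels = c("alternate", "adjacent", "three_to_zero")
    ),
    product = c(
      "normal", "balanced",
      paste0("disomy_", t$chr_a), paste0("nullisomy_", t$chr_a),
      paste0("disomy_", t$chr_b), paste0("nullisomy_", t$chr_b),
      "double_disomy", "double_nullisomy"
    ),
    d_a = c(0L, 0L, 1L, -1L, 0L, 0L, 1L, -1L),
    d_b = c(0L, 0L, 0L, 0L, 1L, -1L, 1L, -1L)
  )
}
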