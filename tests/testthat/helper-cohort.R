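# build a carrier cohort with given per-category counts; karyotypes are
# noise-free representatives of each segregation product
seg_cohort <- function(n_alt, n_adj, n_other, translocation = "rob(13;14)",
                       gender = "male", age = 30) {
  t <- rob_translocation(translocation)
  adj_kary <- sprintf("47,XX,+%s", t$chr_b)
  other_kary <- sprintf("48,XY,+%s,+%s", t$chr_a, t$chr_b)
  tibble::tibble(
    karyotype = rep(c("46,XY", adj_kary, other_kary), c(n_alt, n_adj, n_other)),
    translocation = t$translocation,
    gender = gender,
    age = age
  )
}

# embryo table from a vector of karyotype strings
kary_cohort <- function(karyotype, translocation = NA_character_, ...) {
  tibble::tibble(karyotype = karyotype, translocation = translocation, ...)
}

# a full two-arm cohort table with ids, suitable for read/write round-trips
full_cohort <- function(n_carrier = 6, n_control = 4) {
  tibble::tibble(
    embryo_id = sprintf("E%03d", seq_len(n_carrier + n_control)),
    patient_id = rep(c("P1", "P2"), c(n_carrier, n_control)),
    arm = rep(c("carrier", "control"), c(n_carrier, n_control)),
    gender = rep(c("male", NA), c(n_carrier, n_control)),
    age = rep(c(31L, 36L), c(n_carrier, n_control)),
    translocation = rep(c("rob(13;14)", NA), c(n_carrier, n_control)),
    karyotype = rep(c("46,XY", "47,XX,+14", "46,XX", "47,XY,+16"),
                    length.out = n_carrier + n_control)
  )
}

# hypergeometric enumeration oracle for the two-sided Fisher p-value:
# probabilities of all fixed-margin tables from first principles (choose()),
# summing those no more probable than the observed table
fisher_oracle <- function(x) {
  a <- x[1, 1]
  r1 <- sum(x[1, ])
  r2 <- sum(x[2, ])
  c1 <- sum(x[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# random valid 2x2 table with the given maximum grand total
random_table <- function(max_total) {
  repeat {
    x <- matrix(stats::rpois(4, max_total / 6), 2)
    if (sum(x) <= max_total && sum(x) > 0) return(x)
  }
}
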