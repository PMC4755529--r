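# Shared builders for small fixtures; everything is generated in code.

mk_series <- function(id = "P1", day = integer(), hours = numeric(),
                      followup = 400L) {
  burden_series(id, day, hours, followup_days = followup)
}

mk_record <- function(id = "P1", day = integer(), hours = numeric(),
                      followup = 400L, chads2 = 2L, flag = FALSE) {
  patient_record(mk_series(id, day, hours, followup), chads2, flag)
}

# A record whose post-blanking average daily burden is exactly `avg`: the
# total burden spread over as few days (from day 31) as fit under 20 h/day.
mk_record_with_avg <- function(id, avg, followup = 130L, chads2 = 2L) {
  total <- avg * (followup - 30L)
  n <- max(1L, ceiling(total / 20))
  mk_record(id, day = seq(31L, length.out = n), hours = rep(total / n, n),
            followup = followup, chads2 = chads2)
}

# Random valid sparse cohort for round-trip / property tests.
rand_cohort <- function(n, seed) {
  with_seed_local(seed, {
    af_cohort(lapply(seq_len(n), function(i) {
      followup <- sample(40:400, 1L)
      k <- sample(0:min(20L, followup), 1L)
      day <- sort(sample(seq_len(followup), k))
      mk_record(sprintf("R%03d", i), day,
                round(runif(k, 0, 24), 3), followup,
                chads2 = sample(0:6, 1L), flag = runif(1) < 0.3)
    }))
  })
}

# Local seed sandbox for helpers/tests that should not disturb test RNG.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Central acceptance region for a Bin(n, p) count carrying the same tail
# mass as +/- 4 standard errors under normality (pnorm(-4) per side),
# computed exactly. Parametrized on the rarer outcome because qbinom is
# numerically unreliable for success probabilities near 1.
binom_4sigma_region <- function(n, p) {
  if (p <= 0.5) {
    c(stats::qbinom(stats::pnorm(-4), n, p),
      stats::qbinom(stats::pnorm(4), n, p))
  } else {
    n - rev(c(stats::qbinom(stats::pnorm(-4), n, 1 - p),
              stats::qbinom(stats::pnorm(4), n, 1 - p)))
  }
}

# Independent brute-force oracle: probability that at least one of the
# Bernoulli trials with probabilities `p` succeeds, by enumeration of all
# 2^n outcomes. Deliberately naive; usable for n <= ~12.
enum_detect_prob <- function(p) {
  n <- length(p)
  tot <- 0
  for (mask in seq_len(2^n) - 1L) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (!any(bits == 1L)) next
    tot <- tot + prod(ifelse(bits == 1L, p, 1 - p))
  }
  tot
}
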