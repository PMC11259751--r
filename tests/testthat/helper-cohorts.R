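# Builders for in-code fixtures: no data files are shipped.

# A small hand-built cohort in canonical units.
make_two_breed_cohort <- function() {
  cohort(data.frame(
    specimen_id = c("chihuahua_like", "st_bernard_like"),
    cbl = c(88.7, 240.0),
    msw = c(100, 132),
    v_cav = c(320, 4540),
    a_tm = c(27.7, 63.7),
    a_fp = c(1.1, 2.1),
    stringsAsFactors = FALSE
  ))
}

# Randomized valid cohort for round-trip property tests; sprinkles NAs
# (missing traits) and a projected specimen.
random_cohort <- function(n = 8, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    specimen_id = sprintf("sp%02d", seq_len(n)),
    cbl = runif(n, 80, 250),
    msw = runif(n, 50, 150),
    iw = runif(n, 40, 120),
    v_cav = runif(n, 300, 5000),
    v_mal = runif(n, 3, 15),
    v_inc = runif(n, 1.5, 8),
    v_stp = runif(n, 0.2, 0.8),
    v_lab = runif(n, 40, 120),
    a_tm = runif(n, 25, 70),
    a_fp = runif(n, 0.8, 2.2),
    d1 = runif(n, 7, 11),
    d2 = runif(n, 3, 5),
    malleus_length = runif(n, 6, 12),
    cochlear_turns = runif(n, 2.9, 3.4),
    role = c(rep("fit", n - 1), "projected"),
    stringsAsFactors = FALSE
  )
  # drop a few optional measurements at random
  for (f in c("v_mal", "d1", "d2", "malleus_length")) {
    drop <- sample(n, size = sample(0:2, 1))
    d[[f]][drop] <- NA
  }
  cohort(d, source = sprintf("random_cohort(seed=%d)", seed))
}

# Noise-free synthetic spec: every trait law with r2_target = 1.
noise_free_spec <- function(n = 17, seed = 7) {
  laws <- default_trait_laws()
  for (t in names(laws)) laws[[t]]$r2_target <- 1
  synthetic_cohort_spec(n = n, trait_laws = laws, seed = seed)
}

expect_cohorts_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 0,
               ignore_attr = TRUE)
}
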