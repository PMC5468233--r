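test_that("the probe filter keeps exactly the segments at or above threshold", {
  p <- make_profile(c(0.1, 0.2, 0.3), n_probes = c(50L, 100L, 250L))
  expect_equal(nrow(filter_segments(p, 100L)$segments), 2L)
  expect_equal(filter_segments(p, 100L)$segments$logR, c(0.2, 0.3))
  expect_equal(filter_segments(p, 1L)$segments, p$segments)
  expect_equal(nrow(filter_segments(p, 1000L)$segments), 0L)
})

test_that("BAF mirroring reflects about 0.5 and is idempotent", {
  expect_equal(mirror_baf(0.2), 0.8)
  expect_equal(mirror_baf(0.5), 0.5)
  expect_equal(mirror_baf(0.85), 0.85)
  expect_equal(mirror_baf(mirror_baf(c(0, 0.3, 0.9))), mirror_baf(c(0, 0.3, 0.9)))
  expect_error(mirror_baf(1.2), class = "snpdiv_param_error")
})

test_that("unit normalisation maps to [0,1] with the degenerate-range rule", {
  expect_equal(unit_normalise(c(-1, 0, 1)), c(0, 0.5, 1))
  expect_equal(unit_normalise(c(3, 3, 3)), c(0.5, 0.5, 0.5))
  expect_equal(unit_normalise(c(0, 4)), c(0, 1))
  expect_error(unit_normalise(numeric(0)), class = "snpdiv_param_error")
})

test_that("bin proportions follow the left-closed convention over the observed range", {
  h <- bin_proportions(c(0, 0, 0.5, 1.0), 2L)
  expect_equal(h$proportions, c(0.5, 0.5))
  expect_equal(h$edges, c(0, 0.5, 1))
  # degenerate range occupies one bin
  expect_equal(sum(bin_proportions(c(0.3, 0.3, 0.3), 10L)$proportions > 0), 1L)
  # uniform grid of 10 over 10 bins: 0.1 each (max lands in the top bin)
  expect_equal(bin_proportions(seq(0, 1, length.out = 10), 10L)$proportions,
               rep(0.1, 10))
  expect_error(bin_proportions(1:3, 1L), class = "snpdiv_param_error")
  # proportions always sum to 1
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(sample(1:50, 1))
    expect_equal(sum(bin_proportions(v, sample(2:30, 1))$proportions), 1)
  }
})

test_that("the Shannon index matches direct evaluation and vegan", {
  expect_equal(shannon_index(1), 0)
  expect_equal(shannon_index(c(0.5, 0.5)), log(2))
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_error(shannon_index(c(-0.1, 1.1)), class = "snpdiv_param_error")
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    p <- p / sum(p)
    expect_equal(shannon_index(p), unname(vegan::diversity(p, "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("the S score reproduces hand-binned entropies", {
  # all segments at one logR value: one occupied bin, zero entropy
  expect_equal(s_score(make_profile(rep(0.3, 6))), 0)
  # five segments, ten bins: proportions (0.4, 0.4, 0.2)
  p5 <- make_profile(c(-0.5, -0.5, 0, 0, 0.58))
  expect_equal(s_score(p5), 1.0549202, tolerance = 1e-6)
  # two equal groups at the range extremes: ln 2 for any bin count
  for (nb in c(2L, 5L, 10L, 24L)) {
    p2 <- make_profile(c(-1, -1, 1, 1))
    expect_equal(s_score(p2, score_params(n_bins = nb)), log(2))
  }
})

test_that("S is bounded, order-invariant and affine-invariant", {
  set.seed(21)
  for (i in 1:15) {
    v <- rnorm(sample(5:60, 1))
    nb <- sample(2:24, 1)
    pars <- score_params(n_bins = nb)
    s <- s_score(make_profile(v), pars)
    expect_gte(s, 0)
    expect_lte(s, log(nb) + 1e-12)
    expect_equal(s_score(make_profile(sample(v)), pars), s)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(s_score(make_profile(a * v + b), pars), s, tolerance = 1e-9)
  }
})

test_that("unscorable profiles raise typed errors, and batches survive them", {
  tiny <- make_profile(c(0.1, 0.2), n_probes = c(10L, 10L))
  expect_error(s_score(tiny), class = "snpdiv_unscorable")
  expect_error(r_score(tiny), class = "snpdiv_unscorable")
  ok <- make_profile(rnorm(10), runif(10), sample_id = "ok")
  res <- score_profiles(list(ok, tiny))
  expect_s3_class(res, "ith_scores")
  expect_equal(nrow(res), 2L)
  expect_false(is.na(res$S[1]))
  expect_true(is.na(res$S[2]) && !is.na(res$reason[2]))
})

test_that("baseline CN is the modal state by covered length, with tie-breaks", {
  allnorm <- make_profile(rep(0, 3), major = c(1, 1, 1), minor = c(1, 1, 1))
  expect_equal(baseline_cn(allnorm), c(major = 1L, minor = 1L))
  mixed <- make_profile(c(0, 0.3), major = c(1, 2), minor = c(1, 1),
                        lengths = c(60e6, 40e6))
  expect_equal(baseline_cn(mixed), c(major = 1L, minor = 1L))
  # 50/50 tie: smaller total CN wins
  tie <- make_profile(c(0, 0.5), major = c(1, 2), minor = c(1, 2),
                      lengths = c(50e6, 50e6))
  expect_equal(baseline_cn(tie), c(major = 1L, minor = 1L))
  nocn <- make_profile(c(0, 0.1))
  expect_error(baseline_cn(nocn), class = "snpdiv_param_error")
})

test_that("percentage of genome altered counts allele-specific mismatches in bp", {
  expect_equal(pct_genome_altered(
    make_profile(rep(0, 4), major = rep(1, 4), minor = rep(1, 4))), 0)
  expect_equal(pct_genome_altered(
    make_profile(c(0, 0.3), major = c(1, 2), minor = c(1, 1),
                 lengths = c(60e6, 40e6))), 0.4)
  # total CN can match the baseline while the allelic split differs
  p <- make_profile(c(0.5, 0.5), major = c(2, 2), minor = c(2, 1),
                    lengths = c(30e6, 10e6))
  expect_equal(pct_genome_altered(p), 0.25)
  # (1,2) order-normalises to (2,1): same state, not altered
  q <- make_profile(c(0.3, 0.3, 0.3), major = c(2, 1, 2), minor = c(1, 2, 1),
                    lengths = c(10e6, 10e6, 10e6))
  expect_equal(pct_genome_altered(q), 0)
})

test_that("splitting a segment into two with the same CN leaves pga unchanged", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    lens <- sample(5:50, n) * 1e6
    maj <- sample(0:3, n, TRUE)
    mnr <- pmin(maj, sample(0:2, n, TRUE))
    p <- make_profile(rnorm(n), major = maj, minor = mnr, lengths = lens)
    pick <- sample(n, 1)
    half <- floor(lens[pick] / 2)
    lens2 <- append(lens[-pick], c(half, lens[pick] - half), after = pick - 1)
    maj2 <- append(maj[-pick], rep(maj[pick], 2), after = pick - 1)
    mnr2 <- append(mnr[-pick], rep(mnr[pick], 2), after = pick - 1)
    p2 <- make_profile(rnorm(n + 1), major = maj2, minor = mnr2, lengths = lens2)
    expect_equal(pct_genome_altered(p2), pct_genome_altered(p))
  }
})
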