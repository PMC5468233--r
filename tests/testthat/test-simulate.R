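quiet_sets <- function(n = 1L, seed = 5L, ...) {
  set_distributions(n, sim_params(...), seed = seed)
}

test_that("set distributions are deterministic and respect their ranges", {
  s1 <- set_distributions(3, seed = 12)
  s2 <- set_distributions(3, seed = 12)
  expect_equal(s1, s2)
  prm <- sim_params(pga_range = c(0.1, 0.4))
  sets <- set_distributions(5, prm, seed = 3)
  for (sd_ in sets) {
    expect_true(sd_$pga_mean >= 0.1 && sd_$pga_mean <= 0.4)
    expect_equal(sum(sd_$baseline_probs), 1)
    # templates tile every chromosome exactly
    for (chr in 1:22)
      for (tmpl in sd_$templates[[chr]])
        expect_equal(sum(tmpl), prm$genome[chr])
  }
})

test_that("clone generation clamps the altered fraction and honours the 95% rule", {
  sd_ <- quiet_sets(seed = 5, pga_range = c(0, 0), pga_sd_frac = 0)[[1]]
  set.seed(8)
  cl <- suppressWarnings(generate_clone(sd_))
  expect_equal(cl$p_target, 0.02)      # clamped to the 2% floor
  expect_gt(length(cl$altered), 0L)
  expect_gt(cl$realised_pga, 0.95 * cl$p_target)
  # altered segments all deviate from the baseline
  seg <- cl$segments
  expect_true(all(seg$major[cl$altered] != cl$baseline[["major"]] |
                    seg$minor[cl$altered] != cl$baseline[["minor"]]))
  # non-altered segments carry exactly the baseline
  rest <- setdiff(seq_len(nrow(seg)), cl$altered)
  expect_true(all(seg$major[rest] == cl$baseline[["major"]] &
                    seg$minor[rest] == cl$baseline[["minor"]]))
})

test_that("realised altered fraction tracks the drawn target across clones", {
  sd_ <- quiet_sets(seed = 6, pga_range = c(0.25, 0.25), pga_sd_frac = 0.8)[[1]]
  set.seed(14)
  cl <- suppressWarnings(replicate(60, generate_clone(sd_), simplify = FALSE))
  p <- vapply(cl, `[[`, numeric(1), "p_target")
  realised <- vapply(cl, `[[`, numeric(1), "realised_pga")
  expect_true(all(realised > 0.95 * p))
  fit <- stats::lm(realised ~ p)
  expect_gt(summary(fit)$r.squared, 0.9)
  expect_gt(coef(fit)[2], 0.85)
  expect_lt(coef(fit)[2], 1.15)
})

test_that("subclones share boundaries, clamp divergence, and differ only on D_i", {
  sd_ <- quiet_sets(seed = 7)[[1]]
  set.seed(20)
  anc <- suppressWarnings(generate_clone(sd_))
  grp <- suppressWarnings(derive_subclones(anc, sd_, k = 4L))
  expect_length(grp$profiles, 5L)
  G <- sum(grp$segments$length)
  for (j in 1:4) {
    sub <- grp$profiles[[j + 1L]]
    expect_equal(sub$segments$start_bp, anc$segments$start_bp)
    expect_equal(sub$segments$end_bp, anc$segments$end_bp)
    D <- grp$divergent_sets[[j]]
    expect_gt(sum(grp$segments$length[D]), 0.95 * grp$divergences[j] * G)
    same <- sub$segments$major == anc$segments$major &
      sub$segments$minor == anc$segments$minor
    expect_true(all(!same[D]))
    expect_true(all(same[-D]))
  }
  # negative draws are clamped to the 1% floor
  sd0 <- quiet_sets(seed = 7, divergence_mean = -0.2, divergence_sd = 0)[[1]]
  set.seed(21)
  anc0 <- suppressWarnings(generate_clone(sd0))
  grp0 <- suppressWarnings(derive_subclones(anc0, sd0))
  expect_equal(grp0$divergences, rep(0.01, 4))
})

test_that("divergence draws centre on 15% with 5% spread", {
  sd_ <- quiet_sets(seed = 9)[[1]]
  set.seed(30)
  dv <- unlist(replicate(50, {
    anc <- suppressWarnings(generate_clone(sd_))
    suppressWarnings(derive_subclones(anc, sd_))$divergences
  }, simplify = FALSE))
  expect_equal(mean(dv), 0.15, tolerance = 0.012 / 0.15)
})

test_that("design enumeration reproduces the combinatorial layout", {
  set.seed(2)
  des <- enumerate_designs()
  expect_equal(nrow(des), 1105L)
  combos <- unique(des[, c("n_clones", paste0("c", 1:5))])
  expect_equal(nrow(combos), 285L)
  expect_equal(as.vector(table(combos$n_clones)), c(5L, 20L, 60L, 100L, 100L))
  expect_equal(as.vector(table(des$n_clones) / table(combos$n_clones)),
               c(1, 3, 4, 4, 4))
  # order sensitivity: (1,2,3) and (3,1,2) at (45,30,25)% are distinct designs
  t123 <- des[des$n_clones == 3 & des$c1 == 1 & des$c2 == 2 & des$c3 == 3 &
                des$f1 == 0.45, ]
  t312 <- des[des$n_clones == 3 & des$c1 == 3 & des$c2 == 1 & des$c3 == 2 &
                des$f1 == 0.45, ]
  expect_equal(nrow(t123), 1L)
  expect_equal(nrow(t312), 1L)
  # deterministic under a fixed seed
  set.seed(2)
  expect_equal(enumerate_designs(), des)
})

test_that("the full default design space counts 707,200 mixtures", {
  # 16 sets x 10 groups x 1,105 designs x 4 cellularities
  set.seed(4)
  per_group <- nrow(enumerate_designs())
  expect_equal(per_group, 1105L)
  expect_equal(16 * 10 * per_group * 4, 707200)
})

simple_group <- function() {
  # 4 segments of 10 Mb; clone 1 diploid, clone 2 with a (2,1) gain on s1,
  # clone 3 with bi-allelic loss on s2
  make_group(list(
    cbind(c(1, 1, 1, 1), c(1, 1, 1, 1)),
    cbind(c(2, 1, 1, 1), c(1, 1, 1, 1)),
    cbind(c(1, 0, 1, 1), c(1, 0, 1, 1)),
    cbind(c(3, 1, 2, 1), c(1, 1, 2, 1)),
    cbind(c(1, 1, 1, 2), c(1, 1, 1, 2))), lengths = rep(10e6, 4))
}

test_that("mixture allele copy numbers are frequency-weighted sums", {
  grp <- simple_group()
  # single clone: integer CN unchanged
  one <- mixture_allele_cn(list(clone_ids = 2L, frequencies = 1), grp)
  expect_equal(one$Na, c(2, 1, 1, 1))
  expect_equal(one$Nb, c(1, 1, 1, 1))
  # (2,1) at 0.6 + (1,1) at 0.4 -> (1.6, 1.0) on the altered segment
  mix <- mixture_allele_cn(list(clone_ids = c(2L, 1L), frequencies = c(0.6, 0.4)), grp)
  expect_equal(mix$Na[1], 1.6)
  expect_equal(mix$Nb[1], 1.0)
  # (0,0) at 0.5 + (2,2)-ish: use clones 3 and 1 on segment 2
  mix2 <- mixture_allele_cn(list(clone_ids = c(3L, 1L), frequencies = c(0.5, 0.5)), grp)
  expect_equal(mix2$Na[2], 0.5)
  expect_equal(mix2$Nb[2], 0.5)
  expect_error(mixture_allele_cn(list(clone_ids = 1:2, frequencies = 1), grp),
               class = "snpdiv_param_error")
})

test_that("rounding halves away from zero and order-normalises", {
  grp <- simple_group()
  rc <- rounded_cn(list(clone_ids = c(2L, 1L), frequencies = c(0.6, 0.4)), grp)
  expect_equal(rc$major[1], 2L)   # 1.6 -> 2
  expect_equal(rc$minor[1], 1L)   # 1.0 -> 1
  # a half rounds away from zero: 3*0.25 + 1*0.75 = 1.5 -> 2 on segment 1
  rc2 <- rounded_cn(list(clone_ids = c(4L, 1L), frequencies = c(0.25, 0.75)), grp)
  expect_equal(rc2$major[1], 2L)
  # single clone is the identity
  rc3 <- rounded_cn(list(clone_ids = 5L, frequencies = 1), grp)
  expect_equal(rc3$major, c(1L, 1L, 1L, 2L))
  expect_equal(rc3$minor, c(1L, 1L, 1L, 2L))
  # explicit half-away-from-zero check on the kernel
  expect_equal(snpdiv:::.round_half_away(c(1.5, 0.5, 2.5)), c(2, 1, 3))
})

test_that("mixture signals reproduce the cellularity model exactly", {
  grp <- simple_group()
  d1 <- list(clone_ids = 1L, frequencies = 1)
  for (C in c(0.2, 0.5, 1)) {
    sg <- synthesize_signal(d1, grp, cellularity = C, noise_sd = 0)
    expect_equal(sg$L0, rep(0, 4))      # diploid balance at any cellularity
    expect_equal(sg$mB0, rep(0.5, 4))
  }
  # clone with (2,1) at C = 0.5: logR = log2(1.25), mBAF = 0.6
  sg2 <- synthesize_signal(list(clone_ids = 2L, frequencies = 1), grp,
                           cellularity = 0.5, noise_sd = 0)
  expect_equal(sg2$L0[1], log2(1.25))
  expect_equal(sg2$mB0[1], 0.6)
  # bi-allelic loss at C = 0.8: logR = log2(0.2), mBAF = 0.5
  sg3 <- synthesize_signal(list(clone_ids = 3L, frequencies = 1), grp,
                           cellularity = 0.8, noise_sd = 0)
  expect_equal(sg3$L0[2], log2(0.2))
  expect_equal(sg3$mB0[2], 0.5)
  # the Na = Nb = 0 special case also holds at C = 1
  sg4 <- synthesize_signal(list(clone_ids = 3L, frequencies = 1), grp,
                           cellularity = 1, noise_sd = 0)
  expect_equal(sg4$mB0[2], 0.5)
  expect_error(synthesize_signal(d1, grp, cellularity = 0),
               class = "snpdiv_param_error")
})

test_that("noiseless mixture mBAF never drops below 0.5 and diploid logR is 0", {
  grp <- simple_group()
  set.seed(33)
  for (i in 1:20) {
    k <- sample(1:5, 1)
    ids <- sample(1:5, k)
    f <- runif(k); f <- f / sum(f)
    C <- runif(1, 0.05, 1)
    sg <- synthesize_signal(list(clone_ids = ids, frequencies = f), grp,
                            cellularity = C, noise_sd = 0)
    expect_true(all(sg$mB0 >= 0.5))
    tot <- sg$Na + sg$Nb
    expect_equal(sg$L0[abs(tot - 2) < 1e-12],
                 rep(0, sum(abs(tot - 2) < 1e-12)))
  }
})

test_that("true diversity is the Shannon index of the clone frequencies", {
  expect_equal(true_diversity(1), 0)
  expect_equal(true_diversity(c(0.5, 0.5)), 0.693147, tolerance = 1e-6)
  expect_equal(true_diversity(c(0.45, 0.30, 0.25)), 1.0670939, tolerance = 1e-7)
  expect_error(true_diversity(c(0.5, 0.4)), class = "snpdiv_param_error")
  expect_error(true_diversity(c(1.5, -0.5)), class = "snpdiv_param_error")
})

test_that("a pure clone at full cellularity scores like its exact profile", {
  grp <- simple_group()
  for (cid in c(2L, 4L, 5L)) {
    sg <- synthesize_signal(list(clone_ids = cid, frequencies = 1), grp,
                            cellularity = 1, noise_sd = 0)
    mixed <- signal_as_profile(sg, grp, "mix")
    st <- grp$profiles[[cid]]$segments
    exact <- snp_profile("clone", data.frame(
      chromosome = st$chromosome, start_bp = st$start_bp, end_bp = st$end_bp,
      n_probes = st$n_probes, logR = log2((st$major + st$minor) / 2),
      baf = 0.5 + abs(0.5 - st$minor / (st$major + st$minor))),
      mirrored = TRUE)
    pars <- score_params(n_bins = 4L)
    expect_equal(s_score(mixed, pars), s_score(exact, pars))
    expect_equal(r_score(mixed, pars), r_score(exact, pars))
  }
})

test_that("cohort simulation is reproducible end to end", {
  c1 <- suppressWarnings(simulate_cohort(seed = 77, n_sets = 1L, n_groups = 1L,
                                         n_random_combos = 2L))
  c2 <- suppressWarnings(simulate_cohort(seed = 77, n_sets = 1L, n_groups = 1L,
                                         n_random_combos = 2L))
  expect_equal(c1$rows, c2$rows)
  # 5 + 20 + 60 + 2 + 2 combos -> 5 + 60 + 240 + 8 + 8 designs, x4 cellularities
  expect_equal(nrow(c1$rows), 321L * 4L)
  expect_true(all(c1$rows$true_diversity[c1$rows$n_clones == 1] == 0))
  expect_true(all(c1$rows$true_diversity[c1$rows$n_clones > 1] > 0))
})
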