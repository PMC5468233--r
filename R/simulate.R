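# Generative model of clonal/subclonal allele-specific copy-number profiles
# and in-silico clone mixtures with known Shannon diversity.

# hg19 autosome lengths (bp), chromosomes 1..22
.HG19_AUTOSOMES <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392,  90354753,  81195210,  78077248,
   59128983,  63025520,  48129895,  51304566)

# allele-specific states (major >= minor) up to 4 copies per allele, with
# default catalogue weights favouring near-diploid alterations
.DEVIANT_STATES <- cbind(
  major = c(0, 1, 1, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 4),
  minor = c(0, 0, 1, 0, 1, 2, 0, 1, 2, 3, 0, 1, 2, 3, 4))
.DEVIANT_WEIGHTS <- c(0.02, 0.20, 0.12, 0.06, 0.18, 0.12, 0.02, 0.08,
                      0.06, 0.03, 0.01, 0.03, 0.04, 0.02, 0.01)

#' Generator parameters for the synthetic cohort
#'
#' Defaults emulate segmented SNP-array cohorts: hg19 autosomes cut by a
#' Poisson breakpoint process with 25 Mb mean segment length, Illumina-like
#' probe density of one probe per 1.2 kb, near-diploid baselines with some
#' genome-doubled samples, per-set percentage-of-genome-altered means between
#' 10% and 40%, and a deviant-state catalogue spanning (0,0) to (4,4).
#'
#' @param genome Integer vector of autosome lengths in bp (chromosomes 1-22).
#' @param mean_segment_mb Mean segment length (Mb) of the Poisson breakpoint
#'   process used for chromosome segmentation templates.
#' @param probes_per_bp Probe density; probe counts are
#'   `round(length_bp * probes_per_bp)` (min 1).
#' @param templates_per_chrom Number of alternative segmentations sampled per
#'   chromosome in each set (each clone picks one per chromosome at random
#'   with replacement).
#' @param baseline_levels,baseline_probs Possible baseline (major, minor)
#'   states and their cohort-level probabilities; each set perturbs the
#'   probabilities with a Dirichlet draw of concentration
#'   `baseline_concentration`.
#' @param baseline_concentration Dirichlet concentration for the per-set
#'   baseline-state probabilities.
#' @param pga_range Range from which each set's mean percentage of genome
#'   altered is drawn (uniformly).
#' @param pga_sd_frac Per-set sd of the percentage of genome altered, as a
#'   fraction of the set mean.
#' @param pga_min Floor for a clone's target altered fraction (clamped).
#' @param deviant_states,deviant_weights Catalogue states and their sampling
#'   weights.
#' @param catalogue_size Number of (state, length) entries per set.
#' @param catalogue_length_range Range (bp) of catalogue segment lengths
#'   (sampled log-uniformly).
#' @param n_subclones Subclones derived per ancestor clone.
#' @param divergence_mean,divergence_sd,divergence_min Normal parameters (and
#'   floor) of the genome fraction on which a subclone diverges from its
#'   ancestor.
#' @param length_match_tol Relative tolerance when matching catalogue entry
#'   lengths to a segment (doubled until a candidate exists).
#' @param noise_sd Gaussian noise sd added independently to the logR and mBAF
#'   of every mixture segment.
#' @param cellularities Tumour-cell fractions at which mixtures are rendered.
#' @return A `sim_params` list.
#' @export
sim_params <- function(genome = .HG19_AUTOSOMES,
                       mean_segment_mb = 25,
                       probes_per_bp = 1 / 1200,
                       templates_per_chrom = 22L,
                       baseline_levels = cbind(major = c(1, 2, 2),
                                               minor = c(1, 1, 2)),
                       baseline_probs = c(0.65, 0.10, 0.25),
                       baseline_concentration = 30,
                       pga_range = c(0.10, 0.40),
                       pga_sd_frac = 0.5,
                       pga_min = 0.02,
                       deviant_states = .DEVIANT_STATES,
                       deviant_weights = .DEVIANT_WEIGHTS,
                       catalogue_size = 2000L,
                       catalogue_length_range = c(1e5, 2e8),
                       n_subclones = 4L,
                       divergence_mean = 0.15,
                       divergence_sd = 0.05,
                       divergence_min = 0.01,
                       length_match_tol = 0.25,
                       noise_sd = 0.02,
                       cellularities = c(0.2, 0.4, 0.6, 0.8)) {
  if (length(genome) != 22L || any(genome <= 0))
    .param_error("genome must give 22 positive autosome lengths")
  if (mean_segment_mb <= 0 || probes_per_bp <= 0 || templates_per_chrom < 1)
    .param_error("segmentation parameters must be positive")
  if (abs(sum(baseline_probs) - 1) > 1e-9 || any(baseline_probs < 0))
    .param_error("baseline_probs must be a probability vector")
  if (nrow(baseline_levels) != length(baseline_probs))
    .param_error("baseline_levels and baseline_probs disagree")
  if (pga_range[1] < 0 || pga_range[2] < pga_range[1])
    .param_error("invalid pga_range")
  if (length(deviant_weights) != nrow(deviant_states) || any(deviant_weights < 0))
    .param_error("deviant_weights must match deviant_states")
  if (any(cellularities <= 0 | cellularities > 1))
    .param_error("cellularities must lie in (0, 1]")
  structure(list(genome = genome, mean_segment_mb = mean_segment_mb,
                 probes_per_bp = probes_per_bp,
                 templates_per_chrom = as.integer(templates_per_chrom),
                 baseline_levels = baseline_levels,
                 baseline_probs = baseline_probs,
                 baseline_concentration = baseline_concentration,
                 pga_range = pga_range, pga_sd_frac = pga_sd_frac,
                 pga_min = pga_min,
                 deviant_states = deviant_states,
                 deviant_weights = deviant_weights / sum(deviant_weights),
                 catalogue_size = as.integer(catalogue_size),
                 catalogue_length_range = catalogue_length_range,
                 n_subclones = as.integer(n_subclones),
                 divergence_mean = divergence_mean,
                 divergence_sd = divergence_sd,
                 divergence_min = divergence_min,
                 length_match_tol = length_match_tol,
                 noise_sd = noise_sd, cellularities = cellularities),
            class = "sim_params")
}

# deterministic sub-seed derivation (Lehmer-style hash, stays below 2^31)
.substream <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (k in c(...)) s <- (s * 48271 + k + 1) %% 2147483647
  as.integer(s)
}

#' Per-set generative distributions
#'
#' Each "set" stands in for one cancer-type cohort and carries everything a
#' clone draw needs: baseline-state probabilities, moments of the percentage
#' of genome altered, per-chromosome segmentation templates (contiguous,
#' non-overlapping tilings of each autosome) and a catalogue of deviant
#' (state, length) entries.
#'
#' @param n_sets Number of sets to generate.
#' @param params A [sim_params] list.
#' @param seed Optional integer seed (set before any draw).
#' @return List of `set_distributions` objects.
#' @export
set_distributions <- function(n_sets = 16L, params = sim_params(), seed = NULL) {
  if (n_sets < 1L) .param_error("n_sets must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_sets), function(si) {
    g <- stats::rgamma(length(params$baseline_probs),
                       shape = params$baseline_concentration * params$baseline_probs)
    probs <- g / sum(g)
    pga_mean <- stats::runif(1, params$pga_range[1], params$pga_range[2])
    templates <- lapply(seq_along(params$genome), function(chr) {
      len <- params$genome[chr]
      lapply(seq_len(params$templates_per_chrom), function(t) {
        nb <- stats::rpois(1, max(0, len / (params$mean_segment_mb * 1e6) - 1))
        nb <- min(nb, len - 1)
        cuts <- if (nb > 0) sort(sample.int(len - 1L, nb)) else integer(0)
        diff(c(0, cuts, len))
      })
    })
    lr <- log(params$catalogue_length_range)
    idx <- sample.int(nrow(params$deviant_states), params$catalogue_size,
                      replace = TRUE, prob = params$deviant_weights)
    catalogue <- data.frame(major = params$deviant_states[idx, "major"],
                            minor = params$deviant_states[idx, "minor"],
                            length = exp(stats::runif(params$catalogue_size,
                                                      lr[1], lr[2])))
    structure(list(set_id = sprintf("set%02d", si),
                   baseline_levels = params$baseline_levels,
                   baseline_probs = probs,
                   pga_mean = pga_mean,
                   pga_sd = params$pga_sd_frac * pga_mean,
                   templates = templates,
                   catalogue = catalogue,
                   params = params),
              class = "set_distributions")
  })
}

# draw a catalogue state different from `exclude` with length within
# tol * L of L; the tolerance doubles (with a warning) until candidates exist
.draw_deviant <- function(catalogue, exclude_major, exclude_minor, L, tol) {
  differs <- catalogue$major != exclude_major | catalogue$minor != exclude_minor
  if (!any(differs))
    .param_error("deviant catalogue holds no state differing from the baseline")
  repeat {
    cand <- which(differs & abs(catalogue$length - L) <= tol * L)
    if (length(cand))
      return(cand[sample.int(length(cand), 1L)])
    if (tol > 1e6) .param_error("no length-matched deviant state found")
    tol <- tol * 2
    warning(sprintf("no deviant state within +/-%.0f%% of %.0f bp; tolerance doubled",
                    100 * tol / 2, L), call. = FALSE)
  }
}

# sample segments without replacement until their cumulative length exceeds
# 95% of the target fraction of the genome
.accumulate_segments <- function(len, target_fraction) {
  target <- 0.95 * target_fraction * sum(len)
  ord <- sample.int(length(len))
  cum <- cumsum(len[ord])
  k <- which(cum > target)[1L]
  if (is.na(k)) k <- length(len)
  ord[seq_len(k)]
}

#' Generate one clonal copy-number profile
#'
#' Draws a baseline state `B` from the set's baseline distribution and a
#' target altered fraction `P ~ Normal(pga_mean, pga_sd)` clamped to at least
#' `pga_min` (default 2%). The genome is segmented by picking one template
#' per chromosome (at random with replacement), every segment is set to `B`,
#' and segments are then sampled without replacement into the altered set
#' until their cumulative length exceeds 95% of `P` times the genome length.
#' Each altered segment receives a catalogue state different from `B` whose
#' length matches the segment's within +/-25% (tolerance doubled on failure).
#'
#' Uses the current RNG state; callers seed it.
#'
#' @param set_dist A `set_distributions` object.
#' @param clone_id Identifier for the clone.
#' @return A `clone_profile` list: `clone_id`, `baseline`, `p_target`,
#'   `segments` (with `major`/`minor`), `altered` (row indices) and
#'   `realised_pga`.
#' @export
generate_clone <- function(set_dist, clone_id = "clone1") {
  params <- set_dist$params
  bi <- sample.int(nrow(set_dist$baseline_levels), 1L,
                   prob = set_dist$baseline_probs)
  B <- set_dist$baseline_levels[bi, ]
  P <- max(params$pga_min, stats::rnorm(1, set_dist$pga_mean, set_dist$pga_sd))
  segs <- do.call(rbind, lapply(seq_along(params$genome), function(chr) {
    tmpl <- set_dist$templates[[chr]]
    lens <- tmpl[[sample.int(length(tmpl), 1L)]]
    ends <- cumsum(lens)
    data.frame(chromosome = chr, start_bp = c(1, utils::head(ends, -1L) + 1),
               end_bp = ends, length = lens,
               n_probes = pmax(1L, as.integer(round(lens * params$probes_per_bp))))
  }))
  rownames(segs) <- NULL
  segs$major <- rep(B[["major"]], nrow(segs))
  segs$minor <- rep(B[["minor"]], nrow(segs))
  altered <- .accumulate_segments(segs$length, P)
  for (s in altered) {
    j <- .draw_deviant(set_dist$catalogue, B[["major"]], B[["minor"]],
                       segs$length[s], params$length_match_tol)
    segs$major[s] <- set_dist$catalogue$major[j]
    segs$minor[s] <- set_dist$catalogue$minor[j]
  }
  structure(list(clone_id = clone_id, baseline = B, p_target = P,
                 segments = segs, altered = altered,
                 realised_pga = sum(segs$length[altered]) / sum(segs$length)),
            class = "clone_profile")
}

#' Derive subclones from an ancestor clone
#'
#' Each of `k` subclones shares the ancestor's segment boundaries. Its
#' divergence (genome fraction with a copy-number state different from the
#' ancestor's) is drawn from `Normal(divergence_mean, divergence_sd)` clamped
#' to at least `divergence_min` (defaults 15% +/- 5%, floor 1%), and the
#' divergent segment set is accumulated and re-assigned exactly as the
#' altered set of [generate_clone()] — states must differ from the ancestor's
#' state on each chosen segment and be length-matched within +/-25%.
#'
#' @param ancestor A `clone_profile`.
#' @param set_dist The `set_distributions` the ancestor came from.
#' @param k Number of subclones.
#' @param group_id Identifier for the resulting group.
#' @return A `clone_group` list: `profiles` (ancestor first, then `k`
#'   subclones), `divergences`, `divergent_sets`, shared `segments`.
#' @export
derive_subclones <- function(ancestor, set_dist, k = 4L, group_id = "group1") {
  params <- set_dist$params
  segs <- ancestor$segments
  subclones <- vector("list", k)
  divergences <- numeric(k)
  divergent_sets <- vector("list", k)
  for (j in seq_len(k)) {
    dv <- max(params$divergence_min,
              stats::rnorm(1, params$divergence_mean, params$divergence_sd))
    D <- .accumulate_segments(segs$length, dv)
    sub <- segs
    for (s in D) {
      jj <- .draw_deviant(set_dist$catalogue, segs$major[s], segs$minor[s],
                          segs$length[s], params$length_match_tol)
      sub$major[s] <- set_dist$catalogue$major[jj]
      sub$minor[s] <- set_dist$catalogue$minor[jj]
    }
    divergences[j] <- dv
    divergent_sets[[j]] <- D
    subclones[[j]] <- structure(
      list(clone_id = paste0(ancestor$clone_id, "_sub", j),
           baseline = ancestor$baseline, p_target = NA_real_,
           segments = sub, altered = D,
           realised_pga = sum(segs$length[D]) / sum(segs$length)),
      class = "clone_profile")
  }
  structure(list(group_id = group_id, set_id = set_dist$set_id,
                 profiles = c(list(ancestor), subclones),
                 divergences = divergences,
                 divergent_sets = divergent_sets,
                 segments = segs[, c("chromosome", "start_bp", "end_bp",
                                     "length", "n_probes")]),
            class = "clone_group")
}

#' @export
print.clone_group <- function(x, ...) {
  cat(sprintf("<clone_group> %s/%s: 1 ancestor + %d subclones, %d shared segments\n",
              x$set_id, x$group_id, length(x$profiles) - 1L, nrow(x$segments)))
  cat(sprintf("  divergences: %s\n", paste(sprintf("%.3f", x$divergences), collapse = ", ")))
  invisible(x)
}

#' Default clone-frequency assortments
#'
#' The frequency assortments applied to every clone combination of a given
#' size: 1 for singles, 3 for pairs, 4 each for sizes 3-5. Percentages sum
#' to 100 within each assortment.
#'
#' @return Named list (sizes "1".."5") of matrices, one assortment per row,
#'   entries as fractions summing to 1.
#' @export
default_assortments <- function() {
  list(`1` = matrix(1, 1, 1),
       `2` = rbind(c(50, 50), c(65, 35), c(80, 20)) / 100,
       `3` = rbind(c(45, 30, 25), c(34, 33, 33), c(50, 25, 25), c(60, 20, 20)) / 100,
       `4` = rbind(c(25, 25, 25, 25), c(40, 30, 20, 10), c(40, 20, 20, 20),
                   c(55, 15, 15, 15)) / 100,
       `5` = rbind(c(20, 20, 20, 20, 20), c(40, 15, 15, 15, 15),
                   c(30, 25, 20, 15, 10), c(50, 20, 10, 10, 10)) / 100)
}

# all ordered k-tuples of distinct elements of 1..n
.perms <- function(n, k) {
  out <- matrix(seq_len(n), ncol = 1)
  if (k == 1L) return(out)
  for (depth in 2:k) {
    pieces <- lapply(seq_len(nrow(out)), function(r) {
      rest <- setdiff(seq_len(n), out[r, ])
      cbind(matrix(out[r, ], length(rest), depth - 1L, byrow = TRUE), rest)
    })
    out <- do.call(rbind, pieces)
  }
  unname(out)
}

#' Enumerate mixture designs for one clone group
#'
#' Clone combinations are ordered (order-sensitive): all 5 singles, all 20
#' ordered pairs, all 60 ordered triples, and `n_random` (default 100)
#' distinct ordered 4-tuples and 5-tuples sampled uniformly without
#' replacement — 285 combinations in total. Each combination is crossed with
#' the frequency assortments of its size (1/3/4/4/4 by default), giving
#' 1,105 designs. Deterministic under a fixed RNG state.
#'
#' @param group A `clone_group` with 5 profiles.
#' @param assortments As [default_assortments()].
#' @param n_random Number of ordered 4- and 5-tuples sampled.
#' @return data.frame with `design_id`, `n_clones`, clone index columns
#'   `c1..c5`, frequency columns `f1..f5` (NA-padded) and `true_diversity`.
#' @export
enumerate_designs <- function(group = NULL, assortments = default_assortments(),
                              n_random = 100L) {
  n_clones_avail <- if (is.null(group)) 5L else length(group$profiles)
  if (n_clones_avail != 5L) .param_error("a clone group must hold 5 profiles")
  sizes <- as.character(1:5)
  if (!all(sizes %in% names(assortments)))
    .param_error("assortments must cover sizes 1 to 5")
  blocks <- list()
  for (k in 1:5) {
    all_perm <- .perms(5L, k)
    combos <- if (k >= 4L) {
      if (n_random > nrow(all_perm))
        .param_error("n_random exceeds the number of ordered tuples")
      all_perm[sample.int(nrow(all_perm), n_random), , drop = FALSE]
    } else all_perm
    fr <- assortments[[as.character(k)]]
    if (any(abs(rowSums(fr) - 1) > 1e-9))
      .param_error("assortment frequencies must sum to 1")
    for (a in seq_len(nrow(fr))) {
      cl <- matrix(NA_integer_, nrow(combos), 5L)
      cl[, seq_len(k)] <- combos
      f <- matrix(NA_real_, nrow(combos), 5L)
      f[, seq_len(k)] <- matrix(fr[a, ], nrow(combos), k, byrow = TRUE)
      blocks[[length(blocks) + 1L]] <-
        data.frame(n_clones = k, cl, f, true_diversity = .shannon(fr[a, ]))
    }
  }
  out <- do.call(rbind, blocks)
  names(out) <- c("n_clones", paste0("c", 1:5), paste0("f", 1:5), "true_diversity")
  out <- cbind(design_id = sprintf("d%04d", seq_len(nrow(out))), out)
  out$design_id <- as.character(out$design_id)
  rownames(out) <- NULL
  out
}

.as_design <- function(design) {
  if (is.data.frame(design)) {
    if (nrow(design) != 1L) .param_error("design must be a single design row")
    k <- design$n_clones
    list(clone_ids = as.integer(design[1, paste0("c", seq_len(k))]),
         frequencies = as.numeric(design[1, paste0("f", seq_len(k))]))
  } else {
    if (!all(c("clone_ids", "frequencies") %in% names(design)))
      .param_error("design needs clone_ids and frequencies")
    design
  }
}

#' Per-segment mixture allele copy numbers
#'
#' The frequency-weighted sum over clones of each allele's integer copy
#' number, per segment: a real-valued (N_major, N_minor) pair.
#'
#' @param design A design row from [enumerate_designs()] or a list with
#'   `clone_ids` (indices into the group's profiles) and `frequencies`.
#' @param group A `clone_group`.
#' @return List with numeric vectors `Na` (major-allele mix) and `Nb`
#'   (minor-allele mix), one entry per segment.
#' @export
mixture_allele_cn <- function(design, group) {
  d <- .as_design(design)
  if (length(d$clone_ids) != length(d$frequencies))
    .param_error("clone_ids and frequencies lengths differ")
  if (abs(sum(d$frequencies) - 1) > 1e-9)
    .param_error("frequencies must sum to 1")
  if (any(d$clone_ids < 1L | d$clone_ids > length(group$profiles)))
    .param_error("clone_ids outside the group")
  M <- vapply(group$profiles, function(p) as.numeric(p$segments$major),
              numeric(nrow(group$segments)))
  m <- vapply(group$profiles, function(p) as.numeric(p$segments$minor),
              numeric(nrow(group$segments)))
  list(Na = drop(M[, d$clone_ids, drop = FALSE] %*% d$frequencies),
       Nb = drop(m[, d$clone_ids, drop = FALSE] %*% d$frequencies))
}

# round half away from zero (values here are non-negative)
.round_half_away <- function(v) sign(v) * floor(abs(v) + 0.5)

#' Rounded integer copy numbers of a mixture
#'
#' Each allele's real-valued mixture copy number is rounded independently to
#' the nearest integer (halves away from zero), then the pair is
#' order-normalised to major >= minor — emulating the integer output of an
#' allele-specific caller on the mixed sample.
#'
#' @inheritParams mixture_allele_cn
#' @return List with integer vectors `major`, `minor`.
#' @export
rounded_cn <- function(design, group) {
  mix <- mixture_allele_cn(design, group)
  a <- .round_half_away(mix$Na)
  b <- .round_half_away(mix$Nb)
  list(major = as.integer(pmax(a, b)), minor = as.integer(pmin(a, b)))
}

#' Shannon diversity of a frequency vector
#'
#' The true diversity of a mixture: `-sum(f_i * ln(f_i))` over the clone
#' frequencies.
#'
#' @param frequencies Positive fractions summing to 1 (within `1e-9`).
#' @return Non-negative entropy in nats.
#' @export
true_diversity <- function(frequencies) {
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    .param_error("frequencies must be positive")
  if (abs(sum(frequencies) - 1) > 1e-9)
    .param_error("frequencies must sum to 1")
  .shannon(frequencies)
}

# noiseless logR / mBAF of a mixture at cellularity C:
#   L(s)  = log2(((Na + Nb) C + 2 (1 - C)) / 2)
#   mB(s) = 0.5 + |0.5 - (Nb C + (1 - C)) / ((Na + Nb) C + 2 (1 - C))|
# with the uncorrected ratio Nb / (Na + Nb) set to 0.5 when Na = Nb = 0
# (bi-allelic loss of the whole segment).
.signal_kernel <- function(Na, Nb, C) {
  tot <- Na + Nb
  denom <- tot * C + 2 * (1 - C)
  L <- log2(denom / 2)
  ratio <- (Nb * C + (1 - C)) / denom
  ratio[tot == 0] <- 0.5
  list(L = L, mB = 0.5 + abs(0.5 - ratio))
}

#' Synthesise the SNP-array signal of a mixture
#'
#' Computes the noiseless per-segment logR and mirrored BAF of the mixture at
#' cellularity `C`, with the contaminating normal fraction `1 - C`
#' contributing two balanced copies, then adds independent Gaussian noise
#' (sd `noise_sd`) to each channel. Noisy mBAF is neither re-mirrored nor
#' clamped; the scores unit-normalise afterwards. Uses the current RNG state.
#'
#' @inheritParams mixture_allele_cn
#' @param cellularity Tumour-cell fraction `C` in `(0, 1]`.
#' @param noise_sd Gaussian noise sd (default 0.02); set 0 for noiseless.
#' @return A `mixture_signal` list: `Na`, `Nb`, noiseless `L0`/`mB0`, noisy
#'   `logR`/`mbaf`, rounded `major`/`minor`, `cellularity`, `true_diversity`.
#' @export
synthesize_signal <- function(design, group, cellularity, noise_sd = 0.02) {
  if (!is.finite(cellularity) || cellularity <= 0 || cellularity > 1)
    .param_error("cellularity must lie in (0, 1]")
  d <- .as_design(design)
  mix <- mixture_allele_cn(d, group)
  sg <- .signal_kernel(mix$Na, mix$Nb, cellularity)
  n <- length(sg$L)
  rc <- rounded_cn(d, group)
  structure(list(Na = mix$Na, Nb = mix$Nb, L0 = sg$L, mB0 = sg$mB,
                 logR = sg$L + stats::rnorm(n, 0, noise_sd),
                 mbaf = sg$mB + stats::rnorm(n, 0, noise_sd),
                 major = rc$major, minor = rc$minor,
                 cellularity = cellularity,
                 true_diversity = true_diversity(d$frequencies)),
            class = "mixture_signal")
}

#' Render a mixture signal as a segmented profile
#'
#' @param signal A `mixture_signal`.
#' @param group The `clone_group` the signal was synthesised from.
#' @param sample_id Sample identifier for the resulting profile.
#' @return A [snp_profile] in the mirrored-BAF dialect, carrying the rounded
#'   integer CN.
#' @export
signal_as_profile <- function(signal, group, sample_id) {
  seg <- group$segments
  snp_profile(sample_id,
              data.frame(chromosome = seg$chromosome, start_bp = seg$start_bp,
                         end_bp = seg$end_bp, n_probes = seg$n_probes,
                         logR = signal$logR, baf = signal$mbaf,
                         major_cn = signal$major, minor_cn = signal$minor),
              mirrored = TRUE)
}
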