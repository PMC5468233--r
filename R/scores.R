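# The S (entropy) and R (spatial homogeneity) diversity scores, plus baseline
# copy number and percentage of genome altered.

#' Scoring parameters
#'
#' @param n_bins Number of equally sized logR bins for the S score
#'   (definitional default 10; 12 is the calibrated recommendation for real
#'   data).
#' @param r_max Maximum radius of the Ripley's L grid, on the unit-normalised
#'   logR/mBAF plane (default 0.05).
#' @param r_step Radius increment (default 0.001). The grid includes both
#'   endpoints, `0` and `r_max`.
#' @param min_probes Minimum number of probes for a segment to enter either
#'   score (default 100).
#' @return A `score_params` list.
#' @export
score_params <- function(n_bins = 10L, r_max = 0.05, r_step = 0.001,
                         min_probes = 100L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) .param_error("n_bins must be an integer >= 2")
  if (!is.finite(r_max) || r_max <= 0) .param_error("r_max must be > 0")
  if (!is.finite(r_step) || r_step <= 0) .param_error("r_step must be > 0")
  if (r_step > r_max) .param_error("r_step must be <= r_max")
  min_probes <- as.integer(min_probes)
  if (is.na(min_probes) || min_probes < 1L) .param_error("min_probes must be >= 1")
  structure(list(n_bins = n_bins, r_max = r_max, r_step = r_step,
                 min_probes = min_probes), class = "score_params")
}

.r_grid <- function(params) seq(0, params$r_max, by = params$r_step)

#' Drop short segments before scoring
#'
#' Short segments carry less reliable logR/BAF estimates; only segments with
#' `min_probes` probes or more are taken into account by the diversity scores.
#'
#' @param profile A [snp_profile].
#' @param min_probes Minimum probe count (default 100). Segments with
#'   `n_probes >= min_probes` are retained, order preserved.
#' @return A `snp_profile` (possibly with zero segments; downstream scores
#'   raise an unscorable error in that case).
#' @export
filter_segments <- function(profile, min_probes = 100L) {
  stopifnot(inherits(profile, "snp_profile"))
  keep <- profile$segments$n_probes >= min_probes
  out <- profile
  out$segments <- profile$segments[keep, , drop = FALSE]
  rownames(out$segments) <- NULL
  out
}

#' Mirror B-allele frequencies about 0.5
#'
#' Removes the arbitrary A/B allele labelling by reflecting BAF into
#' `[0.5, 1]`: `mBAF = 0.5 + |0.5 - BAF|`. Idempotent.
#'
#' @param baf Numeric vector in `[0, 1]`.
#' @return Numeric vector in `[0.5, 1]`.
#' @export
mirror_baf <- function(baf) {
  if (any(!is.finite(baf)) || any(baf < 0 | baf > 1))
    .param_error("BAF values must lie in [0, 1]")
  0.5 + abs(0.5 - baf)
}

#' Linearly rescale values to the unit interval
#'
#' Maps `v` to `(v - min) / (max - min)`. When all values are equal the range
#' is degenerate and every output is set to 0.5, which keeps the point pattern
#' defined.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
unit_normalise <- function(values) {
  if (length(values) == 0L) .param_error("unit_normalise needs at least one value")
  if (any(!is.finite(values))) .param_error("values must be finite")
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(values)))
  (values - rng[1L]) / (rng[2L] - rng[1L])
}

# Bin proportions over the observed range; left-closed/right-open bins, top
# edge closed so max(v) lands in bin n. Returns counts/total, unweighted by
# segment length.
.bin_props <- function(v, n_bins) {
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    p <- numeric(n_bins)
    p[1L] <- 1
    return(p)
  }
  w <- (rng[2L] - rng[1L]) / n_bins
  idx <- pmin(floor((v - rng[1L]) / w), n_bins - 1L)
  tabulate(idx + 1L, nbins = n_bins) / length(v)
}

#' Histogram proportions of segmented logR values
#'
#' Groups values into `n_bins` equally sized bins spanning the observed
#' `[min, max]` range, so the bin width is `(max - min) / n_bins` and the
#' lowest bin starts at the observed minimum. Bins are left-closed/right-open
#' with the top edge closed; proportions count segments (not base pairs).
#'
#' @param logR_values Non-empty numeric vector.
#' @param n_bins Integer `>= 2`.
#' @return A `bin_histogram` list with `n`, `edges` (length `n + 1`) and
#'   `proportions` (summing to 1).
#' @export
bin_proportions <- function(logR_values, n_bins) {
  if (length(logR_values) == 0L) .param_error("need at least one value")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) .param_error("n_bins must be an integer >= 2")
  rng <- range(logR_values)
  structure(list(n = n_bins,
                 edges = seq(rng[1L], rng[2L], length.out = n_bins + 1L),
                 proportions = .bin_props(logR_values, n_bins)),
            class = "bin_histogram")
}

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon diversity index
#'
#' `-sum(p_i * ln(p_i))` over the positive proportions; zero proportions
#' contribute nothing. Used both for the S score (logR bin proportions) and
#' for the true diversity of simulated clone mixtures (clone frequencies).
#'
#' @param proportions Non-negative proportions summing to 1 (within `1e-9`).
#' @return Non-negative entropy in nats.
#' @export
shannon_index <- function(proportions) {
  if (any(!is.finite(proportions)) || any(proportions < 0))
    .param_error("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9)
    .param_error("proportions must sum to 1")
  .shannon(proportions)
}

#' The S score: entropy of binned segmented logR
#'
#' Segments sharing a copy-number state share a logR value, so the logR
#' distribution of a clonal genome is concentrated in a few peaks; subclonal
#' alterations create outliers and raise the entropy. S is the Shannon index
#' of the proportions of retained segments per logR bin and lies in
#' `[0, ln(n_bins)]`.
#'
#' @param profile A [snp_profile].
#' @param params A [score_params] list.
#' @return Non-negative entropy in nats.
#' @export
s_score <- function(profile, params = score_params()) {
  f <- filter_segments(profile, params$min_probes)
  v <- f$segments$logR
  if (length(v) < 1L)
    .unscorable(sprintf("sample %s: no segments pass the %d-probe filter",
                        profile$sample_id, params$min_probes))
  shannon_index(.bin_props(v, params$n_bins))
}

.profile_pattern <- function(profile, params) {
  f <- filter_segments(profile, params$min_probes)
  s <- f$segments
  if (nrow(s) < 2L)
    .unscorable(sprintf("sample %s: fewer than 2 segments pass the %d-probe filter",
                        profile$sample_id, params$min_probes))
  mb <- if (isTRUE(attr(profile, "mirrored"))) s$baf else mirror_baf(s$baf)
  point_pattern(unit_normalise(s$logR), unit_normalise(mb))
}

#' The R score: summed Ripley's L deviations
#'
#' Each retained segment becomes a point with x the unit-normalised logR and
#' y the unit-normalised mirrored BAF. On this unit-square pattern the score
#' is `R = sum over r in {0, r_step, ..., r_max} of (L(r) - r)` with signed
#' differences. Clonal genomes produce tight clusters (L above its random
#' expectation r, positive R); subclonal outliers scatter the pattern and
#' lower R, so R decreases as diversity increases.
#'
#' @inheritParams s_score
#' @return The summed signed deviation (any sign).
#' @export
r_score <- function(profile, params = score_params()) {
  pp <- .profile_pattern(profile, params)
  .r_kernel(pp$x, pp$y, .r_grid(params))
}

.order_states <- function(major, minor) {
  cbind(major = pmax(major, minor), minor = pmin(major, minor))
}

.baseline_kernel <- function(major, minor, len) {
  st <- .order_states(major, minor)
  code <- st[, 1L] * 100000 + st[, 2L]
  bp <- rowsum(len, code)
  codes <- as.numeric(rownames(bp))
  cand <- which(bp[, 1L] == max(bp[, 1L]))
  if (length(cand) > 1L) {
    M <- codes[cand] %/% 100000
    m <- codes[cand] %% 100000
    cand <- cand[order(M + m, M)][1L]
  }
  code_best <- codes[cand]
  c(major = code_best %/% 100000, minor = code_best %% 100000)
}

.check_cn <- function(profile) {
  s <- profile$segments
  if (any(is.na(s$major_cn)) || any(is.na(s$minor_cn)))
    .param_error(sprintf("sample %s: integer allele-specific CN is required",
                         profile$sample_id))
  invisible(s)
}

#' Baseline (modal) allele-specific copy-number state
#'
#' The baseline is the ordered (major, minor) state covering the greatest
#' total number of base pairs. Ties are broken towards the smaller total copy
#' number, then the smaller major copy number. States are order-normalised to
#' major >= minor before tallying.
#'
#' @param profile A [snp_profile] whose segments all carry integer CN.
#' @return Named integer vector `c(major, minor)`.
#' @export
baseline_cn <- function(profile) {
  s <- .check_cn(profile)
  b <- .baseline_kernel(s$major_cn, s$minor_cn, .segment_lengths(profile))
  c(major = as.integer(b[["major"]]), minor = as.integer(b[["minor"]]))
}

.pga_kernel <- function(major, minor, len) {
  st <- .order_states(major, minor)
  b <- .baseline_kernel(major, minor, len)
  sum(len[st[, 1L] != b[["major"]] | st[, 2L] != b[["minor"]]]) / sum(len)
}

#' Percentage of genome altered
#'
#' The base-pair fraction of the covered genome whose allele-specific
#' (major, minor) state differs from the baseline state of [baseline_cn()].
#' The mismatch is allele-specific: a segment whose total copy number matches
#' the baseline but whose allelic split differs counts as altered.
#'
#' @inheritParams baseline_cn
#' @return Fraction in `[0, 1]`.
#' @export
pct_genome_altered <- function(profile) {
  s <- .check_cn(profile)
  .pga_kernel(s$major_cn, s$minor_cn, .segment_lengths(profile))
}

#' Score one profile
#'
#' Computes the full panel (S, R, percentage of genome altered) for a single
#' sample. `pga` is `NA` when the profile carries no integer CN.
#'
#' @inheritParams s_score
#' @return A `score_panel` list with `sample_id`, `S`, `R`, `pga`,
#'   `n_segments_used` and the `params` used.
#' @export
score_profile <- function(profile, params = score_params()) {
  f <- filter_segments(profile, params$min_probes)
  pga <- if (all(!is.na(profile$segments$major_cn)) &&
             all(!is.na(profile$segments$minor_cn)))
    pct_genome_altered(profile) else NA_real_
  structure(list(sample_id = profile$sample_id,
                 S = s_score(profile, params),
                 R = r_score(profile, params),
                 pga = pga,
                 n_segments_used = nrow(f$segments),
                 params = params),
            class = "score_panel")
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf("<score_panel> %s: S = %.4f, R = %.4f, pga = %s (%d segments, %d bins, r_max %.3f)\n",
              x$sample_id, x$S, x$R,
              if (is.na(x$pga)) "NA" else sprintf("%.3f", x$pga),
              x$n_segments_used, x$params$n_bins, x$params$r_max))
  invisible(x)
}

#' Score a batch of profiles
#'
#' Per-sample failures (e.g. fewer than two segments passing the probe
#' filter) never abort the batch: the affected sample gets `NA` scores and
#' the failure message in the `reason` column.
#'
#' @param profiles List of [snp_profile] objects.
#' @param params A [score_params] list.
#' @return A data.frame of class `ith_scores` with one row per sample:
#'   `sample_id`, `S`, `R`, `pga`, `n_segments_used`, `reason`.
#' @export
score_profiles <- function(profiles, params = score_params()) {
  if (inherits(profiles, "snp_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    res <- tryCatch(score_profile(p, params),
                    snpdiv_unscorable = function(e) e)
    if (inherits(res, "condition"))
      data.frame(sample_id = p$sample_id, S = NA_real_, R = NA_real_,
                 pga = NA_real_,
                 n_segments_used = nrow(filter_segments(p, params$min_probes)$segments),
                 reason = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(sample_id = res$sample_id, S = res$S, R = res$R, pga = res$pga,
                 n_segments_used = res$n_segments_used, reason = NA_character_,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("ith_scores", "data.frame")
  out
}
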