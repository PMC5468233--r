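# End-to-end synthetic benchmark: sets -> clone groups -> designs ->
# rendered mixtures -> score panel rows.

#' Simulate and score a synthetic mixture cohort
#'
#' Runs the full generative pipeline: per-set distributions, `n_groups`
#' clone groups per set (1 ancestor + 4 subclones), 1,105 mixture designs per
#' group (285 ordered clone combinations crossed with the frequency
#' assortments), rendered at every requested cellularity with Gaussian
#' channel noise, then scored (S, R and percentage of genome altered from
#' the rounded integer CN). Every stochastic stage consumes a named
#' sub-stream of `seed`, so any run is exactly reproducible.
#'
#' @param seed Integer master seed.
#' @param n_sets,n_groups Cohort dimensions (defaults 16 sets x 10 groups).
#' @param params A [sim_params] list (noise sd, cellularities, generator
#'   settings).
#' @param score A [score_params] list used to score every mixture.
#' @param cellularities Cellularity grid (defaults to `params$cellularities`).
#' @param n_random_combos Ordered 4-/5-tuples sampled per group (default 100).
#' @param keep_signals Keep the per-mixture noisy logR/mBAF vectors (needed
#'   by [calibration_sweep()]; memory-heavy at full scale).
#' @param progress Print one line per set.
#' @return An `ith_cohort` list: `rows` (one data.frame row per mixture:
#'   `set_id`, `group_id`, `design_id`, `n_clones`, `cellularity`,
#'   `true_diversity`, `S`, `R`, `pga`), `sets`, `groups`, `designs` (one
#'   data.frame per group), optional `signals`, and the parameters used.
#' @export
simulate_cohort <- function(seed, n_sets = 16L, n_groups = 10L,
                            params = sim_params(), score = score_params(),
                            cellularities = params$cellularities,
                            n_random_combos = 100L,
                            keep_signals = FALSE, progress = FALSE) {
  sets <- set_distributions(n_sets, params, seed = .substream(seed, 1))
  r_grid <- .r_grid(score)
  nC <- length(cellularities)

  groups <- list()
  designs <- list()
  row_chunks <- list()
  signals <- if (keep_signals) list() else NULL

  for (si in seq_len(n_sets)) {
    sd_ <- sets[[si]]
    for (gi in seq_len(n_groups)) {
      set.seed(.substream(seed, 2, si * 1000 + gi))
      anc <- generate_clone(sd_, clone_id = sprintf("%s_g%02d_c1", sd_$set_id, gi))
      grp <- derive_subclones(anc, sd_, k = params$n_subclones,
                              group_id = sprintf("g%02d", gi))
      set.seed(.substream(seed, 3, si * 1000 + gi))
      des <- enumerate_designs(grp, n_random = n_random_combos)

      seg <- grp$segments
      keep <- seg$n_probes >= score$min_probes
      len <- seg$length
      M <- vapply(grp$profiles, function(p) as.numeric(p$segments$major),
                  numeric(nrow(seg)))
      m <- vapply(grp$profiles, function(p) as.numeric(p$segments$minor),
                  numeric(nrow(seg)))

      nd <- nrow(des)
      S <- R <- pga <- matrix(NA_real_, nd, nC)
      set.seed(.substream(seed, 4, si * 1000 + gi))
      for (di in seq_len(nd)) {
        k <- des$n_clones[di]
        ids <- as.integer(des[di, paste0("c", seq_len(k))])
        f <- as.numeric(des[di, paste0("f", seq_len(k))])
        Na <- drop(M[, ids, drop = FALSE] %*% f)
        Nb <- drop(m[, ids, drop = FALSE] %*% f)
        a <- .round_half_away(Na); b <- .round_half_away(Nb)
        pga_d <- .pga_kernel(pmax(a, b), pmin(a, b), len)
        for (ci in seq_len(nC)) {
          sg <- .signal_kernel(Na, Nb, cellularities[ci])
          n <- length(sg$L)
          logr <- sg$L + stats::rnorm(n, 0, params$noise_sd)
          mbaf <- sg$mB + stats::rnorm(n, 0, params$noise_sd)
          lr_k <- logr[keep]; mb_k <- mbaf[keep]
          if (length(lr_k) >= 1L)
            S[di, ci] <- .shannon(.bin_props(lr_k, score$n_bins))
          if (length(lr_k) >= 2L)
            R[di, ci] <- .r_kernel(unit_normalise(lr_k), unit_normalise(mb_k),
                                   r_grid)
          pga[di, ci] <- pga_d
          if (keep_signals)
            signals[[length(signals) + 1L]] <-
              list(set = si, group = gi, design = di,
                   cellularity = cellularities[ci], logR = logr, mbaf = mbaf)
        }
      }
      gkey <- sprintf("%s_%s", sd_$set_id, grp$group_id)
      groups[[gkey]] <- grp
      designs[[gkey]] <- des
      row_chunks[[gkey]] <- data.frame(
        set_id = sd_$set_id, group_id = grp$group_id,
        design_id = rep(des$design_id, each = nC),
        n_clones = rep(des$n_clones, each = nC),
        cellularity = rep(cellularities, nd),
        true_diversity = rep(des$true_diversity, each = nC),
        S = as.vector(t(S)), R = as.vector(t(R)), pga = as.vector(t(pga)),
        stringsAsFactors = FALSE)
    }
    if (progress)
      message(sprintf("set %d/%d done (%d groups x %d designs x %d cellularities)",
                      si, n_sets, n_groups, nrow(designs[[length(designs)]]), nC))
  }
  rows <- do.call(rbind, row_chunks)
  rownames(rows) <- NULL
  structure(list(rows = rows, sets = sets, groups = groups, designs = designs,
                 signals = signals, seed = seed, params = params,
                 score = score, cellularities = cellularities),
            class = "ith_cohort")
}

#' @export
print.ith_cohort <- function(x, ...) {
  cat(sprintf("<ith_cohort> %d sets x %d groups, %d mixtures (seed %d)\n",
              length(x$sets), length(x$groups) / max(1L, length(x$sets)),
              nrow(x$rows), x$seed))
  cat(sprintf("  cellularities: %s; %d bins, r_max %.3f, noise sd %.3f\n",
              paste(x$cellularities, collapse = ", "), x$score$n_bins,
              x$score$r_max, x$params$noise_sd))
  invisible(x)
}
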