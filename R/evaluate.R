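# Benchmark analyses: score-vs-true-diversity regressions, monoclonal vs
# polyclonal ROC/AUC, and the bin/radius calibration sweep.

.check_rows <- function(rows, score) {
  need <- c("n_clones", "true_diversity", score)
  miss <- setdiff(need, names(rows))
  if (length(miss))
    .param_error(paste0("benchmark rows lack column(s): ", paste(miss, collapse = ", ")))
  rows[is.finite(rows[[score]]), , drop = FALSE]
}

# closed-form OLS of y on x with R^2 and the regression F-test p-value
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  if (sxx == 0) .param_error("true diversity is constant; cannot fit")
  slope <- sxy / sxx
  r2 <- if (syy == 0) 0 else sxy^2 / (sxx * syy)
  p <- if (n > 2 && r2 < 1) {
    f <- r2 / (1 - r2) * (n - 2)
    stats::pf(f, 1, n - 2, lower.tail = FALSE)
  } else if (r2 >= 1) 0 else NA_real_
  list(slope = slope, intercept = my - slope * mx, r_squared = r2,
       p_value = p, n_points = n)
}

#' Linear fit of a score against true diversity
#'
#' Ordinary least squares of the score on the true Shannon diversity of the
#' mixtures. In `medians` mode rows are grouped by true-diversity level
#' (values rounded to 6 decimals) and the per-level medians are fitted — the
#' headline benchmark regression; `all_points` fits every mixture and is
#' expected to be much weaker because within-level spread is large.
#'
#' @param rows Benchmark rows (as `simulate_cohort()$rows`): needs
#'   `true_diversity` and the score column.
#' @param score `"S"`, `"R"` or `"pga"`.
#' @param mode `"medians"` or `"all_points"`.
#' @return An `ith_fit` list: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_points`, `mode`, `score`.
#' @export
median_fit <- function(rows, score = c("S", "R", "pga"),
                       mode = c("medians", "all_points")) {
  score <- match.arg(score)
  mode <- match.arg(mode)
  rows <- .check_rows(rows, score)
  if (mode == "medians") {
    lev <- factor(round(rows$true_diversity, 6))   # grouping only
    if (nlevels(lev) < 3L) .param_error("medians mode needs >= 3 diversity levels")
    x <- as.numeric(tapply(rows$true_diversity, lev, stats::median))
    y <- as.numeric(tapply(rows[[score]], lev, stats::median))
    ord <- order(x)
    x <- x[ord]
    y <- y[ord]
  } else {
    if (nrow(rows) < 3L) .param_error("all_points mode needs >= 3 rows")
    x <- rows$true_diversity
    y <- rows[[score]]
  }
  fit <- .ols(x, y)
  structure(c(fit, list(mode = mode, score = score)), class = "ith_fit")
}

#' @export
print.ith_fit <- function(x, ...) {
  cat(sprintf("<ith_fit> %s ~ true diversity (%s, n = %d): slope %.4f, R^2 %.4f, p %.3g\n",
              x$score, x$mode, x$n_points, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

# Mann-Whitney AUC of `values` for predicting `positive`; ties count 0.5.
.auc <- function(values, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) .param_error("both classes must be present")
  r <- rank(values)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' AUC for detecting polyclonal mixtures
#'
#' Area under the ROC curve of a score for classifying mixtures as
#' polyclonal (2 clones or more) versus monoclonal, via the Mann-Whitney
#' identity with ties counted 0.5. Orientation is fixed by the expected
#' direction of each score: S and the percentage of genome altered are used
#' as-is (higher predicts polyclonal) while R is negated (lower R predicts
#' polyclonal).
#'
#' @param rows Benchmark rows: needs `n_clones` and the score column.
#' @param score `"S"`, `"R"` or `"pga"`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(rows, score = c("S", "R", "pga")) {
  score <- match.arg(score)
  rows <- .check_rows(rows, score)
  v <- rows[[score]]
  if (score == "R") v <- -v
  .auc(v, rows$n_clones >= 2L)
}

#' Summarise a benchmark cohort
#'
#' Computes, per set: the polyclonal-vs-monoclonal AUC of each score within
#' each cellularity stratum and with all cellularities pooled
#' (stratum `"all"`); the medians of the per-set AUCs; and the median-mode
#' and all-points regressions of each score on the true diversity per
#' stratum. Cells where a class is missing are dropped with a recorded note.
#'
#' @param rows Benchmark rows (as `simulate_cohort()$rows`).
#' @param scores Score columns to analyse.
#' @return An `ith_benchmark` list: `auc`, `auc_medians`, `fits`, `notes`.
#' @export
benchmark_scores <- function(rows, scores = c("S", "R", "pga")) {
  strata <- c(as.character(sort(unique(rows$cellularity))), "all")
  sets <- sort(unique(rows$set_id))
  notes <- character(0)
  auc_rows <- list()
  for (sc in scores) for (st in strata) for (se in sets) {
    in_stratum <- if (st == "all") TRUE else rows$cellularity == as.numeric(st)
    sub <- rows[rows$set_id == se & in_stratum, , drop = FALSE]
    res <- tryCatch(roc_auc(sub, sc), snpdiv_param_error = function(e) e)
    if (inherits(res, "condition")) {
      notes <- c(notes, sprintf("AUC skipped for set %s, score %s, stratum %s: %s",
                                se, sc, st, conditionMessage(res)))
      next
    }
    auc_rows[[length(auc_rows) + 1L]] <-
      data.frame(set_id = se, score = sc, stratum = st, auc = res,
                 n_mono = sum(sub$n_clones == 1L),
                 n_poly = sum(sub$n_clones >= 2L), stringsAsFactors = FALSE)
  }
  auc <- do.call(rbind, auc_rows)
  auc_medians <- if (!is.null(auc))
    stats::aggregate(auc ~ score + stratum, data = auc, FUN = stats::median)
  else NULL
  fit_rows <- list()
  for (sc in scores) for (st in strata) for (md in c("medians", "all_points")) {
    in_stratum <- if (st == "all") TRUE else rows$cellularity == as.numeric(st)
    sub <- rows[in_stratum, , drop = FALSE]
    res <- tryCatch(median_fit(sub, sc, md), snpdiv_param_error = function(e) e)
    if (inherits(res, "condition")) {
      notes <- c(notes, sprintf("fit skipped for score %s, stratum %s (%s): %s",
                                sc, st, md, conditionMessage(res)))
      next
    }
    fit_rows[[length(fit_rows) + 1L]] <-
      data.frame(score = sc, stratum = st, mode = md, slope = res$slope,
                 intercept = res$intercept, r_squared = res$r_squared,
                 p_value = res$p_value, n_points = res$n_points,
                 stringsAsFactors = FALSE)
  }
  if (length(notes)) message(paste(notes, collapse = "\n"))
  structure(list(auc = auc,
                 auc_medians = auc_medians,
                 fits = do.call(rbind, fit_rows),
                 notes = notes),
            class = "ith_benchmark")
}

#' @export
print.ith_benchmark <- function(x, ...) {
  cat("<ith_benchmark>\n")
  if (!is.null(x$auc_medians)) {
    cat("median per-set AUC (polyclonal vs monoclonal):\n")
    print(x$auc_medians, row.names = FALSE)
  }
  if (!is.null(x$fits)) {
    cat("median-mode fits vs true diversity:\n")
    print(x$fits[x$fits$mode == "medians",
                 c("score", "stratum", "slope", "r_squared", "p_value")],
          row.names = FALSE)
  }
  if (length(x$notes)) cat(length(x$notes), "cell(s) skipped\n")
  invisible(x)
}

#' @export
plot.ith_benchmark <- function(x, ...) {
  if (is.null(x$auc)) {
    warning("no AUC rows to plot")
    return(invisible(x))
  }
  a <- x$auc
  a$grp <- paste(a$score, a$stratum)
  graphics::boxplot(auc ~ grp, data = a, las = 2, ylab = "AUC",
                    main = "Per-set polyclonality AUC by score and cellularity",
                    cex.axis = 0.7, ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}

#' Bin / radius calibration sweep
#'
#' Re-scores every stored mixture of a cohort at each value of the bin grid
#' (S score) and each maximum radius of the radius grid (R score), and
#' reports for each grid value the median-mode regression against the true
#' diversity and the pooled polyclonality AUC. The cohort must have been
#' simulated with `keep_signals = TRUE`.
#'
#' @param cohort An `ith_cohort` from [simulate_cohort()] with signals kept.
#' @param bin_grid Bin counts for the S sweep (default 6 to 24 by 2).
#' @param radius_grid Maximum radii for the R sweep (default the 7 values
#'   0.025 to 0.25).
#' @return data.frame with one row per (parameter, value): `score`,
#'   `parameter`, `value`, `slope_medians`, `r_squared_medians`, `auc_pooled`.
#' @export
calibration_sweep <- function(cohort,
                              bin_grid = seq(6L, 24L, by = 2L),
                              radius_grid = c(0.025, 0.05, 0.075, 0.1, 0.15,
                                              0.2, 0.25)) {
  if (!inherits(cohort, "ith_cohort") || is.null(cohort$signals))
    .param_error("calibration_sweep needs a cohort simulated with keep_signals = TRUE")
  if (!length(bin_grid) || !length(radius_grid))
    .param_error("grids must be non-empty")
  sig <- cohort$signals
  meta <- cohort$rows
  if (length(sig) != nrow(meta))
    .param_error("signals and rows are out of step")
  keep_of_group <- lapply(cohort$groups, function(g)
    g$segments$n_probes >= cohort$score$min_probes)
  gkey <- sprintf("%s_%s", meta$set_id, meta$group_id)
  out <- list()
  rescore <- function(fun) {
    vapply(seq_along(sig), function(i) {
      keep <- keep_of_group[[gkey[i]]]
      fun(sig[[i]]$logR[keep], sig[[i]]$mbaf[keep])
    }, numeric(1))
  }
  for (b in bin_grid) {
    v <- rescore(function(lr, mb) .shannon(.bin_props(lr, b)))
    rows2 <- meta; rows2$S <- v
    fit <- median_fit(rows2, "S", "medians")
    out[[length(out) + 1L]] <- data.frame(
      score = "S", parameter = "n_bins", value = b, slope_medians = fit$slope,
      r_squared_medians = fit$r_squared, auc_pooled = roc_auc(rows2, "S"),
      stringsAsFactors = FALSE)
  }
  for (rmax in radius_grid) {
    grid <- seq(0, rmax, by = cohort$score$r_step)
    v <- rescore(function(lr, mb)
      .r_kernel(unit_normalise(lr), unit_normalise(mb), grid))
    rows2 <- meta; rows2$R <- v
    fit <- median_fit(rows2, "R", "medians")
    out[[length(out) + 1L]] <- data.frame(
      score = "R", parameter = "r_max", value = rmax, slope_medians = fit$slope,
      r_squared_medians = fit$r_squared, auc_pooled = roc_auc(rows2, "R"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
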