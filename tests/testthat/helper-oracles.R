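# Independent oracles, deliberately sharing no code with the package.

# Fraction of the circle centred at (cx, cy), radius r, lying inside the unit
# square: collect every angle where a window side can cut the circle, then
# classify the midpoint of each angular piece by a point-in-rectangle test.
oracle_inside_frac <- function(cx, cy, r) {
  if (r == 0) return(1)
  ang <- c(0, 2 * pi)
  add_cut <- function(centre, dd) {
    if (dd < r) ang <<- c(ang, centre + c(-1, 1) * acos(dd / r))
    invisible(NULL)
  }
  add_cut(pi, cx)           # left side x = 0
  add_cut(0, 1 - cx)        # right side x = 1
  add_cut(3 * pi / 2, cy)   # bottom y = 0
  add_cut(pi / 2, 1 - cy)   # top y = 1
  ang <- sort(unique(ang %% (2 * pi)))
  ang <- c(ang, ang[1] + 2 * pi)
  inside <- 0
  for (k in seq_len(length(ang) - 1)) {
    mid <- (ang[k] + ang[k + 1]) / 2
    px <- cx + r * cos(mid)
    py <- cy + r * sin(mid)
    if (px >= 0 && px <= 1 && py >= 0 && py <= 1)
      inside <- inside + (ang[k + 1] - ang[k])
  }
  inside / (2 * pi)
}

# Brute-force Ripley's K: explicit double loop over ordered pairs.
oracle_K <- function(x, y, r) {
  n <- length(x)
  vapply(r, function(rr) {
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d <= rr) tot <- tot + 1 / oracle_inside_frac(x[i], y[i], d)
    }
    tot / (n * (n - 1))
  }, numeric(1))
}

# Brute-force Mann-Whitney AUC: pair counting with ties worth 0.5.
oracle_auc <- function(values, positive) {
  pos <- values[positive]
  neg <- values[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Small profile builder: one segment per value, 2 Mb each on chromosome 1.
make_profile <- function(logR, baf = rep(0.5, length(logR)),
                         n_probes = rep(1000L, length(logR)),
                         major = NULL, minor = NULL,
                         sample_id = "s1", mirrored = FALSE,
                         lengths = rep(2e6, length(logR))) {
  ends <- cumsum(lengths)
  seg <- data.frame(chromosome = 1L, start_bp = c(1, head(ends, -1) + 1),
                    end_bp = ends, n_probes = n_probes, logR = logR, baf = baf)
  if (!is.null(major)) {
    seg$major_cn <- as.integer(major)
    seg$minor_cn <- as.integer(minor)
  }
  snp_profile(sample_id, seg, mirrored = mirrored)
}

# Hand-built clone group: 5 profiles sharing one segmentation.
make_group <- function(states_list, lengths, n_probes = NULL,
                       set_id = "setT", group_id = "gT") {
  n <- length(lengths)
  if (is.null(n_probes)) n_probes <- rep(1000L, n)
  ends <- cumsum(lengths)
  seg <- data.frame(chromosome = 1L, start_bp = c(1, head(ends, -1) + 1),
                    end_bp = ends, length = lengths, n_probes = n_probes)
  profiles <- lapply(seq_along(states_list), function(i) {
    st <- states_list[[i]]
    s <- seg
    s$major <- st[, 1]
    s$minor <- st[, 2]
    structure(list(clone_id = paste0("c", i), baseline = c(major = 1, minor = 1),
                   p_target = NA_real_, segments = s, altered = integer(0),
                   realised_pga = NA_real_),
              class = "clone_profile")
  })
  structure(list(group_id = group_id, set_id = set_id, profiles = profiles,
                 divergences = rep(NA_real_, length(states_list) - 1L),
                 divergent_sets = list(), segments = seg),
            class = "clone_group")
}
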