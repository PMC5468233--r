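# Reading/writing segment tables in the dialects produced by allele-specific
# copy-number callers (ASCAT-like), plus run manifests.

.AUTOSOMES <- 1:22

.DIALECTS <- list(
  ascat_like = list(value_col = "BAF",  mirrored = FALSE),
  mbaf_table = list(value_col = "mBAF", mirrored = TRUE)
)

.required_cols <- function(dialect) {
  c("sample", "chromosome", "start", "end", "nprobes", "logR",
    .DIALECTS[[dialect]]$value_col)
}

#' Construct a segmented profile for one sample
#'
#' A `snp_profile` holds the ordered genomic segments of one sample with their
#' segmented logR and (mirrored) B-allele frequency, plus optional integer
#' allele-specific copy numbers. Segments must lie on autosomes 1-22, be
#' 1-based inclusive, and be non-overlapping within a chromosome.
#'
#' @param sample_id Sample identifier.
#' @param segments `data.frame` with columns `chromosome` (integer 1-22),
#'   `start_bp`, `end_bp` (1-based inclusive), `n_probes`, `logR`, `baf`
#'   (BAF or mirrored BAF depending on `mirrored`), and optionally
#'   `major_cn`, `minor_cn`.
#' @param mirrored Logical; `TRUE` when the `baf` column already holds
#'   mirrored B-allele frequencies (nominal range `[0.5, 1]`).
#' @return An object of class `snp_profile`.
#' @export
snp_profile <- function(sample_id, segments, mirrored = FALSE) {
  need <- c("chromosome", "start_bp", "end_bp", "n_probes", "logR", "baf")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    .format_error(paste0("segments lack column(s): ", paste(miss, collapse = ", ")))
  if (!"major_cn" %in% names(segments)) segments$major_cn <- NA_integer_
  if (!"minor_cn" %in% names(segments)) segments$minor_cn <- NA_integer_
  segments <- segments[order(segments$chromosome, segments$start_bp),
                       c(need, "major_cn", "minor_cn"), drop = FALSE]
  rownames(segments) <- NULL
  obj <- structure(list(sample_id = as.character(sample_id), segments = segments),
                   mirrored = isTRUE(mirrored), class = "snp_profile")
  .validate_profile(obj)
  obj
}

.validate_profile <- function(x) {
  seg <- x$segments
  if (nrow(seg) == 0L) .validation_error("profile has no segments")
  if (any(!(seg$chromosome %in% .AUTOSOMES)))
    .validation_error("chromosome labels must be autosomes 1-22")
  bad <- which(seg$end_bp < seg$start_bp)
  if (length(bad))
    .validation_error(paste0("end_bp < start_bp for segment row(s) ",
                             paste(utils::head(bad, 5L), collapse = ", ")))
  if (any(seg$n_probes < 1L)) .validation_error("n_probes must be >= 1")
  for (chr in unique(seg$chromosome)) {
    s <- seg[seg$chromosome == chr, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start_bp[-1L] <= s$end_bp[-nrow(s)]))
      .validation_error(sprintf(
        "overlapping segments for sample %s on chromosome %d", x$sample_id, chr))
  }
  if (sum(.segment_lengths(x)) <= 0) .validation_error("total covered length is 0")
  invisible(x)
}

.segment_lengths <- function(profile) {
  # 1-based inclusive coordinates
  profile$segments$end_bp - profile$segments$start_bp + 1
}

#' @export
print.snp_profile <- function(x, ...) {
  seg <- x$segments
  cat(sprintf("<snp_profile> sample %s: %d segments on %d autosomes, %.1f Mb covered\n",
              x$sample_id, nrow(seg), length(unique(seg$chromosome)),
              sum(.segment_lengths(x)) / 1e6))
  cat(sprintf("  BAF column is %s; integer CN %s\n",
              if (isTRUE(attr(x, "mirrored"))) "mirrored (mBAF)" else "unmirrored (BAF)",
              if (all(is.na(seg$major_cn))) "absent" else "present"))
  invisible(x)
}

#' Read segment tables
#'
#' Parses a tab-separated segment table into one [snp_profile] per distinct
#' sample. Two dialects are supported: `ascat_like` with columns
#' `sample, chromosome, start, end, nprobes, logR, BAF` (optional `nMajor`,
#' `nMinor`), and `mbaf_table` which carries a mirrored `mBAF` column instead
#' of `BAF`. Coordinates are 1-based inclusive. Rows on sex chromosomes (or
#' with unrecognised chromosome labels) are skipped with a warning; malformed
#' numeric fields and overlapping segments are reported with their line
#' numbers.
#'
#' @param path Path to a tab-separated table with a header row.
#' @param dialect `"ascat_like"` or `"mbaf_table"`.
#' @return Named list of [snp_profile] objects (one per sample, in order of
#'   first appearance).
#' @seealso [write_segments()]
#' @export
read_segments <- function(path, dialect = c("ascat_like", "mbaf_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .format_error(paste0("file not found: ", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  req <- .required_cols(dialect)
  miss <- setdiff(req, names(raw))
  if (length(miss))
    .format_error(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  if (nrow(raw) == 0L) .format_error("table has no data rows")
  line_no <- seq_len(nrow(raw)) + 1L   # header is line 1

  chrom <- suppressWarnings(as.integer(sub("^chr", "", raw$chromosome)))
  skip <- !(chrom %in% .AUTOSOMES)
  if (any(skip)) {
    warning(sprintf("skipping %d non-autosomal row(s) (lines %s)", sum(skip),
                    paste(utils::head(line_no[skip], 5L), collapse = ", ")),
            call. = FALSE)
    raw <- raw[!skip, , drop = FALSE]
    chrom <- chrom[!skip]
    line_no <- line_no[!skip]
  }
  if (nrow(raw) == 0L) .format_error("no autosomal data rows")

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  vals <- list(start = num("start"), end = num("end"), nprobes = num("nprobes"),
               logR = num("logR"), baf = num(.DIALECTS[[dialect]]$value_col))
  bad <- Reduce(`|`, lapply(vals, is.na))
  if (any(bad))
    .format_error(sprintf("non-numeric value(s) in required column(s) at line(s) %s",
                          paste(utils::head(line_no[bad], 10L), collapse = ", ")))
  bad_coord <- vals$end < vals$start
  if (any(bad_coord))
    .validation_error(sprintf("end < start at line(s) %s",
                              paste(utils::head(line_no[bad_coord], 10L), collapse = ", ")))

  has_cn <- all(c("nMajor", "nMinor") %in% names(raw))
  major <- if (has_cn) suppressWarnings(as.integer(raw$nMajor)) else NA_integer_
  minor <- if (has_cn) suppressWarnings(as.integer(raw$nMinor)) else NA_integer_

  seg <- data.frame(chromosome = chrom, start_bp = vals$start, end_bp = vals$end,
                    n_probes = as.integer(vals$nprobes), logR = vals$logR,
                    baf = vals$baf, major_cn = major, minor_cn = minor)
  mirrored <- .DIALECTS[[dialect]]$mirrored
  ids <- unique(raw$sample)
  profiles <- lapply(ids, function(id)
    snp_profile(id, seg[raw$sample == id, , drop = FALSE], mirrored = mirrored))
  names(profiles) <- ids
  profiles
}

#' Write segment tables
#'
#' Serialises a collection of [snp_profile] objects to one tab-separated
#' table. The dialect (BAF vs mBAF column) is taken from the profiles
#' themselves; floating-point fields are written with 17 significant digits so
#' `read_segments(write_segments(x))` reproduces `x` field for field.
#'
#' @param profiles Non-empty list of [snp_profile] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "snp_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) .param_error("profiles must be non-empty")
  mirrored <- vapply(profiles, function(p) isTRUE(attr(p, "mirrored")), logical(1))
  if (length(unique(mirrored)) != 1L)
    .param_error("all profiles must share one BAF dialect")
  value_col <- if (mirrored[1L]) "mBAF" else "BAF"
  fm <- function(x) sprintf("%.17g", x)
  tabs <- lapply(profiles, function(p) {
    s <- p$segments
    data.frame(sample = p$sample_id, chromosome = s$chromosome,
               start = fm(s$start_bp), end = fm(s$end_bp),
               nprobes = s$n_probes, logR = fm(s$logR), value = fm(s$baf),
               nMajor = s$major_cn, nMinor = s$minor_cn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  names(out)[names(out) == "value"] <- value_col
  if (all(is.na(out$nMajor))) out$nMajor <- out$nMinor <- NULL
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .format_error(paste0("cannot write to ", path))
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records every tunable parameter of a run together with the master seed as
#' YAML, so any run can be replayed exactly. If `seed` is `NULL` a seed is
#' drawn and recorded.
#'
#' @param config Named list of run parameters (e.g. `n_bins`, `r_max`,
#'   simulation settings).
#' @param seed Integer master seed, or `NULL` to auto-draw one.
#' @param path Output path for the YAML manifest.
#' @return The manifest list, invisibly (with the recorded seed).
#' @export
write_run_manifest <- function(config, seed = NULL, path) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  manifest <- list(tool = "snpdiv",
                   version = as.character(utils::packageVersion("snpdiv")),
                   seed = as.integer(seed),
                   parameters = config)
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}
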