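#' Column dialect for SEG files
#'
#' SEG files in the wild vary in header names and coordinate convention.
#' A dialect maps the five required concepts onto column names and records
#' whether coordinates are 0-based half-open (UCSC style) rather than the
#' 1-based inclusive GISTIC/TCGA convention used internally.
#'
#' @param sample,chrom,start,end,mean Column names in the file header.
#' @param probes Optional column name holding the per-segment probe count,
#'   or `NULL` when the file has none.
#' @param zero_based Set `TRUE` for 0-based half-open input coordinates;
#'   they are shifted to 1-based inclusive on read.
#' @return A list of class `seg_dialect`.
#' @export
#' @examples
#' seg_dialect(sample = "Sample", mean = "Segment_Mean")
seg_dialect <- function(sample = "ID", chrom = "chrom", start = "loc.start",
                        end = "loc.end", mean = "seg.mean",
                        probes = "num.mark", zero_based = FALSE) {
  structure(list(sample = sample, chrom = chrom, start = start, end = end,
                 mean = mean, probes = probes, zero_based = zero_based),
            class = "seg_dialect")
}

normalize_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

#' Read a segmented copy-number (SEG) file
#'
#' Reads a tab-delimited SEG file into a typed segment table. Chromosome
#' labels are normalized by stripping any `chr` prefix. Rows with
#' non-numeric coordinates or with `start > end` are rejected and reported;
#' a missing required column is a fatal error naming the column.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect A [seg_dialect()] mapping concepts to column names.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `num_probes` (NA when absent) and `seg_mean`, carrying the number of
#'   rejected rows in attribute `rejected`.
#' @export
read_seg <- function(path, dialect = seg_dialect()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  needed <- c(dialect$sample, dialect$chrom, dialect$start, dialect$end, dialect$mean)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("SEG file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  has_probes <- !is.null(dialect$probes) && dialect$probes %in% names(raw)
  seg <- tibble::tibble(
    sample_id  = raw[[dialect$sample]],
    chrom      = normalize_chrom(raw[[dialect$chrom]]),
    start      = suppressWarnings(as.numeric(raw[[dialect$start]])),
    end        = suppressWarnings(as.numeric(raw[[dialect$end]])),
    num_probes = if (has_probes) suppressWarnings(as.numeric(raw[[dialect$probes]])) else NA_real_,
    seg_mean   = suppressWarnings(as.numeric(raw[[dialect$mean]]))
  )
  if (isTRUE(dialect$zero_based)) seg$start <- seg$start + 1
  bad <- !is.finite(seg$start) | !is.finite(seg$end) | is.na(seg$seg_mean) |
    seg$start > seg$end
  if (any(bad)) {
    warn(paste0("read_seg: rejected ", sum(bad),
                " row(s) with non-numeric coordinates, missing mean, or start > end"))
    seg <- seg[!bad, , drop = FALSE]
  }
  attr(seg, "rejected") <- sum(bad)
  seg
}

#' Write a segment table back to SEG format
#'
#' Inverse of [read_seg()]: coordinates and intensities round-trip exactly
#' up to text formatting.
#'
#' @param segments A segment table as returned by [read_seg()].
#' @param path Output path.
#' @param dialect Column naming to use on output.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, dialect = seg_dialect()) {
  out <- tibble::tibble(segments$sample_id, segments$chrom,
                        segments$start, segments$end,
                        segments$num_probes, segments$seg_mean)
  names(out) <- c(dialect$sample, dialect$chrom, dialect$start, dialect$end,
                  dialect$probes %||% "num.mark", dialect$mean)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Keep only primary-tumor TCGA barcodes
#'
#' TCGA sample barcodes encode the sample type in their fourth field;
#' code `01` denotes primary solid tumor. With `enabled = TRUE` only
#' barcodes whose sample-type field starts with `01` are retained (so
#' `...-01A-...` vials qualify, `...-11A-...` normals do not). With
#' `enabled = FALSE` the table passes through untouched, for non-TCGA
#' cohorts whose ids are not barcode-shaped.
#'
#' @param segments A segment table.
#' @param enabled Apply the filter? Default `TRUE`.
#' @return The filtered segment table.
#' @export
filter_primary_tumor_barcodes <- function(segments, enabled = TRUE) {
  if (!enabled) return(segments)
  parts <- strsplit(segments$sample_id, "-", fixed = TRUE)
  shaped <- vapply(parts, function(p) length(p) >= 4 && grepl("^[0-9]{2}", p[4]),
                   logical(1))
  if (!all(shaped)) {
    abort(paste0("sample ids are not TCGA barcodes (example: ",
                 segments$sample_id[which(!shaped)[1]],
                 "); use enabled = FALSE for non-TCGA cohorts"))
  }
  keep <- vapply(parts, function(p) substr(p[4], 1, 2) == "01", logical(1))
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(paste0("filter_primary_tumor_barcodes: dropped ", dropped,
                  " non-primary sample row(s)"))
  }
  segments[keep, , drop = FALSE]
}

#' Read a clinical outcome table into long survival records
#'
#' @param path Tab-delimited file with a header and one row per sample.
#' @param endpoint_map Named list; each element is `c(time = <col>, event =
#'   <col>)` and its name is the endpoint label (e.g. `"OS"`, `"LFFR"`,
#'   `"PFS"`).
#' @param sample_col Name of the sample-id column. Default `"sample_id"`.
#' @param time_unit `"months"` (no conversion) or `"days"` (divided by
#'   365.25/12).
#' @return A tibble with columns `sample_id`, `endpoint`, `time` (months),
#'   `event` (0/1). Rows with non-positive or missing time are rejected with
#'   a warning; an event value outside \{0, 1\} is a fatal error.
#' @export
read_clinical <- function(path, endpoint_map, sample_col = "sample_id",
                          time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!sample_col %in% names(raw)) {
    abort(paste0("clinical file is missing sample column '", sample_col, "'"))
  }
  recs <- purrr::imap(endpoint_map, function(cols, ep) {
    for (cc in cols) {
      if (!cc %in% names(raw)) abort(paste0("clinical file is missing column '", cc, "'"))
    }
    tibble::tibble(sample_id = as.character(raw[[sample_col]]),
                   endpoint = ep,
                   time = as.numeric(raw[[cols[["time"]]]]),
                   event = as.numeric(raw[[cols[["event"]]]]))
  })
  out <- dplyr::bind_rows(recs)
  out <- out[!is.na(out$time) | !is.na(out$event), , drop = FALSE]
  if (any(!out$event %in% c(0, 1))) {
    abort("event indicator must be 0 or 1")
  }
  if (time_unit == "days") out$time <- out$time / (365.25 / 12)
  bad <- !is.finite(out$time) | out$time <= 0
  if (any(bad)) {
    warn(paste0("read_clinical: rejected ", sum(bad),
                " record(s) with non-positive or missing time"))
    out <- out[!bad, , drop = FALSE]
  }
  dup <- duplicated(out[c("sample_id", "endpoint")])
  if (any(dup)) {
    warn(paste0("read_clinical: dropped ", sum(dup),
                " duplicate (sample, endpoint) record(s)"))
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Read a chromosome-arm definition table
#'
#' Expects a tab-delimited file with columns `chrom`, `arm`, `start`, `end`
#' (1-based inclusive). An approximate hg38-like table ships with the
#' package: `system.file("extdata", "hg38_arms.tsv", package = "cnvsizer")`.
#'
#' @param path Path to the arm table.
#' @return A tibble of arm definitions with a combined `arm_id`
#'   (e.g. `"1p"`).
#' @export
read_arm_table <- function(path) {
  arms <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(chrom = readr::col_character(),
                                                  arm = readr::col_character(),
                                                  start = readr::col_double(),
                                                  end = readr::col_double()))
  arms$chrom <- normalize_chrom(arms$chrom)
  validate_arms(arms)
}

validate_arms <- function(arms) {
  stopifnot(all(c("chrom", "arm", "start", "end") %in% names(arms)))
  if (any(arms$start > arms$end)) abort("arm table has start > end")
  if (!all(arms$arm %in% c("p", "q"))) abort("arm must be 'p' or 'q'")
  by_chr <- split(arms, arms$chrom)
  for (ch in by_chr) {
    if (all(c("p", "q") %in% ch$arm)) {
      if (ch$end[ch$arm == "p"] >= ch$start[ch$arm == "q"]) {
        abort(paste0("arms overlap on chromosome ", ch$chrom[1]))
      }
    }
  }
  arms$arm_id <- paste0(arms$chrom, arms$arm)
  tibble::as_tibble(arms[order(suppressWarnings(as.numeric(arms$chrom)), arms$chrom, arms$arm), ])
}

#' Drop arms excluded from copy-number profiling
#'
#' Removes sex chromosomes and the p arms of the acrocentric chromosomes
#' (13p, 14p, 15p, 21p, 22p), which carry negligible unique sequence.
#'
#' @param arms An arm table from [read_arm_table()] or [synthetic_arms()].
#' @return The filtered arm table.
#' @export
filter_arms <- function(arms) {
  acro_p <- paste0(c(13, 14, 15, 21, 22), "p")
  keep <- !(toupper(arms$chrom) %in% c("X", "Y")) & !(arms$arm_id %in% acro_p)
  arms[keep, , drop = FALSE]
}

#' Read a BED file of gene annotations
#'
#' BED coordinates are 0-based half-open; they are converted to the internal
#' 1-based inclusive convention on read. Malformed lines are skipped with a
#' warning.
#'
#' @param path Path to a BED3+ file (optionally a 4th name column).
#' @return A tibble with `chrom`, `start`, `end` (1-based inclusive), `name`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 3 && !is.na(suppressWarnings(as.numeric(f[2]))) &&
      !is.na(suppressWarnings(as.numeric(f[3])))
  }, logical(1))
  if (any(!ok)) warn(paste0("read_bed: skipped ", sum(!ok), " malformed line(s)"))
  fields <- fields[ok]
  tibble::tibble(
    chrom = normalize_chrom(vapply(fields, `[`, "", 1)),
    start = vapply(fields, function(f) as.numeric(f[2]), 0) + 1,
    end = vapply(fields, function(f) as.numeric(f[3]), 0),
    name = vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  )
}

#' Assemble a cohort from segments, outcomes and arm definitions
#'
#' Restricts segments and survival records to their common sample set and
#' bundles them with the (exclusion-filtered) arm table. Samples present on
#' only one side are dropped and reported; an empty intersection is fatal.
#'
#' @param segments Segment table ([read_seg()]).
#' @param survival Long survival records ([read_clinical()]).
#' @param arms Arm table; [filter_arms()] is applied.
#' @return A `cnv_cohort` object: a list with elements `segments`,
#'   `survival`, `arms`, `samples` and `dropped`.
#' @export
build_cohort <- function(segments, survival, arms) {
  arms <- filter_arms(validate_arms(arms))
  seg_samples <- unique(segments$sample_id)
  surv_samples <- unique(survival$sample_id)
  common <- intersect(seg_samples, surv_samples)
  if (length(common) == 0) abort("no samples shared between segments and outcomes")
  dropped <- list(segments_only = setdiff(seg_samples, common),
                  survival_only = setdiff(surv_samples, common))
  n_drop <- length(dropped$segments_only) + length(dropped$survival_only)
  if (n_drop > 0) {
    inform(paste0("build_cohort: dropped ", length(dropped$segments_only),
                  " segment-only and ", length(dropped$survival_only),
                  " outcome-only sample(s)"))
  }
  structure(list(
    segments = segments[segments$sample_id %in% common, , drop = FALSE],
    survival = survival[survival$sample_id %in% common, , drop = FALSE],
    arms = arms,
    samples = sort(common),
    dropped = dropped
  ), class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("<cnv_cohort> ", length(x$samples), " samples, ",
      nrow(x$segments), " segments, ", nrow(x$arms), " arms, endpoints: ",
      paste(unique(x$survival$endpoint), collapse = ", "), "\n", sep = "")
  invisible(x)
}
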