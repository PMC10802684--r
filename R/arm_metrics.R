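#' Grid positions along a chromosome arm
#'
#' Positions are anchored at the arm start and advance in fixed steps of
#' 30000 bases (configurable) while they remain inside the arm, so an arm
#' of length L contributes `floor((L - 1) / step) + 1` points.
#'
#' @param start,end Arm boundaries, 1-based inclusive, `start <= end`.
#' @param step Grid step in bases. Default 30000.
#' @return Numeric vector of positions.
#' @export
#' @examples
#' length(grid_positions(1, 3e6))  # 100
grid_positions <- function(start, end, step = 30000) {
  stopifnot(start <= end, step > 0)
  seq(from = start, to = end, by = step)
}

#' Classify a segment mean intensity as loss, neutral or gain
#'
#' Segment log-ratio intensities below −0.1 are losses and intensities above
#' 0.15 are gains; the inequalities are strict, so the boundary values
#' themselves are neutral. `NA`/`NaN` intensities yield `NA`.
#'
#' @param mean_intensity Numeric vector of segment mean log-ratios.
#' @param loss_cut,gain_cut Cutoffs; defaults −0.1 and 0.15.
#' @return Character vector in `{"loss", "neutral", "gain"}` (or `NA`).
#' @export
classify_intensity <- function(mean_intensity, loss_cut = -0.1, gain_cut = 0.15) {
  out <- rep(NA_character_, length(mean_intensity))
  ok <- is.finite(mean_intensity)
  out[ok] <- "neutral"
  out[ok & mean_intensity < loss_cut] <- "loss"
  out[ok & mean_intensity > gain_cut] <- "gain"
  out
}

# Classify each grid position by its covering segment. Overlapping segments
# are resolved in favour of the larger probe count (ties: first in file
# order); uncovered positions stay NA.
classify_positions <- function(positions, segs, loss_cut = -0.1, gain_cut = 0.15) {
  n_seg <- nrow(segs)
  if (n_seg == 0) return(rep(NA_character_, length(positions)))
  ord <- order(segs$start)
  starts <- segs$start[ord]
  ends <- segs$end[ord]
  overlapping <- n_seg > 1 && any(starts[-1] <= cummax(ends[-n_seg]))
  cls <- classify_intensity(segs$seg_mean, loss_cut, gain_cut)
  if (!overlapping) {
    fi <- findInterval(positions, starts)
    hit <- fi > 0 & positions <= ends[pmax(fi, 1)]
    out <- rep(NA_character_, length(positions))
    out[hit] <- cls[ord][fi[hit]]
    return(out)
  }
  # priority resolution for overlapping tables
  prio <- order(-ifelse(is.na(segs$num_probes), -Inf, segs$num_probes),
                seq_len(n_seg))
  out <- rep(NA_character_, length(positions))
  for (i in prio) {
    idx <- is.na(out) & positions >= segs$start[i] & positions <= segs$end[i]
    out[idx] <- cls[i]
  }
  attr(out, "overlap") <- TRUE
  out
}

#' Per-arm altered fractions on a fixed grid
#'
#' For every sample and (non-excluded) chromosome arm, samples the segment
#' profile at 30-kb intervals, classifies each covered grid point as loss,
#' neutral or gain, and sums non-consecutive alterations: the loss (gain)
#' fraction is the number of loss (gain) points divided by the number of
#' covered points. Arms whose coverage falls below `min_coverage` of the
#' grid are reported as missing. Segments spanning an arm boundary are
#' clipped logically at query time.
#'
#' @param cohort A `cnv_cohort` from [build_cohort()].
#' @param step Grid step in bases (default 30000).
#' @param min_coverage Minimum fraction of grid points that must be covered
#'   by a segment for the arm to be non-missing (default 0.5).
#' @param loss_cut,gain_cut Intensity cutoffs passed to
#'   [classify_intensity()].
#' @return A tibble of class `arm_fractions`: one row per sample
#'   (`sample_id` first), one column per feature named `<arm>_<direction>`
#'   (e.g. `"1p_loss"`), values in \[0, 1\] or `NA`. Attribute `features`
#'   holds the feature table, attribute `grid` the per-arm grid sizes.
#' @export
arm_fractions <- function(cohort, step = 30000, min_coverage = 0.5,
                          loss_cut = -0.1, gain_cut = 0.15) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  arms <- cohort$arms
  grids <- purrr::map(seq_len(nrow(arms)),
                      ~grid_positions(arms$start[.x], arms$end[.x], step))
  if (any(lengths(grids) == 0)) abort("an arm has zero grid points; check step")
  samples <- cohort$samples
  seg_by_sample <- split(cohort$segments, cohort$segments$sample_id)
  n_overlap <- 0L
  rows <- purrr::map(samples, function(sid) {
    segs <- seg_by_sample[[sid]]
    vals <- numeric(0)
    for (a in seq_len(nrow(arms))) {
      pos <- grids[[a]]
      sub <- segs[segs$chrom == arms$chrom[a] &
                    segs$end >= arms$start[a] & segs$start <= arms$end[a], ,
                  drop = FALSE]
      cls <- classify_positions(pos, sub, loss_cut, gain_cut)
      if (isTRUE(attr(cls, "overlap"))) n_overlap <<- n_overlap + 1L
      covered <- sum(!is.na(cls))
      if (covered < min_coverage * length(pos)) {
        fl <- fg <- NA_real_
      } else {
        fl <- sum(cls == "loss", na.rm = TRUE) / covered
        fg <- sum(cls == "gain", na.rm = TRUE) / covered
      }
      vals <- c(vals, fl, fg)
    }
    vals
  })
  features <- tibble::tibble(
    feature = as.vector(t(outer(arms$arm_id, c("loss", "gain"), paste, sep = "_"))),
    arm_id = rep(arms$arm_id, each = 2),
    direction = rep(c("loss", "gain"), nrow(arms))
  )
  if (n_overlap > 0) {
    warn(paste0("arm_fractions: resolved overlapping segments in ", n_overlap,
                " sample-arm combination(s) by larger probe count"))
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- features$feature
  out <- dplyr::bind_cols(tibble::tibble(sample_id = samples),
                          tibble::as_tibble(mat))
  attr(out, "features") <- features
  attr(out, "grid") <- tibble::tibble(arm_id = arms$arm_id, n_grid = lengths(grids))
  class(out) <- c("arm_fractions", class(out))
  out
}

feature_columns <- function(x) setdiff(names(x), "sample_id")

#' Extract the sample-by-feature matrix from a fractions or call table
#'
#' @param x An `arm_fractions` or `cnv_calls` tibble.
#' @return A numeric matrix with sample ids as row names.
#' @export
feature_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x[feature_columns(x)]))
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' Binarize altered fractions at size thresholds
#'
#' A feature is called (1) when its altered fraction meets the threshold
#' (`fraction >= threshold`); missing fractions propagate to missing calls.
#'
#' @param fractions An `arm_fractions` tibble.
#' @param thresholds Either a single threshold in (0, 1\] applied to every
#'   feature, or a named numeric vector / two-column tibble
#'   (`feature`, `threshold`) giving one per feature. Features without a
#'   threshold are dropped.
#' @return A `cnv_calls` tibble (sample_id + 0/1/NA feature columns) with
#'   the thresholds used in attribute `thresholds`.
#' @export
binarize <- function(fractions, thresholds) {
  if (is.data.frame(thresholds)) {
    thresholds <- setNames(thresholds$threshold, thresholds$feature)
  }
  feats <- feature_columns(fractions)
  if (is.null(names(thresholds))) {
    if (length(thresholds) != 1) abort("unnamed thresholds must be a single value")
    thresholds <- setNames(rep(thresholds, length(feats)), feats)
  }
  if (any(thresholds <= 0 | thresholds > 1)) abort("thresholds must lie in (0, 1]")
  use <- intersect(feats, names(thresholds))
  mat <- feature_matrix(fractions)[, use, drop = FALSE]
  calls <- sweep(mat, 2, thresholds[use], FUN = ">=") * 1
  out <- dplyr::bind_cols(tibble::tibble(sample_id = fractions$sample_id),
                          tibble::as_tibble(calls))
  attr(out, "thresholds") <- thresholds[use]
  feats_tbl <- attr(fractions, "features")
  if (!is.null(feats_tbl)) {
    attr(out, "features") <- feats_tbl[feats_tbl$feature %in% use, , drop = FALSE]
  }
  class(out) <- c("cnv_calls", class(out))
  out
}
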