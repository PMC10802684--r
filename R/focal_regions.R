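#' Per-position alteration pileup along an arm
#'
#' At each 30-kb grid position of an arm, the fraction of samples whose
#' covering segment classifies as the given direction; the denominator is
#' the number of samples with a covering segment at that position, and
#' positions covered by fewer than `min_sample_frac` of samples are
#' reported missing.
#'
#' @param cohort A `cnv_cohort`.
#' @param arm Arm identifier, e.g. `"3p"`.
#' @param direction `"loss"` or `"gain"`.
#' @param step Grid step in bases (default 30000).
#' @param min_sample_frac Minimum fraction of samples covering a position
#'   (default 0.5).
#' @param loss_cut,gain_cut Intensity cutoffs.
#' @return A tibble of class `cnv_pileup`: `position`, `prop`, `n_covered`;
#'   attributes `arm`, `direction`, `step`, `n_samples`.
#' @export
pileup <- function(cohort, arm, direction = c("loss", "gain"), step = 30000,
                   min_sample_frac = 0.5, loss_cut = -0.1, gain_cut = 0.15) {
  direction <- match.arg(direction)
  stopifnot(inherits(cohort, "cnv_cohort"))
  a <- cohort$arms[cohort$arms$arm_id == arm, , drop = FALSE]
  if (nrow(a) != 1) abort(paste0("arm '", arm, "' not found in cohort arms"))
  pos <- grid_positions(a$start, a$end, step)
  samples <- cohort$samples
  seg_by_sample <- split(cohort$segments, cohort$segments$sample_id)
  hits <- matrix(NA_character_, nrow = length(samples), ncol = length(pos))
  for (i in seq_along(samples)) {
    segs <- seg_by_sample[[samples[i]]]
    sub <- segs[segs$chrom == a$chrom & segs$end >= a$start & segs$start <= a$end, ,
                drop = FALSE]
    hits[i, ] <- classify_positions(pos, sub, loss_cut, gain_cut)
  }
  covered <- colSums(!is.na(hits))
  prop <- colSums(hits == direction, na.rm = TRUE) / covered
  prop[covered < min_sample_frac * length(samples)] <- NA_real_
  out <- tibble::tibble(position = pos, prop = prop, n_covered = covered)
  attr(out, "arm") <- arm
  attr(out, "direction") <- direction
  attr(out, "step") <- step
  attr(out, "n_samples") <- length(samples)
  class(out) <- c("cnv_pileup", class(out))
  out
}

moving_average <- function(x, window) {
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, 0)
}

#' Detect focal regions standing above their flanking background
#'
#' Formalizes the visual selection of focal events on a pileup track: the
#' track is smoothed with a centered moving average; a position is a
#' candidate when its smoothed value exceeds the median of its flanking
#' band (within `flank` bases on both sides, excluding the smoothing core)
#' by at least `margin`; adjacent candidates merge into regions; regions
#' spanning fewer than `min_points` grid points are discarded. Defaults are
#' chosen so a 30%-over-5% spike is detected while binomial sampling noise
#' in cohorts of a few hundred samples is not.
#'
#' @param track A `cnv_pileup`.
#' @param window Smoothing window in grid points (default 5).
#' @param flank Flanking band half-width in bases (default 3e6).
#' @param margin Minimum prominence above the flank median (default 0.05).
#' @param min_points Minimum region length in grid points (default 2).
#' @return A tibble of class `focal_regions`: `arm`, `direction`, `start`,
#'   `end`, `n_points`, `peak`, `background`, `prominence`.
#' @export
detect_focal <- function(track, window = 5, flank = 3e6, margin = 0.05,
                         min_points = 2) {
  pos <- track$position
  step <- attr(track, "step") %||% (if (length(pos) > 1) diff(pos[1:2]) else 30000)
  sm <- moving_average(track$prop, window)
  half <- floor(window / 2)
  n <- length(pos)
  flank_pts <- max(1, round(flank / step))
  bg <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - flank_pts); hi <- min(n, i + flank_pts)
    band <- setdiff(lo:hi, max(1, i - half):min(n, i + half))
    if (length(band) == 0 || all(is.na(sm[band]))) return(NA_real_)
    median(sm[band], na.rm = TRUE)
  }, 0)
  cand <- !is.na(sm) & !is.na(bg) & (sm - bg >= margin)
  if (!any(cand)) {
    return(empty_focal(attr(track, "arm"), attr(track, "direction")))
  }
  runs <- rle(cand)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_points
  if (!any(keep)) {
    return(empty_focal(attr(track, "arm"), attr(track, "direction")))
  }
  out <- purrr::map_dfr(which(keep), function(r) {
    i0 <- starts[r]; i1 <- ends[r]
    ipk <- (i0:i1)[which.max(sm[i0:i1])]
    tibble::tibble(arm = attr(track, "arm") %||% NA_character_,
                   direction = attr(track, "direction") %||% NA_character_,
                   start = pos[i0], end = pos[i1], n_points = i1 - i0 + 1,
                   peak = sm[ipk], background = bg[ipk],
                   prominence = sm[ipk] - bg[ipk])
  })
  class(out) <- c("focal_regions", class(out))
  out
}

empty_focal <- function(arm, direction) {
  out <- tibble::tibble(arm = character(0), direction = character(0),
                        start = numeric(0), end = numeric(0),
                        n_points = numeric(0), peak = numeric(0),
                        background = numeric(0), prominence = numeric(0))
  class(out) <- c("focal_regions", class(out))
  out
}

#' Annotate focal regions with overlapping genes from a BED file
#'
#' @param regions A `focal_regions` tibble; region coordinates are
#'   1-based inclusive.
#' @param bed A tibble from [read_bed()] (coordinates already converted to
#'   1-based inclusive), or a path to a BED file.
#' @param chrom Chromosome of the regions; by default parsed from the arm
#'   identifier (digits/X/Y prefix).
#' @return `regions` with a `genes` list-column of overlapping gene names.
#' @export
annotate_regions <- function(regions, bed, chrom = NULL) {
  if (is.character(bed)) bed <- read_bed(bed)
  if (nrow(regions) == 0) {
    regions$genes <- list()
    return(regions)
  }
  chroms <- chrom %||% sub("[pq]$", "", regions$arm)
  regions$genes <- purrr::map(seq_len(nrow(regions)), function(i) {
    hit <- bed$chrom == chroms[i] & bed$start <= regions$end[i] &
      bed$end >= regions$start[i]
    gn <- bed$name[hit]
    gn[!is.na(gn)]
  })
  regions
}

#' @rdname pileup
#' @param object,x A `cnv_pileup`.
#' @param regions Optional `focal_regions` to shade.
#' @param ... Ignored.
#' @method autoplot cnv_pileup
#' @export
autoplot.cnv_pileup <- function(object, regions = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$prop)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = paste0("Position on ", attr(object, "arm"), " (bp)"),
                  y = paste0("Fraction of samples with ", attr(object, "direction")))
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1),
      fill = "firebrick", alpha = 0.15)
  }
  p
}
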