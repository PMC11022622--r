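#' Allelic-ratio matrix
#'
#' Computes per-cell allelic ratios alt/(ref+alt) from an allele-depth
#' matrix restricted to nuclear sites. Ratios computed from fewer than
#' `min_depth` reads are set missing; the study protocol treats ratios below
#' 15 reads as uninformative for ploidy profiling.
#'
#' @param ad an [allele_depth_matrix()] (nuclear sites).
#' @param min_depth minimum reads for a usable ratio (default 15).
#' @return a `ratio_matrix`: list with `ratio` (samples x sites, NA where
#'   depth < `min_depth`), `depth`, `min_depth_used`.
#' @export
allelic_ratios <- function(ad, min_depth = 15) {
  if (any(ad$sites$compartment != "nuclear"))
    stop("allelic_ratios expects nuclear sites only; see subset_compartment()")
  ratio <- ad$alt_depth / ad$depth
  ratio[ad$depth < min_depth] <- NA_real_
  structure(list(ratio = ratio, depth = ad$depth, min_depth_used = min_depth,
                 samples = ad$samples),
            class = "ratio_matrix")
}

#' Select reference SNPs from a clear-diploid panel
#'
#' Reproduces the reference-SNP filtration: a site is retained iff, pooling
#' the diploid panel's non-missing ratios, (a) the panel mean depth is at
#' least `min_mean_depth`, (b) after discarding ratios below 0.05 or above
#' 0.95 the distribution mode lies within the `mode_window`, and (c) at
#' least `central_mass_min` of the remaining ratios fall inside the
#' `central_mass_window`. The mode is the midpoint of the maximal-count
#' histogram bin (width 0.02, ties broken toward 0.5).
#'
#' @param R a `ratio_matrix` from [allelic_ratios()].
#' @param diploid_panel sample ids with a clear diploid profile.
#' @param min_mean_depth minimum panel mean depth (default 24).
#' @param mode_window,central_mass_window ratio windows.
#' @param tail_exclusion ratios outside (lo, hi) are discarded first.
#' @param central_mass_min minimum fraction of mass in the central window.
#' @return integer vector of retained site indices.
#' @export
select_reference_snps <- function(R, diploid_panel,
                                  min_mean_depth = 24,
                                  mode_window = c(0.45, 0.55),
                                  tail_exclusion = c(0.05, 0.95),
                                  central_mass_window = c(0.4, 0.6),
                                  central_mass_min = 2 / 3) {
  if (!length(diploid_panel)) stop("diploid panel is empty")
  idx <- match(diploid_panel, R$samples)
  if (anyNA(idx)) stop("diploid panel contains unknown sample ids")
  ratio <- R$ratio[idx, , drop = FALSE]
  depth <- R$depth[idx, , drop = FALSE]
  keep <- logical(ncol(ratio))
  breaks <- seq(0, 1, by = 0.02)
  mids <- breaks[-1] - 0.01
  for (j in seq_len(ncol(ratio))) {
    r <- ratio[, j]
    r <- r[!is.na(r)]
    if (!length(r)) next
    if (mean(depth[, j]) < min_mean_depth) next
    r <- r[r >= tail_exclusion[1] & r <= tail_exclusion[2]]
    if (!length(r)) next
    cnt <- tabulate(pmin(findInterval(r, breaks, rightmost.closed = TRUE),
                         length(mids)), nbins = length(mids))
    best <- which(cnt == max(cnt))
    mode_r <- mids[best[which.min(abs(mids[best] - 0.5))]]
    if (mode_r < mode_window[1] || mode_r > mode_window[2]) next
    frac <- mean(r >= central_mass_window[1] & r <= central_mass_window[2])
    keep[j] <- frac >= central_mass_min
  }
  which(keep)
}

#' Kernel density of allelic ratios on [0, 1]
#'
#' Gaussian kernel density with boundary reflection at 0 and 1 on a 512-point
#' grid. Observations can be weighted (by read depth, so better-covered
#' ratios contribute more). The curve integrates to 1 up to grid error.
#'
#' @param ratios usable allelic ratios of one sample (or pooled group).
#' @param bandwidth numeric kernel bandwidth, or "nrd0" for Silverman.
#' @param weights optional non-negative observation weights.
#' @param min_sites below this many usable ratios the profile is considered
#'   unreliable and NULL is returned (callers translate that to "unknown").
#' @return a `density_curve` (list with `x`, `y`, `n`), or NULL.
#' @export
ratio_density <- function(ratios, bandwidth = 0.03, weights = NULL,
                          min_sites = 30) {
  ratios <- as.numeric(ratios)
  ok <- !is.na(ratios)
  ratios <- ratios[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(ratios) < min_sites) return(NULL)
  if (identical(bandwidth, "nrd0")) bandwidth <- stats::bw.nrd0(ratios)
  w <- if (is.null(weights)) rep(1, length(ratios)) else weights
  w3 <- rep(w / sum(w), 3) / 3
  d <- stats::density(c(ratios, -ratios, 2 - ratios), weights = w3,
                      bw = bandwidth, n = 512, from = 0, to = 1)
  structure(list(x = d$x, y = 3 * d$y, n = length(ratios), bw = bandwidth),
            class = "density_curve")
}

## local maxima of a curve together with their topographic prominence
find_peaks <- function(y) {
  dy <- diff(y)
  pk <- which(diff(sign(dy)) < 0) + 1L
  if (length(y) > 1) {
    if (y[1] > y[2]) pk <- c(1L, pk)
    if (y[length(y)] > y[length(y) - 1]) pk <- c(pk, length(y))
  }
  prom <- vapply(pk, function(i) {
    h <- y[i]
    left <- y[seq_len(i)]
    hi <- which(left > h)
    lmin <- if (length(hi)) min(left[max(hi):i]) else min(left)
    right <- y[i:length(y)]
    hi <- which(right > h)
    rmin <- if (length(hi)) min(right[1:min(hi)]) else min(right)
    h - max(lmin, rmin)
  }, 0)
  list(index = pk, prominence = prom)
}

ploidy_templates <- list(diploid = 0.5,
                         triploid = c(1 / 3, 2 / 3),
                         tetraploid = c(0.25, 0.5, 0.75),
                         pentaploid = c(0.2, 0.4, 0.6, 0.8))

match_template <- function(pos, tolerance) {
  for (lab in names(ploidy_templates)) {
    tp <- ploidy_templates[[lab]]
    if (length(pos) == length(tp) && all(abs(sort(pos) - tp) <= tolerance))
      return(lab)
  }
  "unknown"
}

#' Classify a ploidy level from a ratio density curve
#'
#' Detects local maxima with topographic prominence of at least
#' `min_prominence` of the curve maximum and matches the detected peak set
#' against the canonical templates: one peak near 0.5 (diploid), peaks near
#' 1/3 and 2/3 (triploid), near 0.25/0.5/0.75 (tetraploid) and near
#' 0.2/0.4/0.6/0.8 (pentaploid). Every detected peak must lie within
#' `tolerance` of a distinct template position and every template position
#' must be hit; anything else is "unknown".
#'
#' @param curve a `density_curve` from [ratio_density()], or NULL.
#' @param tolerance maximal |peak - template| distance (default 0.07).
#' @param min_prominence minimal prominence as a fraction of the curve
#'   maximum (default 0.1).
#' @return a `ploidy_call` list: `label`, `peaks`, `n_sites`, `note`.
#' @export
classify_ploidy <- function(curve, tolerance = 0.07, min_prominence = 0.1) {
  if (is.null(curve))
    return(ploidy_call("unknown", numeric(0), 0L, "too few usable sites"))
  pks <- find_peaks(curve$y)
  keep <- pks$prominence >= min_prominence * max(curve$y)
  pos <- curve$x[pks$index[keep]]
  label <- match_template(pos, tolerance)
  note <- if (label == "unknown") "peak pattern matches no template" else ""
  ploidy_call(label, sort(pos), curve$n, note)
}

ploidy_call <- function(label, peaks, n_sites, note = "") {
  structure(list(label = label, peaks = peaks, n_sites = n_sites, note = note),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("ploidy call: %s (peaks: %s; %d sites)%s\n", x$label,
              paste(sprintf("%.3f", x$peaks), collapse = ", "), x$n_sites,
              if (nzchar(x$note)) paste0(" - ", x$note) else ""))
  invisible(x)
}

## the bandwidth / prominence ladder used for per-sample classification;
## coarse-to-fine bandwidths bracket the component widths expected between
## ~15x and ~45x depth
ploidy_bw_ladder <- c(0.045, 0.04, 0.035, 0.03, 0.0275, 0.025, 0.0225, 0.02)
ploidy_prom_ladder <- c(0.1, 0.05)

#' Classify one sample's ploidy from its allelic ratios
#'
#' Per-sample wrapper around [ratio_density()] and [classify_ploidy()].
#' Ratios in the extreme tails (below 0.05 or above 0.95, mostly homozygous
#' sites) are discarded, densities are estimated depth-weighted across a
#' ladder of bandwidths and prominence levels, and each curve is classified.
#' Among template matches the richest template (most peaks) wins — an
#' oversmoothed curve can only lose peaks, never gain template-consistent
#' ones — except that four-peak (pentaploid) matches must be confirmed at
#' `min_confirm_rich` ladder steps to suppress noise-driven matches. Ties
#' keep the coarsest matching bandwidth. If nothing matches, the call is
#' "unknown" with the default-bandwidth peak set reported.
#'
#' @param ratios numeric ratios (NA allowed).
#' @param depths read depths aligned with `ratios` (KDE weights); NULL for
#'   equal weights.
#' @param tolerance,min_sites see [classify_ploidy()] / [ratio_density()].
#' @param min_confirm_rich bandwidth-step confirmations required for a
#'   pentaploid match (default 3).
#' @return a `ploidy_call`.
#' @export
classify_sample_ploidy <- function(ratios, depths = NULL, tolerance = 0.07,
                                   min_sites = 30, min_confirm_rich = 3L) {
  ok <- !is.na(ratios) & ratios > 0.05 & ratios < 0.95
  r <- ratios[ok]
  w <- if (is.null(depths)) NULL else depths[ok]
  if (length(r) < min_sites)
    return(ploidy_call("unknown", numeric(0), length(r), "too few usable sites"))
  sizes <- c(diploid = 1L, triploid = 2L, tetraploid = 3L, pentaploid = 4L)
  matches <- stats::setNames(vector("list", 4), names(sizes))
  for (bw in ploidy_bw_ladder) {
    d <- ratio_density(r, bandwidth = bw, weights = w, min_sites = min_sites)
    for (pr in ploidy_prom_ladder) {
      call <- classify_ploidy(d, tolerance = tolerance, min_prominence = pr)
      if (call$label == "unknown") next
      matches[[call$label]] <- c(matches[[call$label]], list(call$peaks))
    }
  }
  votes <- lengths(matches)
  ## richest confirmed template wins; >= 4-peak templates need confirmation
  ok <- votes > 0 & (sizes < 4L | votes >= min_confirm_rich)
  best_call <- NULL
  if (any(ok)) {
    lab <- names(sizes)[ok][which.max(sizes[ok])]
    ## peak positions: ensemble average over the rungs that matched (damps
    ## the one-lattice-atom wobble of any single bandwidth), then refined
    ## to the local density mode at a mid-ladder bandwidth
    pk <- colMeans(do.call(rbind, lapply(matches[[lab]], sort)))
    pk <- refine_peaks(pk, r, w, min_sites)
    best_call <- ploidy_call(lab, pk, length(r))
  }
  if (is.null(best_call)) {
    ## report the most sensitive rung's peak set for unmatched profiles
    d <- ratio_density(r, bandwidth = 0.025, weights = w,
                       min_sites = min_sites)
    call <- classify_ploidy(d, tolerance = tolerance, min_prominence = 0.05)
    return(ploidy_call("unknown", call$peaks, length(r),
                       "peak pattern matches no template"))
  }
  best_call$n_sites <- length(r)
  best_call
}


## re-locate each peak at the local mode of a mid-bandwidth density; a
## window-edge argmax means the local mode is not identifiable there and the
## original position is kept
refine_peaks <- function(peaks, r, w, min_sites, bw = 0.035, halfwin = 0.06) {
  d <- ratio_density(r, bandwidth = bw, weights = w, min_sites = min_sites)
  if (is.null(d)) return(peaks)
  vapply(peaks, function(p) {
    win <- which(d$x >= p - halfwin & d$x <= p + halfwin)
    if (length(win) < 3) return(p)
    i <- win[which.max(d$y[win])]
    if (i == win[1] || i == win[length(win)]) p else d$x[i]
  }, 0)
}

#' Pooled ploidy classification for unresolved groups
#'
#' Concatenates the usable ratios of a group of individually unresolved
#' samples and classifies the pooled profile; the study applies this to
#' unknowns grouped by (putative) species, whose pooled profiles resemble
#' the species' common profile.
#'
#' @param R a `ratio_matrix`.
#' @param sample_ids ids of the group (non-empty).
#' @param ref_sites site indices (reference SNPs); NULL = all sites.
#' @param ... passed to [classify_sample_ploidy()].
#' @return a `ploidy_call` for the group.
#' @export
pooled_classification <- function(R, sample_ids, ref_sites = NULL, ...) {
  if (!length(sample_ids)) stop("empty group")
  idx <- match(sample_ids, R$samples)
  if (anyNA(idx)) stop("unknown sample ids in group")
  cols <- if (is.null(ref_sites)) seq_len(ncol(R$ratio)) else ref_sites
  rat <- as.numeric(R$ratio[idx, cols, drop = FALSE])
  dep <- as.numeric(R$depth[idx, cols, drop = FALSE])
  classify_sample_ploidy(rat, dep, ...)
}

#' Infer ploidy for every sample in a dataset
#'
#' Full ploidy-inference pass: (1) compute allelic ratios; (2) bootstrap a
#' clear-diploid panel by classifying every sample on all sites and keeping
#' those called diploid; (3) select reference SNPs from that panel; (4)
#' re-classify every sample on the reference SNPs (one refinement pass);
#' (5) optionally rescue unknowns by pooled classification within the given
#' groups (putative species), labelling them "putative diploid",
#' "putative tetraploid", etc.
#'
#' @param ad nuclear [allele_depth_matrix()].
#' @param min_depth per-ratio depth floor (default 15).
#' @param groups optional named vector (sample id -> group label) used to
#'   pool unknowns for rescue.
#' @param min_sites minimum usable ratios per sample.
#' @return data.frame: `id`, `label` (diploid/triploid/tetraploid/
#'   pentaploid/unknown), `putative` (TRUE when resolved only by pooling),
#'   `peaks`, `n_sites`, plus attributes `ref_sites` and `panel`.
#' @export
infer_ploidy <- function(ad, min_depth = 15, groups = NULL, min_sites = 30) {
  R <- allelic_ratios(ad, min_depth = min_depth)
  classify_all <- function(cols) {
    lapply(seq_along(R$samples), function(i)
      classify_sample_ploidy(R$ratio[i, cols], R$depth[i, cols],
                             min_sites = min_sites))
  }
  all_cols <- seq_len(ncol(R$ratio))
  pass1 <- classify_all(all_cols)
  panel <- R$samples[vapply(pass1, `[[`, "", "label") == "diploid"]
  ref <- if (length(panel)) select_reference_snps(R, panel) else integer(0)
  if (length(ref) < min_sites) {
    ref <- all_cols  # degenerate panel; fall back to all sites
  } else {
    ## one refinement pass: re-derive the panel on reference SNPs
    pass2 <- classify_all(ref)
    panel2 <- R$samples[vapply(pass2, `[[`, "", "label") == "diploid"]
    if (length(panel2) >= 2) {
      ref2 <- select_reference_snps(R, panel2)
      if (length(ref2) >= min_sites) { ref <- ref2; panel <- panel2 }
    }
  }
  calls <- classify_all(ref)
  out <- data.frame(
    id = R$samples,
    label = vapply(calls, `[[`, "", "label"),
    putative = FALSE,
    peaks = vapply(calls, function(cc) paste(sprintf("%.3f", cc$peaks),
                                             collapse = ","), ""),
    n_sites = vapply(calls, function(cc) as.integer(cc$n_sites), 0L),
    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    unk <- out$id[out$label == "unknown"]
    for (g in unique(stats::na.omit(groups[unk]))) {
      ids <- unk[!is.na(groups[unk]) & groups[unk] == g]
      if (!length(ids)) next
      pc <- pooled_classification(R, ids, ref_sites = ref)
      if (pc$label != "unknown") {
        out$label[out$id %in% ids] <- pc$label
        out$putative[out$id %in% ids] <- TRUE
      }
    }
  }
  attr(out, "ref_sites") <- ref
  attr(out, "panel") <- panel
  out
}
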