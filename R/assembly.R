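#' Remove samples exceeding a missing-data fraction
#'
#' @param G a [genotype_matrix()].
#' @param max_missing maximal tolerated per-sample missing fraction (0.40
#'   for the initial diploid dataset, 0.50 for the diploid-tetraploid one).
#' @return the filtered [genotype_matrix()]; removal counts in attribute
#'   `removed`.
#' @export
filter_samples_by_missingness <- function(G, max_missing) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- rowMeans(is.na(G$dosage))
  keep <- miss <= max_missing
  if (!any(keep)) stop("all samples removed by missingness filter")
  out <- genotype_matrix(G$dosage[keep, , drop = FALSE], G$ploidy[keep],
                         G$provenance, G$loci)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Retain polymorphic loci passing MAF and missingness thresholds
#'
#' Locus allele frequency is ploidy-aware: sum of dosages over the sum of
#' ploidies of non-missing samples. Loci with minor-allele frequency below
#' `maf_min` (monomorphic included) or missing fraction of `max_missing` or
#' more are removed.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param max_missing maximal locus missing fraction, exclusive (default 0.30).
#' @export
filter_loci <- function(G, maf_min = 0.01, max_missing = 0.30) {
  stopifnot(maf_min >= 0, maf_min <= 1, max_missing >= 0, max_missing <= 1)
  dos <- G$dosage
  pl <- matrix(G$ploidy, nrow(dos), ncol(dos))
  pl[is.na(dos)] <- 0L
  p <- colSums(dos, na.rm = TRUE) / pmax(colSums(pl), 1L)
  maf <- pmin(p, 1 - p)
  missfrac <- colMeans(is.na(dos))
  keep <- maf >= maf_min & missfrac < max_missing
  if (!any(keep)) stop("no loci remain after filtering")
  out <- genotype_matrix(dos[, keep, drop = FALSE], G$ploidy, G$provenance,
                         G$loci[keep, , drop = FALSE])
  attr(out, "removed") <- sum(!keep)
  out
}

#' Pairwise genetic distance between individuals
#'
#' d(i, j) = sum over loci non-missing in both individuals of the absolute
#' dosage difference. Distances are not rescaled for pairwise missingness
#' (the study's clone thresholds of 350/300 are absolute counts); pairs
#' sharing fewer than 50 loci are flagged in the `low_overlap` attribute.
#'
#' @param G a [genotype_matrix()].
#' @return symmetric matrix with zero diagonal.
#' @export
genetic_distance_matrix <- function(G) {
  dos <- G$dosage
  n <- nrow(dos)
  if (!n) stop("empty genotype matrix")
  M <- !is.na(dos)
  storage.mode(M) <- "double"
  ## |a - b| over shared loci decomposed by dosage thresholds t:
  ## |a - b| = sum_t |1(a > t) - 1(b > t)|, so each threshold contributes a
  ## masked symmetric-difference count computable with matrix products.
  D <- matrix(0, n, n, dimnames = list(rownames(dos), rownames(dos)))
  maxdos <- max(dos, na.rm = TRUE)
  for (t in seq_len(max(maxdos, 1)) - 1L) {
    B <- dos > t
    B[is.na(B)] <- FALSE
    storage.mode(B) <- "double"
    BM <- tcrossprod(B, M)          # loci where i has 1(a>t) and j observed
    D <- D + BM + t(BM) - 2 * tcrossprod(B)
  }
  shared <- tcrossprod(M)
  diag(D) <- 0
  attr(D, "low_overlap") <- which(shared < 50 & upper.tri(shared), arr.ind = TRUE)
  D
}

#' Detect clones by single-linkage distance thresholding
#'
#' Samples i and j belong to one clone group iff they are connected by a
#' chain of pairs at distance <= `threshold` (single linkage). The group
#' representative (genet) is the member with the least missing data, ties
#' broken by lexicographically smallest id.
#'
#' @param D symmetric distance matrix from [genetic_distance_matrix()].
#' @param threshold clone-calling distance (350 for the initial diploid
#'   dataset, 300 for the diploid-tetraploid one).
#' @param missing_fraction optional named per-sample missing fractions used
#'   to pick representatives (defaults to zero for all).
#' @return a `clone_groups` list: `groups` (membership partition),
#'   `representative` (one id per group), `assignment` (sample -> group id),
#'   `threshold`.
#' @export
detect_clones <- function(D, threshold, missing_fraction = NULL) {
  stopifnot(threshold >= 0)
  ids <- rownames(D)
  n <- nrow(D)
  if (is.null(missing_fraction))
    missing_fraction <- stats::setNames(numeric(n), ids)
  if (n > 1) {
    hc <- stats::hclust(stats::as.dist(D), method = "single")
    grp <- stats::cutree(hc, h = threshold)
  } else grp <- stats::setNames(1L, ids)
  groups <- split(ids, grp)
  reps <- vapply(groups, function(g) {
    mf <- missing_fraction[g]
    g[order(mf, g)][1]
  }, "")
  structure(list(groups = groups, representative = unname(reps),
                 assignment = stats::setNames(as.integer(grp), ids),
                 threshold = threshold),
            class = "clone_groups")
}

#' Recode a genotype matrix to the diploid-tetraploid convention
#'
#' Diploid-called samples keep ploidy 2; tetraploid, triploid, pentaploid
#' and unknown calls are all coded as tetraploid (ploidy 4), matching the
#' mixed-ploidy coding in which every non-diploid or ambiguous individual is
#' treated as tetraploid. Dosages are carried unchanged; the allele-row
#' expansion (two trailing -9 rows for diploids) happens at STRUCTURE write
#' time.
#'
#' @param G a [genotype_matrix()].
#' @param calls data.frame with columns `id` and `label` (a ploidy-call
#'   table from [infer_ploidy()]); every sample in `G` must be present.
#' @return a [genotype_matrix()] with provenance "diploid_tetraploid".
#' @export
recode_mixed_ploidy <- function(G, calls) {
  ids <- rownames(G$dosage)
  m <- match(ids, calls$id)
  if (anyNA(m)) stop("missing ploidy call for sample(s): ",
                     paste(ids[is.na(m)], collapse = ", "))
  lab <- calls$label[m]
  pl <- ifelse(lab == "diploid", 2L, 4L)
  ## coding caps the dosage: a sample coded diploid reads any higher dosage
  ## as alternate-homozygous (2)
  dos <- pmin(G$dosage, matrix(pl, nrow(G$dosage), ncol(G$dosage)))
  genotype_matrix(dos, stats::setNames(pl, ids), "diploid_tetraploid",
                  G$loci)
}

#' Assemble an analysis dataset (filters + clone removal)
#'
#' Applies the standard assembly order: sample missingness filter, locus
#' MAF/missingness filters (allele frequencies recomputed after sample
#' removal), genetic-distance clone detection, and reduction to one genet
#' per clone group.
#'
#' @param G a [genotype_matrix()] (already recoded if mixed-ploidy).
#' @param max_missing_ind per-sample missingness cap (0.40 initial, 0.50
#'   mixed).
#' @param maf_min,max_missing_locus locus filters.
#' @param clone_threshold genetic distance threshold (350 initial, 300
#'   mixed).
#' @return list: `G` (filtered, genets only), `clones` (clone_groups),
#'   `report` (named counts of removals).
#' @export
assemble_dataset <- function(G, max_missing_ind = 0.40, maf_min = 0.01,
                             max_missing_locus = 0.30, clone_threshold = 350) {
  n0 <- nrow(G$dosage); l0 <- ncol(G$dosage)
  G1 <- filter_samples_by_missingness(G, max_missing_ind)
  G2 <- filter_loci(G1, maf_min, max_missing_locus)
  D <- genetic_distance_matrix(G2)
  mf <- rowMeans(is.na(G2$dosage))
  cl <- detect_clones(D, clone_threshold, mf)
  keep <- cl$representative
  G3 <- genotype_matrix(G2$dosage[keep, , drop = FALSE], G2$ploidy[keep],
                        G2$provenance, G2$loci)
  list(G = G3, clones = cl,
       report = c(samples_in = n0, loci_in = l0,
                  samples_removed_missing = n0 - nrow(G1$dosage),
                  loci_removed = l0 - ncol(G2$dosage),
                  ramets_collapsed = nrow(G2$dosage) - nrow(G3$dosage),
                  genets = nrow(G3$dosage), loci = ncol(G3$dosage)))
}
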