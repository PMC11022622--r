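#' Select uniquely informative chloroplast SNPs
#'
#' Drops chloroplast sites that are invariant among genotyped samples or
#' whose missing fraction exceeds `max_missing`, then collapses information redundancy: sites inducing the same sample
#' partition (identical columns up to a global 0/1 allele swap, compared on
#' their shared non-missing samples) are represented by the single site
#' with the least missing data (ties: smallest position / first column).
#'
#' @param cpG chloroplast [genotype_matrix()] (haploid dosages in \{0,1\}).
#' @param max_missing per-site missingness cap (default 0.10).
#' @return integer vector of retained column indices (genomic order).
#' @export
informative_cp_snps <- function(cpG, max_missing = 0.10) {
  dos <- cpG$dosage
  variable <- apply(dos, 2, function(x) length(unique(x[!is.na(x)])) > 1)
  cand <- which(colMeans(is.na(dos)) <= max_missing & variable)
  if (!length(cand)) stop("no chloroplast sites pass the missingness cap")
  equivalent <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(TRUE)  # no shared samples: indistinguishable
    all(a[ok] == b[ok]) || all(a[ok] == 1 - b[ok])
  }
  kept <- integer(0)
  for (j in cand) {
    dup <- FALSE
    for (k in kept) {
      if (equivalent(dos[, j], dos[, k])) {
        ## keep the less-missing of the two (tie: earlier position wins)
        if (sum(is.na(dos[, j])) < sum(is.na(dos[, k])))
          kept[kept == k] <- j
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, j)
  }
  sort(kept)
}

#' Build chloroplast haplotypes by SNP concatenation
#'
#' The haplotype is the allele string over the retained sites in genomic
#' order; a sample missing any retained site gets a missing haplotype.
#' Haplotype ids are letters (A, B, C, ...) assigned by decreasing global
#' frequency, ties broken by first occurrence.
#'
#' @param cpG chloroplast [genotype_matrix()].
#' @param retained site (column) indices from [informative_cp_snps()].
#' @return a `haplotype_table` data.frame: `id`, `haplotype` (string or NA),
#'   `hap_id` (letter or NA).
#' @export
cp_haplotypes <- function(cpG, retained) {
  if (!length(retained)) stop("retained site set is empty")
  sub <- cpG$dosage[, retained, drop = FALSE]
  full <- rowSums(is.na(sub)) == 0
  hap <- rep(NA_character_, nrow(sub))
  hap[full] <- apply(sub[full, , drop = FALSE], 1, paste, collapse = "")
  freq <- sort(table(hap), decreasing = TRUE)
  first_seen <- match(names(freq), hap)
  ord <- names(freq)[order(-as.integer(freq), first_seen)]
  letters_ext <- c(LETTERS, paste0("A", LETTERS))  # >26 haplotypes
  ids <- stats::setNames(letters_ext[seq_along(ord)], ord)
  data.frame(id = rownames(sub), haplotype = hap,
             hap_id = ifelse(is.na(hap), NA_character_, ids[hap]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Haplotype sharing across clusters and populations
#'
#' Per haplotype: carrying clusters, shared/endemic status and abundance;
#' per population and per cluster: haplotype richness (count of distinct
#' non-missing haplotype ids).
#'
#' @param H a `haplotype_table` from [cp_haplotypes()].
#' @param clusters,populations named vectors (sample id -> label).
#' @return list: `haplotypes` (hap_id, abundance, clusters, shared),
#'   `cluster_richness`, `population_richness`, `population_spectrum`.
#' @export
haplotype_summary <- function(H, clusters, populations = NULL) {
  has <- !is.na(H$hap_id)
  cl <- clusters[H$id]
  haps <- sort(unique(H$hap_id[has]))
  tab <- do.call(rbind, lapply(haps, function(h) {
    sel <- has & H$hap_id == h
    cls <- sort(unique(stats::na.omit(cl[sel])))
    data.frame(hap_id = h, abundance = sum(sel),
               clusters = paste(cls, collapse = ","),
               n_clusters = length(cls),
               shared = length(cls) > 1, stringsAsFactors = FALSE)
  }))
  cl_rich <- tapply(H$hap_id[has], cl[has],
                    function(x) length(unique(x)))
  out <- list(haplotypes = tab,
              cluster_richness = data.frame(cluster = names(cl_rich),
                                            richness = as.integer(cl_rich),
                                            stringsAsFactors = FALSE))
  if (!is.null(populations)) {
    pp <- populations[H$id]
    out$population_richness <-
      data.frame(population = names(tapply(H$hap_id[has], pp[has],
                                           function(x) length(unique(x)))),
                 richness = as.integer(tapply(H$hap_id[has], pp[has],
                                              function(x) length(unique(x)))),
                 stringsAsFactors = FALSE)
    out$population_spectrum <- as.data.frame(table(population = pp[has],
                                                   hap_id = H$hap_id[has]))
  }
  out
}
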