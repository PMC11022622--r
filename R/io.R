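#' Allele-depth matrix container
#'
#' Per-sample x per-site (ref, alt) read counts plus site metadata. Cells
#' with depth 0 are treated as missing. Only bi-allelic SNPs are admitted.
#'
#' @param samples character vector of sample ids (row order).
#' @param sites data.frame with columns `compartment` (one of "nuclear",
#'   "chloroplast", "mitochondrial"), `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param depth,alt_depth integer matrices, samples x sites.
#' @return an `allele_depth_matrix`.
#' @export
allele_depth_matrix <- function(samples, sites, depth, alt_depth) {
  stopifnot(nrow(depth) == length(samples), ncol(depth) == nrow(sites),
            all(dim(depth) == dim(alt_depth)))
  if (any(alt_depth > depth, na.rm = TRUE))
    stop("alt_depth must be <= depth cell-wise")
  if (any(depth < 0, na.rm = TRUE)) stop("negative depths")
  rownames(depth) <- rownames(alt_depth) <- samples
  structure(list(samples = samples, sites = sites, depth = depth,
                 alt_depth = alt_depth),
            class = "allele_depth_matrix")
}

#' @export
print.allele_depth_matrix <- function(x, ...) {
  cat(sprintf("allele_depth_matrix: %d samples x %d sites (%s)\n",
              length(x$samples), nrow(x$sites),
              paste(sprintf("%s: %d", names(table(x$sites$compartment)),
                            table(x$sites$compartment)), collapse = ", ")))
  invisible(x)
}

#' Restrict an allele-depth matrix to one genome compartment
#' @param ad an [allele_depth_matrix()].
#' @param compartment "nuclear", "chloroplast" or "mitochondrial".
#' @export
subset_compartment <- function(ad, compartment) {
  keep <- ad$sites$compartment == compartment
  allele_depth_matrix(ad$samples, ad$sites[keep, , drop = FALSE],
                      ad$depth[, keep, drop = FALSE],
                      ad$alt_depth[, keep, drop = FALSE])
}

#' Genotype (dosage) matrix container
#'
#' Per-sample x per-locus alternate-allele dosage with per-sample ploidy and
#' missing entries (NA). `provenance` records which analysis dataset the
#' matrix represents: the all-diploid-coded initial dataset, the mixed
#' diploid-tetraploid recoding, or haploid chloroplast dosages.
#'
#' @param dosage integer matrix (samples x loci), NA = missing.
#' @param ploidy named integer vector per sample.
#' @param provenance one of "initial_diploid", "diploid_tetraploid",
#'   "chloroplast".
#' @param loci optional data.frame of locus metadata (chrom, pos, ref, alt).
#' @export
genotype_matrix <- function(dosage, ploidy, provenance = "initial_diploid",
                            loci = NULL) {
  provenance <- match.arg(provenance,
                          c("initial_diploid", "diploid_tetraploid", "chloroplast"))
  stopifnot(nrow(dosage) == length(ploidy))
  if (is.null(names(ploidy))) names(ploidy) <- rownames(dosage)
  pl_max <- if (provenance == "chloroplast") 1L else ploidy
  if (any(sweep(dosage, 1, pl_max, ">"), na.rm = TRUE))
    stop("dosage exceeds ploidy")
  if (is.null(loci)) {
    cn <- colnames(dosage)
    if (is.null(cn)) cn <- sprintf("L%04d", seq_len(ncol(dosage)))
    loci <- data.frame(locus = cn, stringsAsFactors = FALSE)
  }
  colnames(dosage) <- loci$locus
  structure(list(dosage = dosage, ploidy = ploidy, provenance = provenance,
                 loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix [%s]: %d samples x %d loci, %.1f%% missing\n",
              x$provenance, nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Diploid coding of mixed-ploidy dosages
#'
#' Recodes a dosage called under the sample's true ploidy to the dosage a
#' diploid genotype caller would report from the same reads: both alleles
#' present (any intermediate dosage) reads as heterozygous (1), otherwise
#' homozygous 0 or 2. This is the "initial diploid" coding applied when all
#' individuals are presumed diploid, and it is why diploid-coded polyploids
#' show elevated heterozygosity.
#'
#' @param dosage integer matrix (samples x loci), NA = missing.
#' @param ploidy per-sample true ploidy (recycled over loci).
#' @return integer matrix of diploid-coded dosages in \{0, 1, 2\}.
#' @export
code_diploid <- function(dosage, ploidy) {
  pl <- matrix(ploidy, nrow(dosage), ncol(dosage))
  out <- ifelse(dosage == 0L, 0L, ifelse(dosage == pl, 2L, 1L))
  dimnames(out) <- dimnames(dosage)
  storage.mode(out) <- "integer"
  out
}

## contig -> compartment mapping used by the VCF reader
default_contig_map <- function(chrom) {
  ifelse(grepl("^(cp|chloroplast)", chrom, ignore.case = TRUE), "chloroplast",
  ifelse(grepl("^(mt|mito)", chrom, ignore.case = TRUE), "mitochondrial",
         "nuclear"))
}

#' Write a dataset to VCF (GT:DP:AD)
#'
#' Writes nuclear and chloroplast sites of a synthetic (or assembled) dataset
#' as an uncompressed VCF v4.2 dialect with per-sample GT, DP and AD fields.
#' Chloroplast sites are flagged by the contig name "chloroplast".
#'
#' @param sim a `synthetic_dataset` from [simulate_dataset()].
#' @param path output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf_dataset <- function(sim, path) {
  ad <- sim$ad
  n <- length(ad$samples)
  Ln <- nrow(ad$sites)
  gt_str <- function(dos, pl, dp, alt) {
    ifelse(dp == 0 | is.na(dos), ".",
           vapply(seq_along(dos), function(i) {
             if (dp[i] == 0 || is.na(dos[i])) return(".")
             paste(c(rep("0", pl[i] - dos[i]), rep("1", dos[i])), collapse = "/")
           }, ""))
  }
  pl <- sim$samples$true_ploidy
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1>",
             "##contig=<ID=chloroplast>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ad$samples), collapse = "\t"))
  body <- character(Ln + ncol(sim$cp))
  for (j in seq_len(Ln)) {
    dp <- ad$depth[, j]; al <- ad$alt_depth[, j]
    dos <- sim$genotypes[, j]
    gts <- gt_str(dos, pl, dp, al)
    cells <- sprintf("%s:%d:%d,%d", gts, dp, dp - al, al)
    cells[dp == 0] <- "./.:0:0,0"
    body[j] <- paste(c("chr1", ad$sites$pos[j], sprintf("nuc_%d", j),
                       ad$sites$ref[j], ad$sites$alt[j], ".", "PASS", ".",
                       "GT:DP:AD", cells), collapse = "\t")
  }
  cp_depth <- round(sim$config$mean_depth)
  for (j in seq_len(ncol(sim$cp))) {
    dos <- sim$cp[, j]
    gts <- ifelse(is.na(dos), ".", as.character(dos))
    dp <- ifelse(is.na(dos), 0L, cp_depth)
    alt <- ifelse(is.na(dos) | dos == 0L, 0L, cp_depth)
    cells <- sprintf("%s:%d:%d,%d", gts, dp, dp - alt, alt)
    body[Ln + j] <- paste(c("chloroplast", j * 5L, sprintf("cp_%d", j),
                            "C", "G", ".", "PASS", ".", "GT:DP:AD", cells),
                          collapse = "\t")
  }
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a variant file with allele depths
#'
#' Reads a VCF dialect carrying GT, DP and AD per-sample fields. Sites are
#' partitioned into genome compartments from contig names ("cp*" or
#' "chloroplast*" map to chloroplast, "mt*"/"mito*" to mitochondrial, the
#' rest to nuclear); multi-allelic records are dropped with a message, and
#' genotypes observed at depth below `min_dp` are set missing.
#'
#' @param path VCF path.
#' @param min_dp minimum per-sample depth for a genotype call (default 5).
#' @param contig_map function mapping contig names to compartments.
#' @return list with `ad` (an [allele_depth_matrix()] over all compartments),
#'   `nuclear` (a diploid-coded nuclear [genotype_matrix()] built from GT),
#'   `chloroplast` (haploid [genotype_matrix()] or NULL), `ploidy_gt`
#'   (per-sample ploidy as written in GT), `n_multiallelic_dropped`.
#' @export
read_variant_table <- function(path, min_dp = 5, contig_map = default_contig_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", vcfR::getALT(v))
  n_drop <- sum(multi)
  if (n_drop) {
    message(sprintf("dropping %d multi-allelic record(s)", n_drop))
    v <- v[!multi, ]
  }
  fix <- vcfR::getFIX(v)
  dp <- t(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  adf <- t(vcfR::extract.gt(v, "AD"))
  gt <- t(vcfR::extract.gt(v, "GT"))
  dp[is.na(dp)] <- 0
  ref_d <- matrix(as.integer(sub(",.*", "", adf)), nrow(adf), ncol(adf))
  alt_d <- matrix(as.integer(sub(".*,", "", adf)), nrow(adf), ncol(adf))
  ref_d[is.na(ref_d)] <- 0L; alt_d[is.na(alt_d)] <- 0L
  samples <- rownames(dp)

  sites <- data.frame(compartment = contig_map(fix[, "CHROM"]),
                      chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  ad <- allele_depth_matrix(samples, sites,
                            depth = ref_d + alt_d, alt_depth = alt_d)

  ## dosage = number of "1" alleles in GT; depth < min_dp -> missing
  dos_all <- matrix(NA_integer_, nrow(gt), ncol(gt),
                    dimnames = list(samples, NULL))
  ok <- !is.na(gt) & gt != "."
  dos_all[ok] <- vapply(strsplit(gt[ok], "[/|]"),
                        function(a) sum(a == "1"), 0L)
  dos_all[dp < min_dp] <- NA_integer_
  ploidy_gt <- apply(gt, 1, function(g) {
    g <- g[!is.na(g) & g != "."]
    if (!length(g)) return(2L)
    as.integer(stats::median(lengths(strsplit(g, "[/|]"))))
  })

  nuc <- sites$compartment == "nuclear"
  ## the initial dataset codes everything as diploid: see code_diploid()
  dnuc <- dos_all[, nuc, drop = FALSE]
  dnuc_dip <- code_diploid(dnuc, ploidy_gt)
  colnames(dnuc_dip) <- sprintf("%s_%d", sites$chrom[nuc], sites$pos[nuc])
  nuclear <- genotype_matrix(dnuc_dip, stats::setNames(rep(2L, length(samples)), samples),
                             "initial_diploid",
                             loci = data.frame(locus = colnames(dnuc_dip),
                                               chrom = sites$chrom[nuc],
                                               pos = sites$pos[nuc],
                                               stringsAsFactors = FALSE))
  cp_idx <- sites$compartment == "chloroplast"
  chloroplast <- NULL
  if (any(cp_idx)) {
    dcp <- pmin(dos_all[, cp_idx, drop = FALSE], 1L)
    colnames(dcp) <- sprintf("%s_%d", sites$chrom[cp_idx], sites$pos[cp_idx])
    chloroplast <- genotype_matrix(dcp, stats::setNames(rep(1L, length(samples)), samples),
                                   "chloroplast",
                                   loci = data.frame(locus = colnames(dcp),
                                                     chrom = sites$chrom[cp_idx],
                                                     pos = sites$pos[cp_idx],
                                                     stringsAsFactors = FALSE))
  }
  list(ad = ad, nuclear = nuclear, chloroplast = chloroplast,
       ploidy_gt = ploidy_gt, n_multiallelic_dropped = n_drop)
}

#' Write a mixed-ploidy STRUCTURE input file
#'
#' Every individual occupies exactly four rows. Tetraploid-coded individuals
#' carry four allele rows; diploid-coded individuals carry their two allele
#' rows followed by two rows of -9, the standard mixed-ploidy coding for
#' STRUCTURE. A dosage d in ploidy c is written as (c - d) ref codes (0)
#' followed by d alt codes (1); missing genotypes are -9 on all rows.
#'
#' @param G a [genotype_matrix()] (diploid-tetraploid coded).
#' @param path output path (tab-separated; one header row of locus ids).
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(G, path) {
  dos <- G$dosage
  pl <- G$ploidy[rownames(dos)]
  if (any(is.na(pl))) stop("sample present in G but absent from ploidy calls")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(dos), collapse = "\t"), con)
  for (i in seq_len(nrow(dos))) {
    rows <- matrix(-9L, 4L, ncol(dos))
    d <- dos[i, ]
    for (r in seq_len(pl[i])) {
      ## allele row r: ref (0) for the first c-d rows, alt (1) afterwards
      rows[r, !is.na(d)] <- ifelse(r <= pl[i] - d[!is.na(d)], 0L, 1L)
    }
    rows[seq_len(pl[i]), is.na(d)] <- -9L
    for (r in 1:4)
      writeLines(paste(c(rownames(dos)[i], rows[r, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read back a mixed-ploidy STRUCTURE input file
#'
#' Inverse of [write_structure_file()]: reconstructs dosages (sum of alt
#' codes over non-missing allele rows) and the coded ploidy (number of
#' non-missing rows; individuals missing at every locus read as tetraploid).
#'
#' @param path file written by [write_structure_file()].
#' @return a [genotype_matrix()] with provenance "diploid_tetraploid".
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  loci <- strsplit(lines[1], "\t")[[1]]
  body <- do.call(rbind, strsplit(lines[-1], "\t"))
  ids <- body[, 1]
  codes <- matrix(as.integer(body[, -1, drop = FALSE]), nrow(body))
  if (nrow(codes) %% 4 != 0) stop("row count not a multiple of 4")
  uids <- ids[seq(1, length(ids), by = 4)]
  n <- length(uids)
  dos <- matrix(NA_integer_, n, length(loci))
  pl <- integer(n)
  for (i in seq_len(n)) {
    block <- codes[(i - 1) * 4 + 1:4, , drop = FALSE]
    used <- rowSums(block != -9L) > 0
    pl[i] <- max(2L, sum(used))
    if (pl[i] == 3L) pl[i] <- 4L
    bl <- block[seq_len(pl[i]), , drop = FALSE]
    ok <- colSums(bl == -9L) == 0
    dos[i, ok] <- colSums(bl[, ok, drop = FALSE] == 1L)
  }
  rownames(dos) <- uids
  colnames(dos) <- loci
  genotype_matrix(dos, stats::setNames(pl, uids), "diploid_tetraploid")
}

#' Parse STRUCTURE-style run output files into a run table
#'
#' Each file must contain an estimated ln probability of the data and an
#' "Inferred ancestry of individuals" block whose membership rows sum to 1
#' (renormalised when within 1e-3, an error otherwise).
#'
#' @param paths character vector of run-output files.
#' @return a `run_table` data.frame with columns `K`, `replicate`, `lnP`,
#'   and a list-column `Q` of membership matrices.
#' @export
read_structure_runs <- function(paths) {
  rows <- lapply(paths, function(p) {
    txt <- readLines(p)
    ln_line <- grep("Estimated Ln Prob of Data", txt, value = TRUE)
    if (!length(ln_line))
      stop(sprintf("missing lnP(D) in '%s'", p))
    lnP <- as.numeric(sub(".*=\\s*", "", ln_line[1]))
    k_line <- grep("populations assumed|^K\\s*=", txt, value = TRUE)
    K <- as.integer(gsub("\\D", "", k_line[1]))
    a0 <- grep("Inferred ancestry of individuals", txt)
    if (!length(a0)) stop(sprintf("missing ancestry block in '%s'", p))
    block <- txt[(a0 + 2):length(txt)]
    block <- block[nzchar(trimws(block))]
    block <- block[grepl(":", block)]
    qrows <- lapply(block, function(l) {
      as.numeric(strsplit(trimws(sub(".*:", "", l)), "\\s+")[[1]])
    })
    Q <- do.call(rbind, qrows)
    if (ncol(Q) != K)
      stop(sprintf("Q row dimension (%d) does not match declared K=%d in '%s'",
                   ncol(Q), K, p))
    s <- rowSums(Q)
    if (any(abs(s - 1) > 1e-3))
      stop(sprintf("Q rows in '%s' do not sum to 1 within 1e-3", p))
    Q <- Q / s
    list(K = K, lnP = lnP, Q = Q)
  })
  K <- vapply(rows, `[[`, 0L, "K")
  tab <- data.frame(K = K,
                    replicate = stats::ave(K, K, FUN = seq_along),
                    lnP = vapply(rows, `[[`, 0, "lnP"))
  tab$Q <- lapply(rows, `[[`, "Q")
  class(tab) <- c("run_table", class(tab))
  tab
}

#' Write an admixture result as a STRUCTURE-style run output file
#'
#' Produces the minimal "Estimated Ln Prob of Data" + "Inferred ancestry of
#' individuals" layout that [read_structure_runs()] consumes, so that runs of
#' the package's own EM estimator can flow through the same ΔK machinery as
#' externally produced files.
#'
#' @param res an `admixture_result` from [admixture_em()].
#' @param path output path.
#' @export
write_structure_run <- function(res, path) {
  q <- res$Q
  lines <- c(sprintf("%d populations assumed", res$K),
             sprintf("Estimated Ln Prob of Data   = %.4f", res$loglik),
             "",
             "Inferred ancestry of individuals:",
             sprintf("%8s %s", "Label", "(%Miss) :  Inferred clusters"),
             vapply(seq_len(nrow(q)), function(i)
               sprintf("%3d %8s    (0)   :  %s", i, rownames(q)[i] %||% i,
                       paste(sprintf("%.4f", q[i, ]), collapse = " ")), ""))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
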