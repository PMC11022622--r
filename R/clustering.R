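#' PCA of a genotype dosage matrix
#'
#' Missing dosages are imputed to the locus mean before centering; scores
#' are orthogonal with non-increasing eigenvalues (variances).
#'
#' @param G a [genotype_matrix()] or a numeric dosage matrix.
#' @param n_axes number of axes to keep (default: all).
#' @return list: `scores` (n x n_axes), `eigenvalues`, `center`.
#' @export
pca_genotypes <- function(G, n_axes = NULL) {
  X <- if (inherits(G, "genotype_matrix")) G$dosage else G
  if (nrow(X) < 2) stop("need at least 2 samples")
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_axes %||% ncol(pc$x), ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       eigenvalues = pc$sdev^2, center = mu)
}

#' K-means / BIC scan for the number of genetic groups
#'
#' For each k up to `kmax`, runs k-means with `n_restarts` restarts on the
#' PC scores and records BIC_k = n*ln(WSS_k/n) + k*ln(n); the selected k
#' minimises BIC (a `force_k` override is available because a flat BIC
#' valley is often resolved by external evidence such as geography or
#' morphology).
#'
#' @param scores PC score matrix.
#' @param kmax maximal number of clusters scanned (default 70, capped at
#'   n - 1).
#' @param n_restarts k-means restarts per k.
#' @param seed RNG seed for the restarts.
#' @param force_k optional override of the BIC choice.
#' @return a `cluster_scan` list: `k`, `bic`, `selected_k`, `assignments`
#'   (list of cluster vectors per k).
#' @export
kmeans_bic_scan <- function(scores, kmax = 70, n_restarts = 10, seed = 1L,
                            force_k = NULL) {
  n <- nrow(scores)
  if (kmax >= n) stop("kmax must be < n (the number of samples)")
  if (kmax < 2) stop("kmax must be >= 2")
  ks <- seq_len(kmax)
  with_seed(seed, {
    fits <- lapply(ks, function(k) {
      if (k == 1) {
        wss <- sum(scale(scores, scale = FALSE)^2)
        list(wss = wss, cluster = rep(1L, n))
      } else {
        km <- stats::kmeans(scores, centers = k, nstart = n_restarts,
                            iter.max = 50)
        list(wss = km$tot.withinss, cluster = km$cluster)
      }
    })
    bic <- vapply(seq_along(fits), function(i)
      n * log(fits[[i]]$wss / n) + ks[i] * log(n), 0)
    sel <- if (is.null(force_k)) ks[which.min(bic)] else as.integer(force_k)
    structure(list(k = ks, bic = bic, selected_k = sel,
                   assignments = lapply(fits, `[[`, "cluster"),
                   overridden = !is.null(force_k)),
              class = "cluster_scan")
  })
}

## linear discriminant step shared by a_score and dapc_fit
fit_lda_scores <- function(scores, groups, n_pcs) {
  n_pcs <- min(n_pcs, ncol(scores))
  X <- scores[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(X, grouping = factor(groups))
  pred <- stats::predict(fit, X)
  list(fit = fit, pred = pred, X = X, n_pcs = n_pcs)
}

#' a-score optimisation of the number of retained PCs
#'
#' For each candidate number of PCs, the discriminant step is fit and the
#' observed reassignment proportion is compared with its permutation
#' expectation (group labels permuted `n_permutations` times); the a-score
#' is the mean over groups of (observed - permuted) reassignment. Returns
#' the grid argmax.
#'
#' @param scores PC scores.
#' @param groups group labels.
#' @param n_pcs_grid candidate PC counts (within the available PCs).
#' @param n_permutations label permutations per candidate.
#' @param seed RNG seed.
#' @return list: `optimal_n_pcs`, `grid`, `a_scores`.
#' @export
a_score <- function(scores, groups, n_pcs_grid = NULL, n_permutations = 10,
                    seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("a-score needs at least two groups")
  if (is.null(n_pcs_grid))
    n_pcs_grid <- unique(pmax(1, round(seq(2, ncol(scores), length.out = 8))))
  n_pcs_grid <- n_pcs_grid[n_pcs_grid <= ncol(scores)]
  group_mean_correct <- function(lab, truth) {
    ok <- lab == truth
    mean(tapply(ok, truth, mean))
  }
  with_seed(seed, {
    sc <- vapply(n_pcs_grid, function(np) {
      obs <- tryCatch({
        f <- fit_lda_scores(scores, groups, np)
        group_mean_correct(f$pred$class, groups)
      }, error = function(e) NA_real_)
      if (is.na(obs)) return(NA_real_)
      perm <- vapply(seq_len(n_permutations), function(b) {
        gp <- sample(groups)
        tryCatch({
          f <- fit_lda_scores(scores, gp, np)
          group_mean_correct(f$pred$class, gp)
        }, error = function(e) NA_real_)
      }, 0)
      obs - mean(perm, na.rm = TRUE)
    }, 0)
    list(optimal_n_pcs = n_pcs_grid[which.max(sc)], grid = n_pcs_grid,
         a_scores = sc)
  })
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Fits linear discriminants on the retained PCs, maximising among-group
#' over within-group variance. Individual coordinates, per-axis percent
#' variance (discriminant eigenvalue shares) and posterior group
#' memberships are returned; memberships are a softmax of negative halved
#' squared Euclidean distances to group centroids in discriminant space, so
#' rows sum to 1.
#'
#' @param scores PC score matrix.
#' @param groups group labels (factor or vector).
#' @param n_pcs PCs to retain (reduced automatically if the within-group
#'   scatter is singular, with a warning).
#' @param n_da number of discriminant axes (default: groups - 1).
#' @return a `dapc_model`: `coords`, `percent_variance`, `posterior`,
#'   `assigned`, `groups`, `n_pcs`, `lda`.
#' @export
dapc_fit <- function(scores, groups, n_pcs, n_da = NULL) {
  groups <- factor(groups)
  g <- nlevels(groups)
  if (is.null(n_da)) n_da <- g - 1L
  if (n_da > g - 1L) stop("n_da must be <= groups - 1")
  np <- min(n_pcs, ncol(scores))
  f <- NULL
  repeat {
    f <- tryCatch(fit_lda_scores(scores, groups, np), error = function(e) NULL)
    if (!is.null(f) || np <= 1) break
    np <- np - 1L
  }
  if (is.null(f)) stop("discriminant fit failed")
  if (np < min(n_pcs, ncol(scores)))
    warning(sprintf("within-group scatter singular; reduced to %d PCs", np))
  coords <- f$pred$x[, seq_len(min(n_da, ncol(f$pred$x))), drop = FALSE]
  ev <- f$fit$svd^2
  pct <- 100 * ev / sum(ev)
  cent <- apply(coords, 2, function(cc) tapply(cc, groups, mean))
  cent <- matrix(cent, nrow = g,
                 dimnames = list(levels(groups), colnames(coords)))
  d2 <- outer(rowSums(coords^2), rowSums(cent^2), "+") -
    2 * coords %*% t(cent)
  logp <- -0.5 * d2
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp) / rowSums(exp(logp))
  structure(list(coords = coords,
                 percent_variance = pct[seq_len(ncol(coords))],
                 posterior = post,
                 assigned = levels(groups)[max.col(post)],
                 groups = groups, n_pcs = np, lda = f$fit),
            class = "dapc_model")
}

#' Binomial EM admixture estimator (mixed ploidy)
#'
#' Likelihood-based stand-in for Bayesian admixture clustering: dosages
#' g_il ~ Binomial(c_i, sum_k Q_ik F_kl) with per-sample ploidy c_i. EM
#' alternates expected allele-to-cluster assignments with closed-form Q and
#' F updates; the log-likelihood is non-decreasing. Multiple random
#' restarts are run and the best kept; per-restart log-likelihoods are
#' retained so replicate runs can feed [evanno_delta_k()].
#'
#' @param G a [genotype_matrix()] (any provenance; ploidy taken per sample).
#' @param K number of clusters (>= 1).
#' @param max_iter,tol EM stopping rule (lnL gain below `tol`).
#' @param seed RNG seed.
#' @param n_restarts random restarts (best lnL kept).
#' @return an `admixture_result`: `K`, `Q` (n x K, rows sum to 1), `F`
#'   (K x L), `loglik`, `loglik_trace`, `restart_logliks`, `seed`.
#' @export
admixture_em <- function(G, K, max_iter = 500, tol = 1e-4, seed = 1L,
                         n_restarts = 10) {
  dos <- G$dosage
  pl <- G$ploidy
  n <- nrow(dos); L <- ncol(dos)
  obs <- !is.na(dos)
  g <- dos; g[!obs] <- 0
  cmat <- matrix(pl, n, L) * obs   # per-cell ploidy, 0 where missing
  if (K == 1) {
    Fmat <- matrix(colSums(g) / pmax(colSums(cmat), 1), 1, L)
    Q <- matrix(1, n, 1, dimnames = list(rownames(dos), NULL))
    p <- pmin(pmax(Fmat[rep(1, n), ], 1e-6), 1 - 1e-6)
    ll <- sum((g * log(p) + (cmat - g) * log(1 - p))[obs])
    return(structure(list(K = 1L, Q = Q, F = Fmat, loglik = ll,
                          loglik_trace = ll, restart_logliks = ll,
                          seed = seed),
                     class = "admixture_result"))
  }
  eps <- 1e-6
  run_em <- function() {
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    p0 <- colSums(g) / pmax(colSums(cmat), 1)
    Fmat <- pmin(pmax(matrix(rep(p0, each = K), K, L) +
                        stats::runif(K * L, -0.1, 0.1), eps), 1 - eps)
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      P <- Q %*% Fmat                       # n x L expected alt frequency
      P <- pmin(pmax(P, eps), 1 - eps)
      ll <- sum((g * log(P) + (cmat - g) * log(1 - P))[obs])
      trace <- c(trace, ll)
      ## E-step expected cluster-of-origin counts; M-step closed forms
      Aalt <- g / P                          # n x L
      Aref <- (cmat - g) / (1 - P)
      Ek_alt <- matrix(0, n, K); Ek_ref <- matrix(0, n, K)
      Fa <- matrix(0, K, L); Fr <- matrix(0, K, L)
      for (k in seq_len(K)) {
        wa <- Aalt * Q[, k] %o% rep(1, L) * matrix(Fmat[k, ], n, L, byrow = TRUE)
        wr <- Aref * Q[, k] %o% rep(1, L) * matrix(1 - Fmat[k, ], n, L, byrow = TRUE)
        Ek_alt[, k] <- rowSums(wa)
        Ek_ref[, k] <- rowSums(wr)
        Fa[k, ] <- colSums(wa)
        Fr[k, ] <- colSums(wr)
      }
      Fmat <- pmin(pmax(Fa / pmax(Fa + Fr, eps), eps), 1 - eps)
      Qnew <- (Ek_alt + Ek_ref)
      Q <- Qnew / pmax(rowSums(Qnew), eps)
      if (ll - ll_old < tol && it > 2) break
      ll_old <- ll
    }
    list(Q = Q, F = Fmat, trace = trace, loglik = trace[length(trace)])
  }
  with_seed(seed, {
    runs <- lapply(seq_len(n_restarts), function(r) run_em())
    lls <- vapply(runs, `[[`, 0, "loglik")
    best <- runs[[which.max(lls)]]
    rownames(best$Q) <- rownames(dos)
    structure(list(K = as.integer(K), Q = best$Q, F = best$F,
                   loglik = best$loglik, loglik_trace = best$trace,
                   restart_logliks = lls, seed = seed),
              class = "admixture_result")
  })
}

#' Evanno delta-K from a table of clustering replicates
#'
#' For interior K (both neighbours present), delta-K is the mean over
#' replicates of |L(K+1) - 2 L(K) + L(K-1)| divided by the standard
#' deviation of L(K) across replicates. Undefined (NA) at the endpoints and
#' where the replicate standard deviation is zero.
#'
#' @param runs a `run_table` (columns `K`, `replicate`, `lnP`) from
#'   [read_structure_runs()] or built from [admixture_em()] replicates.
#' @return data.frame: `K`, `mean_lnP`, `sd_lnP`, `delta_K`.
#' @export
evanno_delta_k <- function(runs) {
  ks <- sort(unique(runs$K))
  if (length(ks) >= 2 && any(diff(ks) != 1))
    stop("K range must be contiguous")
  mean_l <- tapply(runs$lnP, runs$K, mean)[as.character(ks)]
  sd_l <- tapply(runs$lnP, runs$K, stats::sd)[as.character(ks)]
  nrep <- tapply(runs$lnP, runs$K, length)[as.character(ks)]
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    if (i == 1 || i == length(ks)) next
    if (is.na(sd_l[i]) || sd_l[i] == 0) next
    if (length(unique(nrep)) == 1) {
      ## paired replicates: average the absolute second difference
      l_by_rep <- function(k) runs$lnP[runs$K == k][order(runs$replicate[runs$K == k])]
      sec <- abs(l_by_rep(ks[i + 1]) - 2 * l_by_rep(ks[i]) + l_by_rep(ks[i - 1]))
      dk[i] <- mean(sec) / sd_l[i]
    } else {
      dk[i] <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1]) / sd_l[i]
    }
  }
  data.frame(K = ks, mean_lnP = as.numeric(mean_l), sd_lnP = as.numeric(sd_l),
             delta_K = dk)
}

#' Assign samples to genetic lineages from a Q matrix
#'
#' A sample is assigned to cluster k iff Q_ik >= `threshold` (default 0.75),
#' else labelled "admixed". Any cluster containing samples from both the
#' "Alaska" and "Europe" regions is split into two lineages by region, to
#' respect geographic separation that a single genetic cluster can mask.
#'
#' @param Q n x K membership matrix (rows sum to 1).
#' @param threshold assignment threshold.
#' @param regions named character vector (sample id -> region) or NULL.
#' @return character vector of lineage labels ("cluster<k>",
#'   "cluster<k>_<region>", or "admixed"), named by sample.
#' @export
assign_lineages <- function(Q, threshold = 0.75, regions = NULL) {
  if (any(abs(rowSums(Q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  k_hat <- max.col(Q)
  ass <- ifelse(Q[cbind(seq_len(nrow(Q)), k_hat)] >= threshold,
                sprintf("cluster%d", k_hat), "admixed")
  names(ass) <- rownames(Q)
  if (!is.null(regions)) {
    for (k in unique(k_hat[ass != "admixed"])) {
      lab <- sprintf("cluster%d", k)
      ids <- names(ass)[ass == lab]
      reg <- regions[ids]
      both <- c("Alaska", "Europe") %in% reg
      if (all(both)) {
        if (anyNA(reg)) stop("missing region label for a split cluster")
        split_reg <- ifelse(reg %in% c("Alaska", "Europe"), reg, "Alaska")
        ass[ids] <- sprintf("%s_%s", lab, split_reg)
      }
    }
  }
  ass
}
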