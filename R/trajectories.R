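#' Temporal trajectory traces from normalized pseudobulk expression
#'
#' For each isoform and cell type, averages size-factor-normalized pseudobulk
#' expression over the samples of each age timepoint and divides by the
#' young-timepoint value, so every trace starts at 1. Traces with a zero
#' young value are dropped with a count of the reasons.
#'
#' @param pb `pseudobulk_matrix` with sample x cell-type units carrying
#'   `age_months`.
#' @param sf per-unit size factors from [size_factors()].
#' @return list of class `trajectory_traces`: `values` (traces x timepoints
#'   matrix), `ages` (months per timepoint), `info` (isoform, cell type per
#'   trace), `dropped` (count of zero-young exclusions).
#' @export
trajectory_traces <- function(pb, sf) {
  stopifnot(inherits(pb, "pseudobulk_matrix"))
  units <- pb$units
  stopifnot(!is.null(units$age_months), !is.null(units$cell_type))
  norm <- pb$counts / sf[rownames(pb$counts)]
  ages <- sort(unique(units$age_months))
  young <- min(ages)
  rows <- list()
  info <- list()
  dropped <- 0L
  for (ct in unique(units$cell_type)) {
    ix_ct <- units$cell_type == ct
    by_age <- vapply(ages, function(a) {
      ix <- ix_ct & units$age_months == a
      if (!any(ix)) return(rep(NA_real_, ncol(norm)))
      colMeans(norm[ix, , drop = FALSE])
    }, numeric(ncol(norm)))          # isoforms x ages
    ok <- by_age[, 1] > 0 & !apply(by_age, 1, anyNA)
    dropped <- dropped + sum(!ok)
    if (!any(ok)) next
    tr <- by_age[ok, , drop = FALSE] / by_age[ok, 1]
    rows[[ct]] <- tr
    info[[ct]] <- data.frame(isoform_id = colnames(norm)[ok], cell_type = ct,
                             stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  info <- do.call(rbind, info)
  rownames(values) <- rownames(info) <- paste(info$isoform_id, info$cell_type,
                                              sep = "|")
  structure(list(values = values, ages = ages, info = info, dropped = dropped),
            class = "trajectory_traces")
}

#' Quadratic-versus-flat likelihood-ratio screen of one trace
#'
#' Fits a flat (intercept-only) and a second-order polynomial model on
#' centered age by Gaussian least squares and reports
#' `lr = n * log(RSS_flat / RSS_quad)`. Because the flat model is nested in
#' the quadratic one within a Gaussian linear model, the LRT is a monotone
#' function of the exact F statistic, and the p-value is computed from
#' `F(2, n - 3)` — exact at any number of timepoints and asymptotically equal
#' to the chi-square(2) tail as n grows.
#'
#' @param values expression values (one per timepoint).
#' @param ages timepoint ages in months (>= 4 required).
#' @return list of class `trajectory_fit` with coefficients (on centered
#'   age), RSS of both models, lr_stat and p_value. Constant traces give
#'   lr_stat 0 and p 1; exact quadratic traces give p 0.
#' @export
fit_trajectory <- function(values, ages) {
  n <- length(values)
  stopifnot(length(ages) == n)
  if (n < 4) stopf("need >= 4 timepoints; the quadratic model is saturated")
  a <- ages - mean(ages)
  X <- cbind(1, a, a^2)
  fit_quad <- lm.fit(X, values)
  rss1 <- sum(fit_quad$residuals^2)
  rss0 <- sum((values - mean(values))^2)
  eps <- 1e-12 * max(1, mean(values)^2)
  if (rss0 <= eps) {
    lr <- 0; p <- 1
  } else if (rss1 <= eps) {
    lr <- Inf; p <- 0
  } else {
    lr <- n * log(rss0 / rss1)
    Fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
    p <- pf(Fstat, 2, n - 3, lower.tail = FALSE)
  }
  structure(list(beta = unname(coef(fit_quad)), loglik_flat = -n / 2 * log(rss0 / n),
                 loglik_quad = -n / 2 * log(rss1 / n),
                 rss_flat = rss0, rss_quad = rss1,
                 lr_stat = max(0, lr), p_value = p, n = n),
            class = "trajectory_fit")
}

#' Vectorized trajectory screen
#'
#' Runs [fit_trajectory()]'s test on every row of a trace matrix via hat
#' matrices (identical results, one pass).
#'
#' @param traces traces x timepoints matrix (a `trajectory_traces` object is
#'   also accepted).
#' @param ages timepoint ages (taken from the object when omitted).
#' @param p_threshold screening threshold (default 0.01).
#' @return data.frame with rss_flat, rss_quad, lr_stat, p_value and `pass`.
#' @export
screen_trajectories <- function(traces, ages = NULL, p_threshold = 0.01) {
  if (inherits(traces, "trajectory_traces")) {
    ages <- ages %||% traces$ages
    traces <- traces$values
  }
  stopifnot(!is.null(ages), ncol(traces) == length(ages))
  n <- length(ages)
  a <- ages - mean(ages)
  X <- cbind(1, a, a^2)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  R1 <- traces - traces %*% t(H)
  rss1 <- rowSums(R1^2)
  rss0 <- rowSums((traces - rowMeans(traces))^2)
  eps <- 1e-12
  lr <- ifelse(rss0 <= eps, 0, n * log(pmax(rss0, eps) / pmax(rss1, eps)))
  Fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  p <- ifelse(rss0 <= eps, 1,
              ifelse(rss1 <= eps, 0, pf(Fstat, 2, n - 3, lower.tail = FALSE)))
  data.frame(rss_flat = rss0, rss_quad = rss1, lr_stat = pmax(0, lr),
             p_value = p, pass = p < p_threshold,
             row.names = rownames(traces))
}

## EM for a mixture of quadratic mean curves with cluster-specific isotropic
## variance on the shared timepoint grid.
em_quadratic_mixture <- function(Y, X, K, maxit = 500, tol = 1e-8) {
  n <- nrow(Y); Tn <- ncol(Y)
  XtXi <- solve(crossprod(X))
  ## init: K distinct traces as provisional means
  centers <- Y[sample.int(n, K), , drop = FALSE]
  beta <- t(apply(centers, 1, function(y) XtXi %*% crossprod(X, y)))
  sig2 <- rep(max(mean((Y - rowMeans(Y))^2), 1e-4), K)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    M <- X %*% t(beta)                       # T x K cluster means
    D <- vapply(seq_len(K), function(k) {
      rowSums(sweep(Y, 2, M[, k])^2)
    }, numeric(n))                           # n x K squared distances
    logd <- sweep(-0.5 * sweep(D, 2, sig2, "/"), 2,
                  Tn / 2 * log(2 * pi * sig2) - log(w), "-")
    mx <- apply(logd, 1, max)
    R <- exp(logd - mx)
    rs <- rowSums(R)
    ll <- sum(mx + log(rs))
    R <- R / rs
    Nk <- colSums(R)
    if (any(Nk < 1e-6)) return(list(degenerate = TRUE))
    w <- Nk / n
    for (k in seq_len(K)) {
      ybar <- crossprod(R[, k], Y) / Nk[k]
      beta[k, ] <- XtXi %*% crossprod(X, as.vector(ybar))
      mu <- as.vector(X %*% beta[k, ])
      sig2[k] <- sum(R[, k] * rowSums(sweep(Y, 2, mu)^2)) / (Nk[k] * Tn)
      if (sig2[k] < 1e-12) return(list(degenerate = TRUE))
    }
    if (is.finite(ll_old) && ll < ll_old - 1e-6) break  # numerical guard
    if (abs(ll - ll_old) < tol) { ll_old <- ll; break }
    ll_old <- ll
  }
  list(degenerate = FALSE, beta = beta, sig2 = sig2, w = w,
       loglik = ll_old, resp = R)
}

#' Cluster temporal trajectories by shape
#'
#' Fits, for each candidate K, a K-component Gaussian mixture of quadratic
#' mean curves (cluster-specific isotropic variance) by EM with multiple
#' random restarts, computes the mean silhouette of the resulting hard
#' assignment on per-timepoint standardized trace vectors with Euclidean
#' distance, and returns the model for the K maximizing the silhouette.
#' Clusters are relabeled in increasing order of the fitted
#' geriatric-over-young fold change of their mean curve.
#'
#' @param traces `trajectory_traces` object or traces x timepoints matrix.
#' @param ages timepoint ages (taken from the object when omitted).
#' @param K_candidates candidate cluster counts (default 8, 10, 12, 14).
#' @param n_restarts EM restarts per K (default 10; best likelihood kept).
#' @param seed integer seed.
#' @return object of class `trajectory_clusters`: K, mean-curve coefficients
#'   (ordered), cluster variances and weights, assignments,
#'   responsibilities, per-K silhouettes, and the fold-change ordering.
#' @export
cluster_trajectories <- function(traces, ages = NULL,
                                 K_candidates = c(8, 10, 12, 14),
                                 n_restarts = 10, seed = 1L) {
  if (inherits(traces, "trajectory_traces")) {
    ages <- ages %||% traces$ages
    traces <- traces$values
  }
  stopifnot(!is.null(ages), ncol(traces) == length(ages))
  if (nrow(traces) <= max(K_candidates)) {
    stopf("need more traces (%d) than the largest candidate K (%d)",
          nrow(traces), max(K_candidates))
  }
  a <- ages - mean(ages)
  X <- cbind(1, a, a^2)
  Z <- scale(traces)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  dz <- dist(Z)
  with_seed(seed, {
    sils <- setNames(rep(NA_real_, length(K_candidates)), K_candidates)
    fits <- vector("list", length(K_candidates))
    for (ki in seq_along(K_candidates)) {
      K <- K_candidates[ki]
      best <- NULL
      for (r in seq_len(n_restarts)) {
        f <- em_quadratic_mixture(traces, X, K)
        if (f$degenerate) next
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      if (is.null(best)) next
      assign <- max.col(best$resp)
      if (length(unique(assign)) < 2) next
      sil <- cluster::silhouette(assign, dz)
      sils[ki] <- mean(sil[, "sil_width"])
      fits[[ki]] <- c(best, list(assignments = assign))
    }
    if (all(is.na(sils))) stopf("all EM fits degenerate for every candidate K")
    ki <- which.max(sils)
    best <- fits[[ki]]
    K <- K_candidates[ki]
    ## order clusters by fitted geriatric/young fold change of the mean curve
    mu <- X %*% t(best$beta)
    fold <- mu[which.max(ages), ] / mu[which.min(ages), ]
    ord <- order(fold)
    relabel <- match(seq_len(K), ord)
    structure(list(
      K = K, ages = ages,
      mean_curves = best$beta[ord, , drop = FALSE],
      cluster_variances = best$sig2[ord],
      weights = best$w[ord],
      assignments = setNames(relabel[best$assignments], rownames(traces)),
      responsibilities = best$resp[, ord, drop = FALSE],
      silhouette = sils[ki], silhouette_by_k = sils,
      fold_change = sort(fold), loglik = best$loglik
    ), class = "trajectory_clusters")
  })
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat(sprintf(
    "trajectory clustering: K = %d (silhouette %.3f over candidates %s)\n",
    x$K, x$silhouette, paste(names(x$silhouette_by_k), collapse = "/")))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Mean relative expression change per cell type
#'
#' For each cell type, the mean over its traces of the mean deviation from
#' the young level (value - 1) across the non-young timepoints.
#'
#' @param traces `trajectory_traces` object.
#' @return data.frame cell_type, mean_change, n_traces.
#' @export
expression_change_summary <- function(traces) {
  stopifnot(inherits(traces, "trajectory_traces"))
  later <- which(traces$ages > min(traces$ages))
  rows <- lapply(unique(traces$info$cell_type), function(ct) {
    ix <- traces$info$cell_type == ct
    if (!any(ix)) return(NULL)
    dev <- rowMeans(traces$values[ix, later, drop = FALSE] - 1)
    data.frame(cell_type = ct, mean_change = mean(dev), n_traces = sum(ix),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Isoform-length stratified fold-change analysis between two ages
#'
#' Computes per-isoform log2 fold changes of size-factor-normalized
#' pseudobulk expression between an old and the young age (pseudocount 0.5),
#' keeps isoforms whose normalized expression is in the top 50% of either
#' age, splits the kept isoforms into length tertiles, and compares the
#' fold-change distributions of each tertile pair by a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie correction).
#'
#' @param pb `pseudobulk_matrix` with `age_category` on its units.
#' @param sf size factors.
#' @param catalog isoform catalog (lengths).
#' @param age_pair character(2): reference (young) and comparison age
#'   category.
#' @param pseudocount added inside the log ratio (default 0.5).
#' @param top_frac expression quantile defining "top" (default 0.5).
#' @return list with `table` (isoform, length, bin, log2fc) and `tests`
#'   (bin pair, n per bin, p_value; skipped pairs carry NA).
#' @export
length_shift_analysis <- function(pb, sf, catalog,
                                  age_pair = c("young", "geriatric"),
                                  pseudocount = 0.5, top_frac = 0.5) {
  stopifnot(inherits(pb, "pseudobulk_matrix"))
  units <- pb$units
  stopifnot(all(age_pair %in% units$age_category))
  norm <- pb$counts / sf[rownames(pb$counts)]
  mean_age <- function(ac) {
    colMeans(norm[units$age_category == ac, , drop = FALSE])
  }
  e_young <- mean_age(age_pair[1])
  e_old <- mean_age(age_pair[2])
  keep <- e_young >= quantile(e_young, 1 - top_frac) |
    e_old >= quantile(e_old, 1 - top_frac)
  lens <- catalog$length[match(colnames(norm), catalog$isoform_id)]
  tab <- data.frame(
    isoform_id = colnames(norm)[keep],
    length = lens[keep],
    log2fc = log2((e_old[keep] + pseudocount) / (e_young[keep] + pseudocount)),
    stringsAsFactors = FALSE
  )
  qs <- quantile(tab$length, c(1 / 3, 2 / 3))
  tab$bin <- cut(tab$length, breaks = c(-Inf, qs, Inf),
                 labels = c("short", "medium", "long"))
  pairs <- utils::combn(levels(tab$bin), 2)
  tests <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- tab$log2fc[tab$bin == pairs[1, i]]
    y <- tab$log2fc[tab$bin == pairs[2, i]]
    p <- if (length(x) < 2 || length(y) < 2) {
      NA_real_
    } else if (length(unique(c(x, y))) == 1) {
      1
    } else {
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    }
    data.frame(bin_a = pairs[1, i], bin_b = pairs[2, i],
               n_a = length(x), n_b = length(y), p_value = p,
               stringsAsFactors = FALSE)
  })
  list(table = tab, tests = do.call(rbind, tests))
}
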