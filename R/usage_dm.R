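## Dirichlet-multinomial likelihood machinery.
##
## Counts for one gene form a units x isoforms matrix y with unit totals n.
## With concentration gamma and proportion simplex pi, the DM log-likelihood
## (multinomial coefficient dropped; constant across the models compared) is
##   sum_u [ lgamma(gamma) - lgamma(n_u + gamma)
##           + sum_j lgamma(y_uj + gamma pi_j) - lgamma(gamma pi_j) ].

dm_loglik <- function(y, n, pi, gamma) {
  a <- gamma * pi
  sum(lgamma(gamma) - lgamma(n + gamma)) +
    sum(lgamma(sweep(y, 2, a, "+"))) - nrow(y) * sum(lgamma(a))
}

# Cox-Reid adjustment term: -1/2 log det of the observed information of the
# free proportions (pi_1..pi_{J-1}) at the profiled optimum. The DM Hessian in
# this parameterization is diag(a_j) + a_J 11', with
# a_j = gamma^2 sum_u [trigamma(y_uj + gamma pi_j) - trigamma(gamma pi_j)],
# so the determinant follows from the matrix determinant lemma.
dm_cr_adjust <- function(y, pi, gamma) {
  a <- gamma^2 * (colSums(trigamma(sweep(y, 2, gamma * pi, "+"))) -
                    nrow(y) * trigamma(gamma * pi))
  d <- pmax(-a, 1e-8)
  J <- length(d)
  -0.5 * (sum(log(d[-J])) + log1p(d[J] * sum(1 / d[-J])))
}

# Maximum-likelihood proportions at fixed gamma via Minka's fixed-point
# update pi_j <- pi_j * sum_u [psi(y_uj + g pi_j) - psi(g pi_j)], normalized.
dm_fit_pi <- function(y, n, gamma, pi0 = NULL, tol = 1e-8, maxit = 200) {
  J <- ncol(y)
  pi <- pi0 %||% pmax(colSums(y), 0.5)
  pi <- pi / sum(pi)
  ll <- dm_loglik(y, n, pi, gamma)
  for (it in seq_len(maxit)) {
    a <- gamma * pi
    num <- colSums(digamma(sweep(y, 2, a, "+"))) - nrow(y) * digamma(a)
    w <- pi * pmax(num, 1e-12)
    pi_new <- w / sum(w)
    ll_new <- dm_loglik(y, n, pi_new, gamma)
    if (!is.finite(ll_new)) break
    converged <- abs(ll_new - ll) < tol
    if (ll_new >= ll) { pi <- pi_new; ll <- ll_new }
    if (converged) break
  }
  list(pi = pi, loglik = ll, iterations = it)
}

#' Estimate the Dirichlet-multinomial precision of a gene
#'
#' Maximizes the DM profile likelihood over the concentration on a log scale
#' within `[lower, upper]`, with proportions profiled out at every
#' concentration. By default proportions are common to all units (the null
#' model); when `groups` is supplied they are profiled per group (the full
#' model), which is the design used by the gene-level test so that a real
#' usage difference is not absorbed into the dispersion estimate. When the
#' data are under-dispersed relative to the multinomial the profile
#' likelihood is maximized at the boundary and the upper bound is returned.
#'
#' @param gene_counts units x isoforms count matrix for one gene (>= 2
#'   isoforms; units with zero total are ignored).
#' @param groups optional group label per unit; proportions are then
#'   profiled within groups.
#' @param lower,upper search bounds for the concentration.
#' @return the estimated concentration, with attributes `pi` (profiled
#'   proportions at the estimate: a vector, or per-group list when `groups`
#'   is given) and `loglik`.
#' @export
estimate_precision <- function(gene_counts, groups = NULL, lower = 1e-2,
                               upper = 1e6) {
  y <- as.matrix(gene_counts)
  n <- rowSums(y)
  if (!is.null(groups)) groups <- as.character(groups)[n > 0]
  y <- y[n > 0, , drop = FALSE]
  n <- n[n > 0]
  if (nrow(y) < 2) stopf("need >= 2 units with nonzero gene totals")
  if (ncol(y) < 2) stopf("need >= 2 isoforms")
  idx <- if (is.null(groups)) list(seq_len(nrow(y))) else
    split(seq_len(nrow(y)), groups)
  # profile search runs at a looser inner tolerance; the returned fit is
  # re-run at full precision
  # Cox-Reid adjusted profile likelihood: the adjustment compensates for the
  # proportions estimated at each concentration, removing the upward bias of
  # plain profile ML when the design has several groups
  prof <- function(lg, tol = 1e-6, maxit = 100) {
    sum(vapply(idx, function(ix) {
      ys <- y[ix, , drop = FALSE]
      f <- dm_fit_pi(ys, n[ix], exp(lg), tol = tol, maxit = maxit)
      f$loglik + dm_cr_adjust(ys, f$pi, exp(lg))
    }, numeric(1)))
  }
  opt <- optimize(prof, c(log(lower), log(upper)), maximum = TRUE, tol = 0.02)
  lg <- if (prof(log(upper)) >= opt$objective - 1e-6) log(upper) else opt$maximum
  gamma <- exp(lg)
  fits <- lapply(idx, function(ix) dm_fit_pi(y[ix, , drop = FALSE], n[ix], gamma))
  pi <- if (is.null(groups)) fits[[1]]$pi else lapply(fits, `[[`, "pi")
  structure(gamma, pi = pi,
            loglik = sum(vapply(fits, `[[`, numeric(1), "loglik")))
}

#' Dirichlet-multinomial likelihood-ratio test for one gene
#'
#' Fits the null model (one usage simplex shared by all units) and the full
#' model (one simplex per group) at a common concentration estimated by
#' profile likelihood under the full model (held fixed for both fits), and
#' compares them by a likelihood-ratio test with
#' `(n_groups - 1) * (J - 1)` degrees of freedom.
#'
#' @param gene_counts units x isoforms count matrix for one gene.
#' @param group_labels factor/character vector of group per unit (>= 2
#'   groups; units with zero gene total are excluded from the fit).
#' @param gamma optional fixed concentration; estimated when `NULL`.
#' @return object of class `dm_fit` (or an untestable stub with a `reason`
#'   when the gene cannot be tested).
#' @export
fit_dm_gene <- function(gene_counts, group_labels, gamma = NULL) {
  y <- as.matrix(gene_counts)
  stopifnot(length(group_labels) == nrow(y))
  groups <- as.character(group_labels)
  n <- rowSums(y)
  keep <- n > 0
  y <- y[keep, , drop = FALSE]
  n <- n[keep]
  groups <- groups[keep]
  untestable <- function(reason) {
    structure(list(testable = FALSE, reason = reason), class = "dm_fit")
  }
  if (ncol(y) < 2) return(untestable("single isoform"))
  if (length(unique(groups)) < 2) return(untestable("fewer than 2 groups with nonzero units"))
  if (nrow(y) < 2) return(untestable("fewer than 2 units with counts"))
  if (is.null(gamma)) {
    gamma <- as.numeric(estimate_precision(y, groups = groups))
  }
  f <- dm_fit_pi(y, n, gamma)
  pi_null <- f$pi
  ll_null <- f$loglik
  glev <- unique(groups)
  pi_full <- matrix(NA_real_, length(glev), ncol(y),
                    dimnames = list(glev, colnames(y)))
  ll_full <- 0
  for (g in glev) {
    ix <- groups == g
    f <- dm_fit_pi(y[ix, , drop = FALSE], n[ix], gamma, pi0 = pi_null)
    pi_full[g, ] <- f$pi
    ll_full <- ll_full + f$loglik
  }
  lr <- 2 * (ll_full - ll_null)
  if (lr < -1e-6) warning("negative LR statistic clamped to 0")
  lr <- max(0, lr)
  df <- (length(glev) - 1) * (ncol(y) - 1)
  structure(list(
    testable = TRUE, J = ncol(y), groups = groups, gamma = gamma,
    pi_null = pi_null, pi_full = pi_full,
    loglik_null = ll_null, loglik_full = ll_full,
    lr_stat = lr, df = df,
    p_value = pchisq(lr, df, lower.tail = FALSE)
  ), class = "dm_fit")
}

#' @export
print.dm_fit <- function(x, ...) {
  if (!isTRUE(x$testable)) {
    cat("Dirichlet-multinomial fit: untestable (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "Dirichlet-multinomial usage test: %d isoforms, %d groups\n  gamma = %.3g, LR = %.3f (df = %d), p = %.3g\n",
    x$J, nrow(x$pi_full), x$gamma, x$lr_stat, x$df, x$p_value))
  invisible(x)
}

#' Feature-level (per-isoform) usage tests
#'
#' Collapses the gene to isoform-vs-rest counts and runs a beta-binomial
#' likelihood-ratio test (df = n_groups - 1) at the gene's concentration.
#' The effect size is the usage difference: mean per-unit usage in the group
#' of interest minus the mean over the other groups' units; its sign gives
#' the high/low-usage direction.
#'
#' @param fit a testable `dm_fit`.
#' @param gene_counts,group_labels as in [fit_dm_gene()].
#' @param focus group of interest (default: first group label).
#' @return data.frame with isoform, effect, direction, lr, p_value.
#' @export
feature_level_test <- function(fit, gene_counts, group_labels, focus = NULL) {
  stopifnot(inherits(fit, "dm_fit"), isTRUE(fit$testable))
  y <- as.matrix(gene_counts)
  groups <- as.character(group_labels)
  n <- rowSums(y)
  keep <- n > 0
  y <- y[keep, , drop = FALSE]
  n <- n[keep]
  groups <- groups[keep]
  glev <- unique(groups)
  focus <- focus %||% glev[1]
  if (!focus %in% glev) stopf("focus group '%s' not among group labels", focus)
  res <- lapply(seq_len(ncol(y)), function(j) {
    yj <- cbind(y[, j], n - y[, j])
    if (all(yj[, 1] == 0)) {
      return(data.frame(isoform = colnames(y)[j], effect = 0,
                        direction = "low usage", lr = 0, p_value = 1,
                        stringsAsFactors = FALSE))
    }
    f0 <- dm_fit_pi(yj, n, fit$gamma)
    ll1 <- 0
    for (g in glev) {
      ix <- groups == g
      ll1 <- ll1 + dm_fit_pi(yj[ix, , drop = FALSE], n[ix], fit$gamma)$loglik
    }
    lr <- max(0, 2 * (ll1 - f0$loglik))
    u <- y[, j] / n
    eff <- mean(u[groups == focus]) - mean(u[groups != focus])
    data.frame(isoform = colnames(y)[j], effect = eff,
               direction = ifelse(eff > 0, "high usage", "low usage"),
               lr = lr,
               p_value = pchisq(lr, length(glev) - 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Differential isoform usage scan over all genes
#'
#' Runs the gene-level Dirichlet-multinomial LRT and the per-isoform
#' feature-level tests for every testable gene of a pseudobulk matrix under
#' one contrast, and adjusts p-values by Benjamini-Hochberg within the scan.
#'
#' @param pb `pseudobulk_matrix` (or units x isoforms count matrix).
#' @param catalog isoform catalog mapping isoforms to genes.
#' @param groups factor/character of group per unit; units with `NA` are
#'   dropped. At least two groups must remain.
#' @param focus group of interest for feature-level effect signs (default:
#'   first level).
#' @param alpha significance threshold recorded on the result (raw p for
#'   cell-type/age scans, adjusted p for marker discovery).
#' @param use_adjusted whether `significant_genes` is thresholded on the
#'   BH-adjusted p-value rather than the raw one.
#' @return object of class `usage_scan` with `gene_table`, `isoform_table`,
#'   and the contrast metadata.
#' @export
run_usage_scan <- function(pb, catalog, groups, focus = NULL, alpha = 0.05,
                           use_adjusted = FALSE) {
  m <- if (inherits(pb, "pseudobulk_matrix")) pb$counts else as.matrix(pb)
  stopifnot(length(groups) == nrow(m))
  groups <- as.character(groups)
  keep <- !is.na(groups)
  m <- m[keep, , drop = FALSE]
  groups <- groups[keep]
  if (length(unique(groups)) < 2) {
    stopf("contrast must define at least 2 groups with units")
  }
  focus <- focus %||% unique(groups)[1]
  gene <- catalog$gene_id[match(colnames(m), catalog$isoform_id)]
  if (anyNA(gene)) stopf("isoforms absent from the catalog")
  by_gene <- split(seq_len(ncol(m)), gene)

  gene_rows <- vector("list", length(by_gene))
  iso_rows <- vector("list", length(by_gene))
  for (k in seq_along(by_gene)) {
    gid <- names(by_gene)[k]
    cols <- by_gene[[k]]
    if (length(cols) < 2) {
      gene_rows[[k]] <- data.frame(gene_id = gid, J = length(cols),
                                   gamma = NA_real_, lr = NA_real_,
                                   df = NA_integer_, p_value = NA_real_,
                                   reason = "single isoform",
                                   stringsAsFactors = FALSE)
      next
    }
    y <- m[, cols, drop = FALSE]
    ## a group with no expressed units makes the gene untestable for this contrast
    tot_by_group <- tapply(rowSums(y), groups, sum)
    if (any(tot_by_group == 0)) {
      gene_rows[[k]] <- data.frame(gene_id = gid, J = length(cols),
                                   gamma = NA_real_, lr = NA_real_,
                                   df = NA_integer_, p_value = NA_real_,
                                   reason = "a group has no counts",
                                   stringsAsFactors = FALSE)
      next
    }
    fit <- fit_dm_gene(y, groups)
    if (!isTRUE(fit$testable)) {
      gene_rows[[k]] <- data.frame(gene_id = gid, J = length(cols),
                                   gamma = NA_real_, lr = NA_real_,
                                   df = NA_integer_, p_value = NA_real_,
                                   reason = fit$reason, stringsAsFactors = FALSE)
      next
    }
    gene_rows[[k]] <- data.frame(gene_id = gid, J = fit$J, gamma = fit$gamma,
                                 lr = fit$lr_stat, df = fit$df,
                                 p_value = fit$p_value, reason = NA_character_,
                                 stringsAsFactors = FALSE)
    ft <- feature_level_test(fit, y, groups, focus = focus)
    ft$gene_id <- gid
    iso_rows[[k]] <- ft
  }
  gene_table <- do.call(rbind, gene_rows)
  gene_table$p_adj <- bh_adjust(gene_table$p_value)
  isoform_table <- do.call(rbind, iso_rows)
  if (!is.null(isoform_table)) {
    isoform_table$p_adj <- bh_adjust(isoform_table$p_value)
    isoform_table <- isoform_table[, c("gene_id", "isoform", "effect",
                                       "direction", "lr", "p_value", "p_adj")]
  }
  crit <- if (use_adjusted) gene_table$p_adj else gene_table$p_value
  structure(list(
    contrast = list(groups = unique(groups), focus = focus, alpha = alpha,
                    use_adjusted = use_adjusted),
    gene_table = gene_table,
    isoform_table = isoform_table,
    significant_genes = gene_table$gene_id[!is.na(crit) & crit < alpha]
  ), class = "usage_scan")
}

#' @export
print.usage_scan <- function(x, ...) {
  tested <- sum(!is.na(x$gene_table$p_value))
  cat(sprintf(
    "usage scan [%s vs %s]: %d/%d genes testable, %d significant (%s p < %g)\n",
    x$contrast$focus,
    paste(setdiff(x$contrast$groups, x$contrast$focus), collapse = "/"),
    tested, nrow(x$gene_table), length(x$significant_genes),
    if (x$contrast$use_adjusted) "adjusted" else "raw", x$contrast$alpha))
  invisible(x)
}

#' @export
summary.usage_scan <- function(object, ...) {
  gt <- object$gene_table
  out <- gt[order(gt$p_value), ]
  head(out, 20)
}

#' Simulate Dirichlet-multinomial unit counts
#'
#' Draws `n_units` unit count vectors of the given depth from a DM with
#' concentration `gamma` around `pi` (used in calibration and power checks).
#'
#' @param n_units number of units.
#' @param depth total count per unit.
#' @param pi proportion simplex.
#' @param gamma concentration.
#' @return units x isoforms integer matrix.
#' @export
rdirmultinom <- function(n_units, depth, pi, gamma) {
  J <- length(pi)
  G <- matrix(rgamma(n_units * J, shape = rep(gamma * pi, each = n_units)),
              n_units, J)
  P <- G / rowSums(G)
  t(vapply(seq_len(n_units), function(u) {
    as.integer(rmultinom(1, depth, P[u, ]))
  }, integer(J)))
}
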