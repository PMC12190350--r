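#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats coef lm lm.fit median optimize p.adjust pchisq pf prcomp
#'   quantile rbinom rgamma rlnorm rmultinom rnorm rpois runif sd setNames var
#'   wilcox.test dist cor aggregate complete.cases predict
#' @importFrom utils head read.delim write.table
NULL

AGE_CATEGORIES <- c("young", "middle", "old", "geriatric")
CELL_TYPES <- c("neuron", "oligo", "astrocyte", "vascular", "immune", "other")
SEXES <- c("M", "F")
REGIONS <- c("cortex", "hippocampus")

# Age-category bins (months): young <= 8, middle <= 19, old <= 25, else geriatric.
age_category_of <- function(age_months) {
  cut(age_months, breaks = c(-Inf, 8, 19, 25, Inf), labels = AGE_CATEGORIES,
      right = TRUE)
}

# Deterministic child seed derived from a parent seed and an operation label,
# so simulation outputs do not depend on the order operations are called in.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 104729L
  as.integer((as.numeric(seed) * 7919 + h * 31 + 17) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Receiver operating characteristic curve and area under it
#'
#' Computes ROC points (false positive rate, true positive rate) over all
#' score thresholds and the area under the curve by the rank (Mann-Whitney)
#' statistic, which equals the trapezoidal area under the empirical ROC.
#'
#' @param labels binary vector (0/1 or logical); 1 is the positive class.
#' @param scores numeric scores, higher meaning more positive.
#' @return list with `points` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("roc_curve needs both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1L)
  fp <- cumsum(lab == 0L)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  pts <- data.frame(
    fpr = c(0, fp[keep] / n_neg),
    tpr = c(0, tp[keep] / n_pos),
    threshold = c(Inf, sc[keep])
  )
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(points = pts, auc = auc)
}

# Benjamini-Hochberg over non-missing entries, NA preserved.
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
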