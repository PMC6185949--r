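# Sibling polygenic transmission disequilibrium, exact enrichment tests,
# and correlation utilities.

#' Sibling polygenic transmission-disequilibrium test
#'
#' Within each nuclear family containing at least one affected and one
#' unaffected sibling, the deviation is the mean standardized risk score of
#' the affected siblings minus that of the unaffected siblings. Under no
#' transmission disequilibrium the deviations are centred at zero; the test
#' is a two-sided one-sample t-test of the per-family deviations. The mean
#' deviation is reported in cohort-SD units of the score.
#'
#' @param prs a `prs_profile` (see [score_genomewide()]) or a named numeric
#'   vector of cohort-standardized scores.
#' @param families list of nuclear families from
#'   [extract_nuclear_families()].
#' @param affected named logical/0-1 vector of affected status.
#' @return object of class `ptdt_result`: `mean_deviation`, `t`, `p`,
#'   `n_families`, and the per-family table `deviations`. With fewer than two
#'   qualifying families the t statistic and p-value are `NA` and the result
#'   carries `insufficient = TRUE`.
#' @export
ptdt_siblings <- function(prs, families, affected) {
  z <- if (inherits(prs, "prs_profile")) {
    stats::setNames(prs$z, prs$id)
  } else prs
  if (is.null(names(z)) || is.null(names(affected)))
    stop("scores and affected status must be named by individual id")
  aff <- as.logical(affected)
  names(aff) <- names(affected)

  rows <- lapply(families, function(fam) {
    sibs <- fam$children
    sibs <- sibs[sibs %in% names(z) & sibs %in% names(aff) &
                   !is.na(z[sibs]) & !is.na(aff[sibs])]
    a <- sibs[aff[sibs]]
    u <- sibs[!aff[sibs]]
    if (!length(a) || !length(u)) return(NULL)
    data.frame(father = fam$father, mother = fam$mother,
               n_affected = length(a), n_unaffected = length(u),
               deviation = mean(z[a]) - mean(z[u]),
               stringsAsFactors = FALSE)
  })
  dev <- do.call(rbind, rows)
  nf <- if (is.null(dev)) 0L else nrow(dev)
  if (nf == 0L) {
    warning("no nuclear family has both affected and unaffected siblings")
    return(structure(list(mean_deviation = NA_real_, t = NA_real_,
                          p = NA_real_, n_families = 0L, deviations = NULL,
                          insufficient = TRUE), class = "ptdt_result"))
  }
  md <- mean(dev$deviation)
  if (nf < 2L) {
    return(structure(list(mean_deviation = md, t = NA_real_, p = NA_real_,
                          n_families = nf, deviations = dev,
                          insufficient = TRUE), class = "ptdt_result"))
  }
  if (stats::sd(dev$deviation) == 0) {
    # degenerate spread: identical deviations in every family
    tstat <- if (md == 0) 0 else sign(md) * Inf
    pval <- if (md == 0) 1 else 0
  } else {
    tt <- stats::t.test(dev$deviation, mu = 0)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  structure(list(mean_deviation = md, t = tstat, p = pval,
                 n_families = nf, deviations = dev,
                 insufficient = FALSE), class = "ptdt_result")
}

#' @export
print.ptdt_result <- function(x, ...) {
  cat(sprintf("pTDT (affected vs unaffected siblings): mean deviation %.3f",
              x$mean_deviation))
  if (!is.na(x$p)) cat(sprintf(", t = %.3f, p = %.3g", x$t, x$p))
  cat(sprintf(" over %d families\n", x$n_families))
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test with both margins fixed: the two-sided p-value is
#' the total hypergeometric probability of all tables at least as extreme as
#' (i.e. with point probability no larger than) the observed one. The
#' reported odds ratio is the sample odds ratio `ad / bc` (not the
#' conditional MLE).
#'
#' @param counts 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return object of class `fisher_result`: `p`, `odds_ratio` (`Inf` when
#'   `bc = 0` with `ad > 0`, `NA` flagged `degenerate` when a margin is
#'   zero), and the input `counts`.
#' @export
fisher_enrichment <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  if (!all(dim(m) == 2) || any(m < 0) || any(m != round(m)))
    stop("counts must be a 2x2 table of non-negative integers")
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    return(structure(list(p = 1, odds_ratio = NA_real_, counts = m,
                          degenerate = TRUE), class = "fisher_result"))
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[match(a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * cc == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * cc)
  structure(list(p = min(1, p), odds_ratio = or, counts = m,
                 degenerate = FALSE), class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher exact (two-sided): OR = %s, p = %.3g\n",
              format(x$odds_ratio, digits = 4), x$p))
  invisible(x)
}

#' Pearson correlation with pairwise-complete observations
#'
#' Thin wrapper used for score-score matrices and the inbreeding versus
#' risk-score check; returns the correlation together with the two-sided
#' t-based p-value.
#'
#' @param a,b numeric vectors of equal length (NAs dropped pairwise).
#' @return list with `r`, `p`, `n` (complete pairs). Zero-variance input
#'   yields `r = NA` with a warning and `degenerate = TRUE`.
#' @export
correlate <- function(a, b) {
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = n, degenerate = FALSE)
}
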