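# Block-wise local-risk association scan, multiple-testing control,
# cross-trait overlap, and PRS decile profiles.

#' Local genetic-risk association scan over LD blocks
#'
#' Fits the kinship mixed model of phenotype on each non-empty block's
#' standardized local risk score. The family-wise (Bonferroni) threshold is
#' `alpha` divided by the number of blocks actually tested — empty blocks
#' carry no test and are excluded from both the output and the denominator.
#' Blocks with `p < 0.01` form the nominal set, whose summed length as a
#' fraction of the total block length is reported as genome coverage.
#'
#' @param local_prs a `local_prs` object from [score_local()].
#' @param y phenotype vector, ordered as the kinship matrix.
#' @param covariates optional fixed-effect matrix.
#' @param kinship numerator relationship matrix or [kinship_eigen()] object.
#' @param alpha family-wise error target (default 0.05).
#' @param shared_components if `TRUE`, variance components are estimated
#'   once without any block score and reused across blocks (fast mode);
#'   the default refits them per block.
#' @return object of class `scan_result`: list with `table` (block, chrom,
#'   start, end, n_variants, beta, se, p, nominal, significant),
#'   `bonferroni`, `n_tested`, `alpha`, `genome_frac_nominal`.
#' @export
local_risk_scan <- function(local_prs, y, covariates = NULL, kinship,
                            alpha = 0.05, shared_components = FALSE) {
  stopifnot(inherits(local_prs, "local_prs"))
  ke <- if (inherits(kinship, "kin_eigen")) kinship else kinship_eigen(kinship)
  use <- !local_prs$empty & apply(!is.na(local_prs$z), 2, all)
  if (!any(use)) stop("all blocks are empty; nothing to scan")
  fixed <- NULL
  if (shared_components) {
    her <- estimate_heritability(y, covariates, ke)
    fixed <- if (her$sigma_e2 > 0) her$sigma_g2 / her$sigma_e2 else 1e5
  }
  rows <- lapply(which(use), function(k) {
    fit <- fit_lmm_association(y, local_prs$z[, k], covariates, ke,
                               fixed_ratio = fixed)
    data.frame(block = colnames(local_prs$z)[k], beta = fit$beta,
               se = fit$se, p = fit$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- merge(local_prs$blocks, tab, by = "block", sort = FALSE)
  tab$n_variants <- local_prs$n_variants[match(tab$block,
                                               local_prs$blocks$block)]
  n_tested <- nrow(tab)
  bonf <- alpha / n_tested
  tab$significant <- tab$p < bonf
  tab$nominal <- tab$p < 0.01
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  len <- local_prs$blocks$end - local_prs$blocks$start
  nom_len <- sum(len[match(tab$block[tab$nominal],
                           local_prs$blocks$block)])
  structure(list(table = tab, bonferroni = bonf, n_tested = n_tested,
                 alpha = alpha,
                 genome_frac_nominal = nom_len / sum(len)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "Local-risk scan: %d blocks tested, Bonferroni p < %.3g: %d; p < 0.01: %d (%.2f%% of genome)\n",
    x$n_tested, x$bonferroni, sum(x$table$significant),
    sum(x$table$nominal), 100 * x$genome_frac_nominal))
  invisible(x)
}

#' Cross-trait overlap of nominal scan regions
#'
#' Given per-trait scan results on the same block set, lists for each block
#' the traits in which it is nominally associated (p < 0.01) and tallies
#' region counts: total nominal regions summed over traits, unique blocks,
#' and blocks shared by two or more traits.
#'
#' @param scans named list of `scan_result` objects, one per trait.
#' @return object of class `overlap_report`: list with `by_block`
#'   (data.frame `block`, `traits`, `n_traits`), `n_regions`, `n_unique`,
#'   `n_shared`.
#' @export
overlap_traits <- function(scans) {
  stopifnot(length(scans) >= 1, !is.null(names(scans)))
  blocksets <- lapply(scans, function(s) sort(s$table$block))
  for (b in blocksets[-1]) {
    if (!identical(b, blocksets[[1]]))
      stop("scans were not run on the same block set")
  }
  nominal <- lapply(scans, function(s) s$table$block[s$table$nominal])
  all_nom <- sort(unique(unlist(nominal)))
  traits_of <- vapply(all_nom, function(b) {
    paste(names(scans)[vapply(nominal, function(v) b %in% v, logical(1))],
          collapse = ";")
  }, "")
  by_block <- data.frame(block = all_nom, traits = unname(traits_of),
                         n_traits = lengths(strsplit(unname(traits_of),
                                                     ";")),
                         stringsAsFactors = FALSE)
  structure(list(by_block = by_block,
                 n_regions = sum(lengths(nominal)),
                 n_unique = length(all_nom),
                 n_shared = sum(by_block$n_traits >= 2)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "Overlap: %d nominal regions over traits, %d unique, %d shared by >1 trait\n",
    x$n_regions, x$n_unique, x$n_shared))
  invisible(x)
}

#' Phenotype composition across risk-score deciles
#'
#' Ranks individuals by risk score (ties broken by stable input order),
#' splits them into `n_groups` equal-rank groups, and reports the percentage
#' of each diagnostic category per group along with the percentage affected.
#' A rank-correlation trend statistic (Spearman, decile index versus
#' affected fraction) summarises whether affection rises across deciles.
#'
#' @param prs a `prs_profile` or named numeric score vector.
#' @param pheno phenotype table (`id`, `category`), or a named category
#'   vector.
#' @param n_groups number of quantile groups (default 10).
#' @return object of class `decile_profile`: list with `table` (decile,
#'   n, percentage per category, pct_affected), `trend_rho`, `trend_p`.
#' @export
decile_profile <- function(prs, pheno, n_groups = 10) {
  score <- if (inherits(prs, "prs_profile")) {
    stats::setNames(prs$z, prs$id)
  } else prs
  category <- if (is.data.frame(pheno)) {
    stats::setNames(pheno$category, pheno$id)
  } else pheno
  ids <- intersect(names(score), names(category))
  if (length(ids) < n_groups)
    stop("need at least ", n_groups, " scored individuals")
  score <- score[ids]
  category <- category[ids]
  rk <- rank(score, ties.method = "first")
  dec <- ceiling(rk * n_groups / length(ids))
  cats <- sort(unique(category))
  tab <- data.frame(decile = seq_len(n_groups),
                    n = as.integer(table(factor(dec, 1:n_groups))))
  for (cl in cats) {
    tab[[paste0("pct_", cl)]] <- vapply(seq_len(n_groups), function(g) {
      100 * mean(category[dec == g] == cl)
    }, numeric(1))
  }
  tab$pct_affected <- vapply(seq_len(n_groups), function(g) {
    100 * mean(category[dec == g] != "unaffected")
  }, numeric(1))
  ct <- suppressWarnings(
    stats::cor.test(tab$decile, tab$pct_affected, method = "spearman"))
  structure(list(table = tab, trend_rho = unname(ct$estimate),
                 trend_p = ct$p.value),
            class = "decile_profile")
}

#' @export
print.decile_profile <- function(x, ...) {
  cat(sprintf("Decile profile: trend rho = %.3f (p = %.3g)\n",
              x$trend_rho, x$trend_p))
  print(x$table)
  invisible(x)
}
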