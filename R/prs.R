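# Polygenic risk scoring: allele harmonisation, LD clumping, p-value
# thresholding, genome-wide and LD-block-local scores.

.palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Harmonise GWAS weights with a genotype matrix
#'
#' Matches summary-statistic variants to the cohort by id, orients each
#' effect onto the ALT dosage (effect allele = ALT keeps the sign; effect
#' allele = REF flips it), and drops strand-ambiguous A/T and C/G variants
#' as well as variants whose alleles do not match the cohort's REF/ALT pair.
#'
#' @param sumstats data.frame with columns `SNP`, `A1` (effect allele),
#'   `A2` (other allele), `BETA`, `SE`, `P` (see [load_sumstats()]).
#' @param geno a `geno` object.
#' @return object of class `prs_weights`: data.frame (`id`, `chrom`, `pos`,
#'   `beta`, `p`) of ALT-oriented weights, with an attribute `log` counting
#'   matched / flipped / palindromic / mismatched / unmatched variants.
#' @export
align_alleles <- function(sumstats, geno) {
  stopifnot(inherits(geno, "geno"))
  v <- geno$variants
  idx <- match(sumstats$SNP, v$id)
  matched <- !is.na(idx)
  ss <- sumstats[matched, , drop = FALSE]
  vi <- v[idx[matched], , drop = FALSE]
  a1 <- toupper(ss$A1); a2 <- toupper(ss$A2)

  pal <- .palindromic(a1, a2)
  same <- a1 == vi$alt & a2 == vi$ref
  flip <- a1 == vi$ref & a2 == vi$alt
  mism <- !(same | flip)

  keep <- !pal & !mism
  beta <- ifelse(flip, -ss$BETA, ss$BETA)[keep]
  out <- data.frame(id = vi$id[keep], chrom = vi$chrom[keep],
                    pos = vi$pos[keep], beta = beta, p = ss$P[keep],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) stop("no summary-statistic variant could be harmonised")
  attr(out, "log") <- c(matched = sum(matched), used = nrow(out),
                        flipped = sum(flip & keep),
                        palindromic_dropped = sum(pal),
                        mismatched_dropped = sum(mism & !pal),
                        unmatched = sum(!matched))
  class(out) <- c("prs_weights", "data.frame")
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the smallest-p not-yet-clumped variant as an index and
#' removes all variants within `window_kb` of it (same chromosome) whose
#' squared dosage correlation with the index exceeds `r2_max`. Ties in p are
#' broken by genomic position (lowest chromosome, then lowest position), so
#' the result is independent of input ordering.
#'
#' @param weights a `prs_weights` object from [align_alleles()].
#' @param geno a `geno` object supplying the dosages from which pairwise r^2
#'   is computed.
#' @param r2_max r^2 above which a neighbour is clumped away (default 0.1).
#' @param window_kb window half-width in kilobases (default 250).
#' @return the retained subset of `weights` (index variants), in p order,
#'   with attribute `n_clumped`.
#' @export
ld_clump <- function(weights, geno, r2_max = 0.1, window_kb = 250) {
  stopifnot(inherits(geno, "geno"))
  w <- weights[weights$id %in% colnames(geno$dosage), , drop = FALSE]
  ord <- order(w$p, w$chrom, w$pos)
  w <- w[ord, , drop = FALSE]
  D <- geno$dosage[, w$id, drop = FALSE]
  alive <- rep(TRUE, nrow(w))
  keep <- logical(nrow(w))
  win <- window_kb * 1000
  for (i in seq_len(nrow(w))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive & w$chrom == w$chrom[i] &
                    abs(w$pos - w$pos[i]) <= win)
    if (length(near)) {
      r <- suppressWarnings(
        stats::cor(D[, i], D[, near, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- as.vector(r)^2
      r2[is.na(r2)] <- 0
      alive[near[r2 > r2_max]] <- FALSE
    }
  }
  out <- w[keep, , drop = FALSE]
  attr(out, "log") <- attr(weights, "log")
  attr(out, "n_clumped") <- nrow(w) - nrow(out)
  class(out) <- c("prs_weights", "data.frame")
  out
}

.score_dosage <- function(geno, ids) {
  D <- geno$dosage[, ids, drop = FALSE]
  if (anyNA(D)) {
    p <- geno$founder_freq
    fill <- if (!is.null(p)) 2 * p[ids] else colMeans(D, na.rm = TRUE)
    for (j in seq_len(ncol(D))) {
      nas <- is.na(D[, j])
      if (any(nas)) D[nas, j] <- fill[j]
    }
  }
  D
}

#' Genome-wide polygenic risk score
#'
#' Raw score: `raw_i = sum_j beta_j * dosage_ij` over the harmonised
#' variants with `p <= p_threshold`; missing dosages are mean-imputed from
#' founder ALT frequencies. Scores are also standardized to z-scores across
#' the cohort.
#'
#' @param weights a `prs_weights` object (optionally clumped).
#' @param geno a `geno` object.
#' @param p_threshold inclusion threshold on the GWAS p-value, in (0, 1].
#' @return object of class `prs_profile`: data.frame (`id`, `raw`, `z`)
#'   with attributes `threshold`, `n_variants` and `degenerate` (TRUE when
#'   the raw scores have zero variance, in which case `z` is NA).
#' @export
score_genomewide <- function(weights, geno, p_threshold = 1) {
  stopifnot(inherits(geno, "geno"), p_threshold > 0, p_threshold <= 1)
  w <- weights[weights$p <= p_threshold, , drop = FALSE]
  if (!nrow(w)) stop("no variants pass p threshold ", p_threshold)
  D <- .score_dosage(geno, w$id)
  raw <- as.vector(D %*% w$beta)
  s <- stats::sd(raw)
  degen <- !is.finite(s) || s == 0
  if (degen) warning("raw scores have zero variance; z set to NA")
  out <- data.frame(id = rownames(geno$dosage), raw = raw,
                    z = if (degen) NA_real_ else (raw - mean(raw)) / s,
                    stringsAsFactors = FALSE)
  structure(out, threshold = p_threshold, n_variants = nrow(w),
            degenerate = degen, class = c("prs_profile", "data.frame"))
}

#' Per-LD-block local polygenic risk scores
#'
#' Partitions the scored variants over a fixed set of approximately
#' independent LD blocks and computes one raw score per individual per block
#' from the variants falling inside it, plus per-block cohort-standardized
#' z-scores. Because the blocks partition the genome, raw block scores sum
#' to the genome-wide raw score over the same variant set.
#'
#' @inheritParams score_genomewide
#' @param blocks block table from [load_blocks()] (columns `block`, `chrom`,
#'   `start`, `end`; 0-based half-open intervals). A variant at 1-based
#'   position `pos` belongs to the block with `start <= pos - 1 < end`.
#' @return object of class `local_prs`: list with `raw` and `z` matrices
#'   (individuals x blocks), `n_variants` per block, `blocks`, `empty`
#'   (logical flag per block) and `uncovered` (variant ids in no block).
#' @export
score_local <- function(weights, geno, blocks, p_threshold = 1) {
  stopifnot(inherits(geno, "geno"))
  w <- weights[weights$p <= p_threshold, , drop = FALSE]
  if (!nrow(w)) stop("no variants pass p threshold ", p_threshold)
  bid <- rep(NA_character_, nrow(w))
  for (k in seq_len(nrow(blocks))) {
    hit <- w$chrom == blocks$chrom[k] &
      (w$pos - 1) >= blocks$start[k] & (w$pos - 1) < blocks$end[k]
    bid[hit] <- blocks$block[k]
  }
  uncovered <- w$id[is.na(bid)]
  n_ind <- nrow(geno$dosage)
  B <- nrow(blocks)
  raw <- matrix(0, n_ind, B,
                dimnames = list(rownames(geno$dosage), blocks$block))
  nvar <- integer(B)
  for (k in seq_len(B)) {
    sel <- which(!is.na(bid) & bid == blocks$block[k])
    nvar[k] <- length(sel)
    if (length(sel)) {
      D <- .score_dosage(geno, w$id[sel])
      raw[, k] <- as.vector(D %*% w$beta[sel])
    }
  }
  z <- apply(raw, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(NA_real_, length(col))
    else (col - mean(col)) / s
  })
  dimnames(z) <- dimnames(raw)
  structure(list(raw = raw, z = z, n_variants = nvar, blocks = blocks,
                 empty = nvar == 0, uncovered = uncovered,
                 threshold = p_threshold),
            class = "local_prs")
}

#' @export
print.local_prs <- function(x, ...) {
  cat("Local PRS:", nrow(x$raw), "individuals x", ncol(x$raw), "blocks (",
      sum(x$empty), "empty );", length(x$uncovered),
      "variant(s) outside all blocks\n")
  invisible(x)
}

#' Association across a grid of p-value thresholds
#'
#' Scores the cohort at each threshold and fits the kinship mixed model of
#' phenotype on the standardized score, emulating high-resolution PRS
#' thresholding. All thresholds are reported; the best is flagged by
#' association p-value.
#'
#' @inheritParams score_genomewide
#' @param thresholds numeric vector of inclusion thresholds.
#' @param y phenotype (0/1 or quantitative), ordered as the kinship matrix.
#' @param kinship numerator relationship matrix or [kinship_eigen()] object.
#' @param covariates optional fixed-effect matrix.
#' @return list with `table` (threshold, n_variants, beta, se, p, best) and
#'   `best_threshold`.
#' @export
threshold_scan <- function(weights, geno, thresholds, y, kinship,
                           covariates = NULL) {
  stopifnot(length(thresholds) >= 1)
  ke <- if (inherits(kinship, "kin_eigen")) kinship else kinship_eigen(kinship)
  rows <- lapply(sort(thresholds), function(th) {
    prof <- score_genomewide(weights, geno, th)
    fit <- fit_lmm_association(y, prof$z, covariates, ke)
    data.frame(threshold = th, n_variants = attr(prof, "n_variants"),
               beta = fit$beta, se = fit$se, p = fit$p)
  })
  tab <- do.call(rbind, rows)
  tab$best <- seq_len(nrow(tab)) == which.min(tab$p)
  list(table = tab, best_threshold = tab$threshold[tab$best][1])
}
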