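# Genotype container shared by the simulator, the file readers and the
# scoring engine.

#' Construct a genotype matrix object
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt` and optionally `cm` (map position in centimorgans).
#'   Positions must be strictly increasing within a chromosome.
#' @param dosage numeric matrix of ALT dosages in `[0, 2]`, individuals in
#'   rows (rownames = ids), variants in columns (colnames = variant ids).
#' @param founder_freq optional ALT allele frequencies among founders, used
#'   for mean imputation of missing dosages during scoring.
#' @param haplotypes optional list with matrices `pat` and `mat` (0/1 alleles
#'   per transmitted haplotype), kept by the simulator.
#' @return object of class `geno`.
#' @export
geno_matrix <- function(variants, dosage, founder_freq = NULL,
                        haplotypes = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(variants))
    stop("dosage columns and variant table rows differ")
  colnames(dosage) <- variants$id
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < -1e-8 || rng[2] > 2 + 1e-8)
    stop("dosages must lie in [0, 2]")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  structure(list(variants = variants, dosage = dosage,
                 founder_freq = founder_freq, haplotypes = haplotypes),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$dosage)
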