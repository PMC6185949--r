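# Pedigree data model, numerator relationship matrix, inbreeding, and
# family-structure extraction.

.norm_parent <- function(p) {
  p <- as.character(p)
  p[p %in% c("0", "", "NA", "na", ".")] <- NA_character_
  p
}

.norm_sex <- function(s) {
  s <- tolower(as.character(s))
  out <- rep("unknown", length(s))
  out[s %in% c("1", "m", "male")] <- "male"
  out[s %in% c("2", "f", "female")] <- "female"
  out
}

#' Validate a raw pedigree table
#'
#' Checks structural integrity of a pedigree (unique ids, known parents, no
#' individual its own ancestor) and derives founder flags and generation
#' numbers. Generation is the longest path from any founder, so a child is
#' always in a strictly later generation than both parents.
#'
#' @param x data.frame with columns `id`, `father`, `mother`, `sex`
#'   (aliases `individual_id`, `father_id`, `mother_id` are accepted).
#'   Missing parents are `NA`, `"0"` or `""`. Sex may be coded
#'   `1`/`2`/`0` or `male`/`female`/`unknown`.
#' @return A `ped` object: a data.frame with columns `id`, `father`,
#'   `mother`, `sex`, `founder`, `generation`.
#' @examples
#' trio <- data.frame(id = c("F", "M", "C"), father = c(NA, NA, "F"),
#'                    mother = c(NA, NA, "M"), sex = c(1, 2, 1))
#' ped <- validate_pedigree(trio)
#' ped$generation  # 0 0 1
#' @export
validate_pedigree <- function(x) {
  stopifnot(is.data.frame(x))
  names(x) <- tolower(names(x))
  alias <- c(individual_id = "id", iid = "id", father_id = "father",
             mother_id = "mother", pat = "father", mat = "mother")
  for (a in names(alias)) {
    if (a %in% names(x) && !(alias[[a]] %in% names(x)))
      names(x)[names(x) == a] <- alias[[a]]
  }
  miss <- setdiff(c("id", "father", "mother", "sex"), names(x))
  if (length(miss))
    stop("pedigree table lacks column(s): ", paste(miss, collapse = ", "))

  id <- as.character(x$id)
  if (anyNA(id) || any(id == "")) stop("missing individual id")
  if (anyDuplicated(id)) {
    stop("duplicate id: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  father <- .norm_parent(x$father)
  mother <- .norm_parent(x$mother)
  for (p in c(father, mother)) {
    if (!is.na(p) && !(p %in% id)) stop("parent id unknown: ", p)
  }
  if (any(!is.na(father) & father == id) || any(!is.na(mother) & mother == id))
    stop("cycle: individual listed as its own parent")

  founder <- is.na(father) & is.na(mother)
  n <- length(id)
  fi <- match(father, id)
  mi <- match(mother, id)

  # longest-path generation by iterative peeling; failure to converge = cycle
  gen <- ifelse(founder, 0L, NA_integer_)
  repeat {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      pg <- c(if (!is.na(fi[i])) gen[fi[i]] else -1L,
              if (!is.na(mi[i])) gen[mi[i]] else -1L)
      if (!anyNA(pg)) {
        gen[i] <- max(pg) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed)
      stop("cycle detected in pedigree involving: ",
           paste(id[todo], collapse = ", "))
  }

  out <- data.frame(id = id, father = father, mother = mother,
                    sex = .norm_sex(x$sex), founder = founder,
                    generation = gen, stringsAsFactors = FALSE)
  class(out) <- c("ped", "data.frame")
  out
}

#' @export
print.ped <- function(x, n = 10L, ...) {
  cat("Pedigree:", nrow(x), "individuals,", sum(x$founder), "founders,",
      max(x$generation) + 1L, "generations\n")
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("... with", nrow(x) - n, "more individuals\n")
  invisible(x)
}

#' Numerator relationship matrix
#'
#' Computes the additive (numerator) relationship matrix A = 2*Phi by the
#' recursive tabular method: processing individuals in generation order,
#' `A[i, j] = (A[father(i), j] + A[mother(i), j]) / 2` for earlier j and
#' `A[i, i] = 1 + A[father(i), mother(i)] / 2`, so the diagonal is
#' `1 + f` with `f` the pedigree inbreeding coefficient. A is the covariance
#' kernel used by all mixed-model fits in this package.
#'
#' @param ped a `ped` object from [validate_pedigree()].
#' @return symmetric numeric matrix with dimnames `ped$id`, in input order.
#' @export
additive_relationship <- function(ped) {
  stopifnot(inherits(ped, "ped"))
  n <- nrow(ped)
  id <- ped$id
  fi <- match(ped$father, id)
  mi <- match(ped$mother, id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in order(ped$generation)) {
    if (ped$founder[i]) {
      A[i, i] <- 1
      next
    }
    fr <- if (!is.na(fi[i])) A[fi[i], ] else numeric(n)
    mr <- if (!is.na(mi[i])) A[mi[i], ] else numeric(n)
    row <- 0.5 * (fr + mr)
    A[i, ] <- row
    A[, i] <- row
    A[i, i] <- 1 + if (!is.na(fi[i]) && !is.na(mi[i]))
      0.5 * A[fi[i], mi[i]] else 0
  }
  A
}

#' Pedigree inbreeding coefficients from a relationship matrix
#'
#' @param A numerator relationship matrix from [additive_relationship()].
#' @return named vector `f = diag(A) - 1`.
#' @export
pedigree_inbreeding <- function(A) {
  diag(A) - 1
}

#' Genotypic inbreeding by excess homozygosity
#'
#' Method-of-moments inbreeding statistic: for each individual,
#' `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is the observed count of
#' homozygous genotypes over its non-missing loci and
#' `E_hom = sum_j (1 - 2 p_j (1 - p_j))` is the Hardy-Weinberg expectation at
#' the supplied allele frequencies. Positive values indicate more homozygous
#' genotypes than expected.
#'
#' @param dosage individuals x variants matrix of ALT dosages; values are
#'   rounded to \{0, 1, 2\} before counting, `NA` allowed.
#' @param freq ALT allele frequencies in (0, 1), one per variant. Frequencies
#'   estimated from founders only avoid pedigree-induced bias (see
#'   [founder_allele_freq()]).
#' @return named vector of per-individual F; `NA` (with a warning) when an
#'   individual has no non-missing loci.
#' @export
excess_homozygosity <- function(dosage, freq) {
  dosage <- as.matrix(dosage)
  stopifnot(ncol(dosage) == length(freq))
  if (any(freq <= 0 | freq >= 1))
    stop("allele frequencies must be in (0, 1)")
  d <- round(dosage)
  hom <- d == 0 | d == 2
  obs <- rowSums(hom, na.rm = TRUE)
  ehom_j <- 1 - 2 * freq * (1 - freq)
  present <- !is.na(d)
  L <- rowSums(present)
  exp_hom <- as.vector(present %*% ehom_j)
  F <- (obs - exp_hom) / (L - exp_hom)
  F[L == 0] <- NA_real_
  if (anyNA(F)) warning("individuals with all loci missing: F set to NA")
  names(F) <- rownames(dosage)
  F
}

#' ALT allele frequencies from founders
#'
#' @param geno a `geno` object or dosage matrix (individuals x variants).
#' @param ped a `ped` object; frequencies use founder rows only.
#' @return vector of ALT frequencies, clipped away from 0 and 1 by half an
#'   allele count so downstream formulas stay finite.
#' @export
founder_allele_freq <- function(geno, ped) {
  dosage <- if (inherits(geno, "geno")) geno$dosage else as.matrix(geno)
  fids <- intersect(ped$id[ped$founder], rownames(dosage))
  if (!length(fids)) stop("no founders present in genotype matrix")
  p <- colMeans(dosage[fids, , drop = FALSE], na.rm = TRUE) / 2
  eps <- 1 / (4 * length(fids))
  pmin(pmax(p, eps), 1 - eps)
}

#' Both inbreeding measures for every individual
#'
#' Emits the pedigree coefficient `f` (from the relationship-matrix diagonal)
#' and the genotypic excess-homozygosity `F` side by side; analyses that
#' correlate inbreeding with risk scores can use either.
#'
#' @param ped a `ped` object.
#' @param geno optional `geno` object (or dosage matrix) for the genotypic F.
#' @param freq optional allele frequencies; defaults to founder frequencies.
#' @return data.frame with columns `id`, `f_pedigree` and (when genotypes are
#'   given) `F_genotypic`.
#' @export
inbreeding_coefficients <- function(ped, geno = NULL, freq = NULL) {
  A <- additive_relationship(ped)
  out <- data.frame(id = ped$id, f_pedigree = unname(diag(A) - 1),
                    stringsAsFactors = FALSE)
  if (!is.null(geno)) {
    dosage <- if (inherits(geno, "geno")) geno$dosage else as.matrix(geno)
    if (is.null(freq)) freq <- founder_allele_freq(dosage, ped)
    F <- excess_homozygosity(dosage, freq)
    out$F_genotypic <- F[match(out$id, names(F))]
  }
  out
}

#' Extract nuclear families
#'
#' One family per distinct (father, mother) pair with at least one child.
#' Individuals can appear in several families (child in one, parent in
#' another).
#'
#' @param ped a `ped` object.
#' @return list of `nuclear_family` objects, each a list with `father`,
#'   `mother`, `children`.
#' @export
extract_nuclear_families <- function(ped) {
  stopifnot(inherits(ped, "ped"))
  has_both <- !is.na(ped$father) & !is.na(ped$mother)
  if (!any(has_both)) return(list())
  key <- paste(ped$father[has_both], ped$mother[has_both], sep = "\r")
  kids <- split(ped$id[has_both], key)
  out <- lapply(names(kids), function(k) {
    par <- strsplit(k, "\r", fixed = TRUE)[[1]]
    structure(list(father = par[1], mother = par[2],
                   children = unname(kids[[k]])),
              class = "nuclear_family")
  })
  out[order(vapply(out, `[[`, "", "father"),
            vapply(out, `[[`, "", "mother"))]
}

#' Flag pioneer descendants versus married-in individuals
#'
#' Individuals reachable by descent from either of the two pioneer members
#' (including the pioneers themselves) are "in family"; all others are
#' "married in". Used for the in-family versus married-in risk-score
#' contrast.
#'
#' @param ped a `ped` object.
#' @param pioneer_ids character vector of pioneer ids (usually length 2).
#' @return data.frame with columns `id`, `in_family` (logical) and `group`
#'   (`"in_family"` / `"married_in"`).
#' @export
founder_descendant_flags <- function(ped, pioneer_ids) {
  stopifnot(inherits(ped, "ped"))
  if (!all(pioneer_ids %in% ped$id))
    stop("pioneer id unknown: ",
         paste(setdiff(pioneer_ids, ped$id), collapse = ", "))
  inf <- ped$id %in% pioneer_ids
  for (i in order(ped$generation)) {
    if (inf[i]) next
    fi <- match(ped$father[i], ped$id)
    mi <- match(ped$mother[i], ped$id)
    inf[i] <- (!is.na(fi) && inf[fi]) || (!is.na(mi) && inf[mi])
  }
  data.frame(id = ped$id, in_family = inf,
             group = ifelse(inf, "in_family", "married_in"),
             stringsAsFactors = FALSE)
}

#' Read a FAM-style pedigree file
#'
#' Whitespace-delimited table with columns family_id, individual_id,
#' father_id, mother_id, sex (1/2/0) and phenotype; `0` encodes a missing
#' parent.
#'
#' @param path file path.
#' @return a `ped` object; the family id and phenotype columns are kept as
#'   attributes `family_id` and `phenotype`.
#' @export
read_fam <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "id", "father",
                                         "mother", "sex", "phenotype"))
  ped <- validate_pedigree(tab[, c("id", "father", "mother", "sex")])
  attr(ped, "family_id") <- tab$family_id
  attr(ped, "phenotype") <- tab$phenotype
  ped
}

#' Write a FAM-style pedigree file
#'
#' @param ped a `ped` object.
#' @param path output path.
#' @param family_id single family label or per-individual vector.
#' @param phenotype per-individual phenotype column (default -9 = missing).
#' @export
write_fam <- function(ped, path, family_id = "FAM1", phenotype = NULL) {
  stopifnot(inherits(ped, "ped"))
  sex_code <- c(male = 1L, female = 2L, unknown = 0L)[ped$sex]
  if (is.null(phenotype)) phenotype <- rep(-9L, nrow(ped))
  tab <- data.frame(family_id, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    sex_code, phenotype)
  utils::write.table(tab, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
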