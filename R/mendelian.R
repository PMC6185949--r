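# Genotype-based Mendelian disease calling, founder-enrichment filtering,
# LoF burden, and carrier-frequency tables.

.hard_call <- function(dosage) round(as.matrix(dosage))

#' Call Mendelian disease status from genotypes
#'
#' Applies the allelic-state rule: for dominant diseases a dosage of 1 or 2
#' (heterozygous or homozygous) predicts disease; for recessive diseases
#' only dosage 2 (homozygous) predicts disease while dosage 1 marks a
#' carrier. Dosages are hard-called by rounding (threshold 0.5) first.
#'
#' @param geno a `geno` object or dosage matrix (individuals x variants).
#' @param catalog data.frame with columns `variant`, `gene`, `disease`,
#'   `mode` (`"dominant"` / `"recessive"`), `effect_class`.
#' @return object of class `mendelian_calls`: list with `states` (long
#'   data.frame `id`, `variant`, `disease`, `mode`, `state` in
#'   non_carrier / carrier / predicted_affected), `disease_status` (`id` x
#'   `disease` predicted status) and `skipped` (catalog variants absent from
#'   the genotypes).
#' @export
call_mendelian_status <- function(geno, catalog) {
  stopifnot(all(c("variant", "disease", "mode") %in% names(catalog)))
  if (anyDuplicated(catalog$variant)) stop("catalog variant ids not unique")
  if (!all(catalog$mode %in% c("dominant", "recessive")))
    stop("inheritance mode must be 'dominant' or 'recessive'")
  dosage <- if (inherits(geno, "geno")) geno$dosage else as.matrix(geno)
  present <- catalog$variant %in% colnames(dosage)
  skipped <- catalog$variant[!present]
  cat2 <- catalog[present, , drop = FALSE]
  if (!nrow(cat2)) stop("no catalog variant present in genotype matrix")
  D <- .hard_call(dosage[, cat2$variant, drop = FALSE])
  n <- nrow(D)
  rows <- lapply(seq_len(nrow(cat2)), function(k) {
    d <- D[, k]
    state <- rep("non_carrier", n)
    if (cat2$mode[k] == "dominant") {
      state[!is.na(d) & d >= 1] <- "predicted_affected"
    } else {
      state[!is.na(d) & d == 1] <- "carrier"
      state[!is.na(d) & d == 2] <- "predicted_affected"
    }
    state[is.na(d)] <- NA_character_
    data.frame(id = rownames(D), variant = cat2$variant[k],
               disease = cat2$disease[k], mode = cat2$mode[k],
               state = state, stringsAsFactors = FALSE)
  })
  states <- do.call(rbind, rows)
  diseases <- unique(cat2$disease)
  ds <- vapply(diseases, function(dz) {
    sub <- states[states$disease == dz, , drop = FALSE]
    tapply(sub$state == "predicted_affected", sub$id, any)[rownames(D)]
  }, logical(n))
  ds <- matrix(ds, nrow = n, dimnames = list(rownames(D), diseases))
  structure(list(states = states, disease_status = ds, skipped = skipped,
                 catalog = cat2),
            class = "mendelian_calls")
}

#' @export
print.mendelian_calls <- function(x, ...) {
  cat("Mendelian calls:", nrow(x$disease_status), "individuals x",
      ncol(x$disease_status), "diseases;",
      sum(x$states$state == "predicted_affected", na.rm = TRUE),
      "predicted-affected states;", length(x$skipped),
      "catalog variant(s) skipped\n")
  invisible(x)
}

#' Founder-enrichment variant filter
#'
#' Keeps variants that are common inside the pedigree but rare in every
#' external reference cohort: internal frequency above `t_internal` and all
#' external frequencies below `t_external` (defaults 5% and 2%).
#'
#' @param internal named vector of within-pedigree allele frequencies.
#' @param external vector, or matrix/data.frame with one column per
#'   reference cohort, aligned to the same variants.
#' @param t_internal,t_external thresholds.
#' @return character vector of retained variant ids.
#' @export
founder_enriched_filter <- function(internal, external,
                                    t_internal = 0.05, t_external = 0.02) {
  ext <- as.matrix(external)
  if (nrow(ext) != length(internal))
    stop("internal and external frequencies not aligned")
  keep <- internal > t_internal & apply(ext < t_external, 1, all)
  names(internal)[keep]
}

#' Loss-of-function burden in disease genes
#'
#' Per individual: the number of LoF variants carried (dosage >= 1 after
#' hard calling) in disease genes, and the number of disease genes predicted
#' completely inactivated, defined as harbouring a homozygous (dosage 2) LoF
#' variant.
#'
#' @param annotation data.frame with columns `variant`, `gene`, `lof`
#'   (logical).
#' @param geno a `geno` object or dosage matrix.
#' @param disease_genes character vector of disease gene symbols.
#' @return data.frame (`id`, `n_lof_carried`, `n_genes_inactivated`).
#' @export
lof_burden <- function(annotation, geno, disease_genes) {
  dosage <- if (inherits(geno, "geno")) geno$dosage else as.matrix(geno)
  ann <- annotation[annotation$lof & annotation$gene %in% disease_genes &
                      annotation$variant %in% colnames(dosage), ,
                    drop = FALSE]
  ids <- rownames(dosage)
  if (!nrow(ann)) {
    return(data.frame(id = ids, n_lof_carried = 0L,
                      n_genes_inactivated = 0L, stringsAsFactors = FALSE))
  }
  D <- .hard_call(dosage[, ann$variant, drop = FALSE])
  carried <- rowSums(D >= 1, na.rm = TRUE)
  hom <- D == 2
  hom[is.na(hom)] <- FALSE
  inact <- apply(hom, 1, function(h) length(unique(ann$gene[h])))
  data.frame(id = ids, n_lof_carried = as.integer(carried),
             n_genes_inactivated = as.integer(inact),
             stringsAsFactors = FALSE)
}

#' Carrier frequencies by phenotype group
#'
#' Percentage of carriers (dosage >= 1: carrier or predicted-affected state)
#' of each catalog variant within each phenotype group, in the layout of a
#' per-variant frequency table with one column per group (e.g. unaffected /
#' BPI-BPII / other psychiatric phenotype).
#'
#' @param calls a `mendelian_calls` object.
#' @param groups named list of individual-id vectors; groups may subset the
#'   cohort.
#' @return data.frame with `variant`, `disease` and one percentage column
#'   per group. Empty groups give `NA` with a warning.
#' @export
carrier_frequency_table <- function(calls, groups) {
  stopifnot(inherits(calls, "mendelian_calls"))
  st <- calls$states
  st$is_carrier <- st$state %in% c("carrier", "predicted_affected")
  vars <- unique(st$variant)
  out <- data.frame(variant = vars,
                    disease = calls$catalog$disease[
                      match(vars, calls$catalog$variant)],
                    stringsAsFactors = FALSE)
  for (gname in names(groups)) {
    ids <- groups[[gname]]
    if (!length(ids)) {
      warning("empty group: ", gname)
      out[[gname]] <- NA_real_
      next
    }
    sub <- st[st$id %in% ids, , drop = FALSE]
    out[[gname]] <- vapply(vars, function(v) {
      s <- sub[sub$variant == v, , drop = FALSE]
      100 * sum(s$is_carrier, na.rm = TRUE) / length(ids)
    }, numeric(1))
  }
  out
}
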