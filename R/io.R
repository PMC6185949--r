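# Readers and writers for the standard interchange formats (VCF, FAM, TSV
# summary statistics, BED blocks, catalogs, phenotypes) plus the YAML-driven
# pipeline entry point.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Load genotype dosages from a VCF
#'
#' Per-sample dosages are taken from the `DS` FORMAT field when present,
#' otherwise derived from `GT` as the ALT allele count; missing genotypes
#' become `NA`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param ped optional `ped` object used to compute founder allele
#'   frequencies for downstream imputation.
#' @return a `geno` object.
#' @export
load_genotypes <- function(path, ped = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (!nrow(fix)) stop("VCF contains no variant records")
  if (ncol(vcf@gt) < 2) stop("VCF contains no samples")
  variants <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  fmt <- vcf@gt[1, "FORMAT"]
  if (grepl("\\bDS\\b", fmt)) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dosage <- t(ds)
  } else if (grepl("\\bGT\\b", fmt)) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    cnt <- function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    }
    dosage <- t(apply(gt, c(1, 2), cnt))
  } else stop("VCF FORMAT provides neither DS nor GT")
  rownames(dosage) <- colnames(vcf@gt)[-1]
  variants$cm <- variants$pos / 1e6
  g <- geno_matrix(variants, dosage)
  if (!is.null(ped) && any(ped$id[ped$founder] %in% rownames(dosage)))
    g$founder_freq <- founder_allele_freq(g, ped)
  g
}

#' Write genotype dosages as a VCF
#'
#' Minimal VCF 4.2 with a single `DS` FORMAT field carrying the ALT dosage.
#'
#' @param geno a `geno` object.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "geno"))
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$dosage)), collapse = "\t")), con)
  D <- t(geno$dosage)
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- ifelse(is.na(D[j, ]), ".", sprintf("%.6g", D[j, ]))
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "DS", ds), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Load GWAS summary statistics
#'
#' Tab-delimited with header; requires columns `SNP`, `A1` (effect allele),
#' `A2`, `BETA`, `SE`, `P` (`CHR`, `BP` optional). Validates `P` in (0, 1]
#' and distinct alleles.
#'
#' @param path file path.
#' @return data.frame of summary statistics.
#' @export
load_sumstats <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("SNP", "A1", "A2", "BETA", "SE", "P"), names(ss))
  if (length(miss))
    stop("summary statistics lack column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(ss$P)) || any(ss$P <= 0 | ss$P > 1))
    stop("p-values must lie in (0, 1]")
  if (any(toupper(ss$A1) == toupper(ss$A2)))
    stop("effect and other allele identical for some variant")
  ss
}

#' @rdname load_sumstats
#' @param sumstats data.frame to write.
#' @export
write_sumstats <- function(sumstats, path) .write_tsv(sumstats, path)

#' Load LD-block definitions from BED
#'
#' BED is 0-based half-open; blocks must not overlap within a chromosome.
#'
#' @param path BED file (3 or 4 columns; the 4th is the block name).
#' @return data.frame (`block`, `chrom`, `start`, `end`).
#' @export
load_blocks <- function(path) {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED needs at least chrom, start, end")
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed$chrom <- as.character(bed$chrom)
  bed$block <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
    sprintf("%s:%d-%d", bed$chrom, bed$start, bed$end)
  if (any(bed$end <= bed$start)) stop("BED interval with end <= start")
  for (ch in unique(bed$chrom)) {
    sub <- bed[bed$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    bad <- which(sub$start[-1] < sub$end[-nrow(sub)])
    if (length(bad)) {
      stop(sprintf("overlapping blocks on chromosome %s: %s and %s",
                   ch, sub$block[bad[1]], sub$block[bad[1] + 1]))
    }
  }
  bed[, c("block", "chrom", "start", "end")]
}

#' @rdname load_blocks
#' @param blocks block table to write (BED with name column).
#' @export
write_blocks <- function(blocks, path) {
  utils::write.table(blocks[, c("chrom", "start", "end", "block")], path,
                     quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Load a Mendelian variant catalog
#'
#' TSV with header; requires `variant`, `gene`, `disease`, `mode`
#' (dominant/recessive) and `effect_class` columns.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
load_catalog <- function(path) {
  cat_ <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("variant", "gene", "disease", "mode", "effect_class"),
                  names(cat_))
  if (length(miss))
    stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cat_$variant)) stop("catalog variant ids not unique")
  if (!all(cat_$mode %in% c("dominant", "recessive")))
    stop("inheritance mode must be 'dominant' or 'recessive'")
  cat_
}

#' Load a phenotype table
#'
#' TSV with header; requires `id` and `category` columns (`liability` and
#' `affected` optional).
#'
#' @param path file path.
#' @return data.frame.
#' @export
load_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "category"), names(ph))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  ph$id <- as.character(ph$id)
  ph
}

#' Run the full analysis pipeline from a configuration
#'
#' Simulates (or loads) a study, then runs every analysis stage — kinship,
#' inbreeding, genome-wide and per-threshold PRS association, heritability
#' per diagnostic model, sibling pTDT, Mendelian calling with carrier
#' frequency tables, association rules, per-trait local-risk scans with
#' cross-trait overlap, and the PRS decile profile — writing each result as
#' TSV plus a provenance JSON (seed, configuration, package version, input
#' checksums) into `outdir`. All randomness derives from `config$seed`, so a
#' rerun reproduces every output byte for byte.
#'
#' @param config path to a YAML configuration or an equivalent list.
#'   Recognised fields: `seed`, `outdir`, `simulate` (arguments to
#'   [sim_config()]), `prs` (`thresholds`, `clump_r2`, `clump_window_kb`),
#'   `scan` (`alpha`), `phenotype_model`.
#' @param outdir output directory (overrides the config's `outdir`).
#' @return (invisibly) list of in-memory results and output paths.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("an output directory is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  prs_cfg <- utils::modifyList(
    list(thresholds = c(0.001, 0.01, 0.05, 0.1, 0.5, 1),
         clump_r2 = 0.1, clump_window_kb = 250),
    if (is.null(config$prs)) list() else config$prs)
  alpha <- if (is.null(config$scan$alpha)) 0.05 else config$scan$alpha
  model <- if (is.null(config$phenotype_model)) "broad_extended" else
    config$phenotype_model

  scfg <- do.call(sim_config, c(list(seed = seed),
                                if (is.null(config$simulate)) list()
                                else config$simulate))
  study <- simulate_study(scfg)
  p <- function(f) file.path(outdir, f)

  # inputs as they would arrive from disk
  write_fam(study$ped, p("pedigree.fam"),
            phenotype = study$phenotypes$affected + 1L)
  write_genotypes_vcf(study$geno, p("genotypes.vcf"))
  write_blocks(study$blocks, p("ld_blocks.bed"))
  .write_tsv(study$catalog, p("mendelian_catalog.tsv"))
  .write_tsv(study$phenotypes, p("phenotypes.tsv"))
  for (tr in names(study$sumstats))
    write_sumstats(study$sumstats[[tr]], p(sprintf("sumstats_%s.tsv", tr)))

  ke <- study$kin_eigen
  y <- phenotype_model(study$phenotypes, model)
  inb <- inbreeding_coefficients(study$ped, study$geno)
  .write_tsv(inb, p("inbreeding.tsv"))

  results <- list(study = study)
  assoc_rows <- list()
  scans <- list()
  profiles <- list()
  for (tr in names(study$sumstats)) {
    w <- align_alleles(study$sumstats[[tr]], study$geno)
    w <- ld_clump(w, study$geno, prs_cfg$clump_r2, prs_cfg$clump_window_kb)
    ts <- threshold_scan(w, study$geno, prs_cfg$thresholds, y, ke)
    .write_tsv(ts$table, p(sprintf("threshold_scan_%s.tsv", tr)))
    prof <- score_genomewide(w, study$geno, ts$best_threshold)
    profiles[[tr]] <- prof
    .write_tsv(data.frame(id = prof$id, trait = tr,
                          threshold = attr(prof, "threshold"),
                          raw = prof$raw, z = prof$z),
               p(sprintf("prs_%s.tsv", tr)))
    fit <- fit_lmm_association(y, prof$z, kinship = ke)
    assoc_rows[[tr]] <- data.frame(
      trait = tr, phenotype_model = model,
      threshold = ts$best_threshold, beta = fit$beta, se = fit$se,
      p = fit$p, sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
      n = fit$n)
    lp <- score_local(w, study$geno, study$blocks, ts$best_threshold)
    sc <- local_risk_scan(lp, y, kinship = ke, alpha = alpha)
    scans[[tr]] <- sc
    .write_tsv(sc$table, p(sprintf("scan_%s.tsv", tr)))
  }
  .write_tsv(do.call(rbind, assoc_rows), p("association.tsv"))

  her_rows <- lapply(c("narrow", "broad", "broad_extended"), function(m) {
    hy <- phenotype_model(study$phenotypes, m)
    h <- estimate_heritability(hy, kinship = ke)
    data.frame(phenotype_model = m, h2 = h$h2, lrt = h$lrt, p = h$p,
               sigma_g2 = h$sigma_g2, sigma_e2 = h$sigma_e2, n = h$n)
  })
  .write_tsv(do.call(rbind, her_rows), p("heritability.tsv"))

  fams <- extract_nuclear_families(study$ped)
  ptdt <- ptdt_siblings(profiles[[1]], fams, y)
  .write_tsv(data.frame(mean_deviation = ptdt$mean_deviation, t = ptdt$t,
                        p = ptdt$p, n_families = ptdt$n_families),
             p("ptdt.tsv"))

  calls <- call_mendelian_status(study$geno, study$catalog)
  .write_tsv(calls$states, p("mendelian_calls.tsv"))
  grp <- list(
    unaffected = study$phenotypes$id[study$phenotypes$category ==
                                       "unaffected"],
    bpi_bpii = study$phenotypes$id[study$phenotypes$category %in%
                                     c("BPI", "BPII")],
    other_psychiatric = study$phenotypes$id[study$phenotypes$category %in%
                                              c("MDDR", "minor")])
  .write_tsv(carrier_frequency_table(calls, grp), p("carrier_freq.tsv"))

  tx <- build_transactions(calls, study$phenotypes, model)
  rules <- mine_rules(tx)
  .write_tsv(rules, p("rules.tsv"))

  ov <- overlap_traits(scans)
  .write_tsv(ov$by_block, p("overlap.tsv"))
  dec <- decile_profile(profiles[[1]], study$phenotypes)
  .write_tsv(dec$table, p("decile.tsv"))

  input_files <- c("pedigree.fam", "genotypes.vcf", "ld_blocks.bed",
                   "mendelian_catalog.tsv", "phenotypes.tsv",
                   sprintf("sumstats_%s.tsv", names(study$sumstats)))
  prov <- list(
    package = "pedprs",
    version = as.character(utils::packageVersion("pedprs")),
    seed = seed, phenotype_model = model, prs = prs_cfg,
    scan = list(alpha = alpha),
    simulate = scfg[setdiff(names(scfg), "category_props")],
    category_props = as.list(scfg$category_props),
    input_checksums = as.list(tools::md5sum(file.path(outdir, input_files))))
  names(prov$input_checksums) <- input_files
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(c(results,
              list(association = do.call(rbind, assoc_rows),
                   heritability = do.call(rbind, her_rows), ptdt = ptdt,
                   calls = calls, rules = rules, scans = scans,
                   overlap = ov, decile = dec, profiles = profiles,
                   outdir = outdir)))
}
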