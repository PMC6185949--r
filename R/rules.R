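# Association-rule mining of phenotype / Mendelian-disease co-occurrence.
#
# Transactions are per-individual item sets; rules are exhaustively
# enumerated over restricted antecedent -> consequent pairs with exact
# counting, so no support-pruning heuristics are involved.

#' Build per-individual transactions
#'
#' One transaction per individual: a single phenotype item
#' (`affected_<model>` or `unaffected`) plus one item per genetically
#' inferred Mendelian disease. By default only predicted-affected disease
#' states contribute items; `level = "carrier"` also admits carrier states
#' (as `carrier_<disease>` items).
#'
#' @param calls a `mendelian_calls` object.
#' @param pheno phenotype table (columns `id`, `category`).
#' @param model diagnostic model passed to [phenotype_model()].
#' @param level `"predicted_affected"` (default) or `"carrier"`.
#' @return object of class `transactions`: named list of character vectors
#'   with attributes `phenotype_items` and `disease_items`.
#' @export
build_transactions <- function(calls, pheno,
                               model = c("broad_extended", "broad",
                                         "narrow"),
                               level = c("predicted_affected", "carrier")) {
  stopifnot(inherits(calls, "mendelian_calls"))
  model <- match.arg(model)
  level <- match.arg(level)
  y <- phenotype_model(pheno, model)
  ids <- rownames(calls$disease_status)
  missing_ph <- setdiff(ids, names(y))
  if (length(missing_ph)) {
    warning("individuals without phenotype excluded: ",
            paste(missing_ph, collapse = ", "))
    ids <- setdiff(ids, missing_ph)
  }
  aff_item <- paste0("affected_", model)
  st <- calls$states
  tx <- lapply(ids, function(i) {
    items <- if (y[[i]] == 1L) aff_item else "unaffected"
    sub <- st[st$id == i, , drop = FALSE]
    dz <- unique(sub$disease[sub$state == "predicted_affected" &
                               !is.na(sub$state)])
    items <- c(items, sort(dz))
    if (level == "carrier") {
      ca <- unique(sub$disease[sub$state == "carrier" & !is.na(sub$state)])
      items <- c(items, paste0("carrier_", sort(ca)))
    }
    items
  })
  names(tx) <- ids
  disease_items <- sort(unique(unlist(lapply(tx, setdiff,
                                             c(aff_item, "unaffected")))))
  structure(tx, phenotype_items = c(aff_item, "unaffected"),
            disease_items = disease_items, class = "transactions")
}

#' @export
print.transactions <- function(x, ...) {
  cat("Transactions:", length(x), "individuals;",
      length(attr(x, "disease_items")), "disease item(s)\n")
  invisible(x)
}

#' Mine single-antecedent association rules
#'
#' Exhaustively enumerates rules `A -> C` with antecedents restricted to
#' phenotype items and consequents to disease items (by default), computing
#' exact support (`count(A and C) / N`), confidence
#' (`count(A and C) / count(A)`) and lift
#' (`confidence / (count(C) / N)`) by counting. Rules are ranked by lift.
#'
#' @param tx a `transactions` object (or plain list of character vectors).
#' @param antecedents candidate antecedent items (default: the transaction
#'   set's phenotype items).
#' @param consequents candidate consequent items (default: disease items).
#' @param min_support,min_confidence inclusion thresholds (defaults 0.01 /
#'   0.01, low enough to retain weak-support comorbidity rules).
#' @return data.frame (`antecedent`, `consequent`, `n_joint`,
#'   `n_antecedent`, `n_consequent`, `support`, `confidence`, `lift`)
#'   ordered by decreasing lift.
#' @export
mine_rules <- function(tx, antecedents = NULL, consequents = NULL,
                       min_support = 0.01, min_confidence = 0.01) {
  if (!length(tx)) stop("empty transaction set")
  N <- length(tx)
  if (is.null(antecedents)) antecedents <- attr(tx, "phenotype_items")
  if (is.null(consequents)) consequents <- attr(tx, "disease_items")
  if (is.null(antecedents) || is.null(consequents))
    stop("antecedent/consequent vocabularies must be supplied")
  has <- function(item) vapply(tx, function(t) item %in% t, logical(1))
  hasA <- vapply(antecedents, has, logical(N))
  hasC <- vapply(consequents, has, logical(N))
  if (N == 1L) {
    hasA <- matrix(hasA, 1, dimnames = list(NULL, antecedents))
    hasC <- matrix(hasC, 1, dimnames = list(NULL, consequents))
  }
  rows <- list()
  for (a in antecedents) {
    nA <- sum(hasA[, a])
    if (nA == 0) next
    for (cn in consequents) {
      nC <- sum(hasC[, cn])
      if (nC == 0) next
      nAC <- sum(hasA[, a] & hasC[, cn])
      supp <- nAC / N
      conf <- nAC / nA
      if (supp < min_support || conf < min_confidence) next
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = a, consequent = cn, n_joint = nAC,
        n_antecedent = nA, n_consequent = nC, support = supp,
        confidence = conf, lift = conf / (nC / N),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(antecedent = character(), consequent = character(),
                      n_joint = integer(), n_antecedent = integer(),
                      n_consequent = integer(), support = numeric(),
                      confidence = numeric(), lift = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$lift, out$antecedent, out$consequent), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
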