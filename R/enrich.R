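#' Per-protein fold enrichment (bait vs control)
#'
#' Pseudo-counted intensity ratio `(bait + pseudo) / (control + pseudo)`
#' per protein, finite for all rows including zero-intensity controls.
#' Rows sharing a `protein_id` are aggregated by summing intensities
#' first (label-free quantitation sums ion intensities per protein).
#'
#' @param table Data frame with columns `protein_id`, `bait_intensity`,
#'   `control_intensity` (non-negative), optional `category`.
#' @param pseudo Intensity floor, > 0; default `"auto"` uses the smallest
#'   nonzero intensity in the table.
#' @return Data frame with one row per protein: `protein_id`, `bait_intensity`,
#'   `control_intensity`, `fold`, plus `category` when present.
#' @export
fold_enrichment <- function(table, pseudo = "auto") {
  d <- as.data.frame(table)
  req <- c("protein_id", "bait_intensity", "control_intensity")
  if (!all(req %in% names(d))) stop("table needs columns ", paste(req, collapse = ", "))
  if (any(!is.finite(d$bait_intensity)) || any(!is.finite(d$control_intensity)) ||
      any(d$bait_intensity < 0) || any(d$control_intensity < 0))
    stop("intensities must be finite and non-negative")
  if (identical(pseudo, "auto")) {
    nz <- c(d$bait_intensity, d$control_intensity)
    nz <- nz[nz > 0]
    if (length(nz) == 0) stop("all intensities zero; supply pseudo explicitly")
    pseudo <- min(nz)
  }
  if (!is.numeric(pseudo) || pseudo <= 0) stop("pseudo must be > 0")
  agg <- stats::aggregate(cbind(bait_intensity, control_intensity) ~ protein_id,
                          data = d, FUN = sum)
  if ("category" %in% names(d)) {
    cats <- d$category[!duplicated(d$protein_id)]
    names(cats) <- d$protein_id[!duplicated(d$protein_id)]
    agg$category <- unname(cats[as.character(agg$protein_id)])
  }
  agg$fold <- (agg$bait_intensity + pseudo) / (agg$control_intensity + pseudo)
  attr(agg, "pseudo") <- pseudo
  agg
}

#' Differentially enriched protein (DEP) filter
#'
#' Proteins whose fold enrichment meets the cut, `fold >= threshold`
#' (inclusive; a "2-fold greater" cut keeps proteins at exactly 2.0).
#'
#' @param folds Data frame from [fold_enrichment()], or a named numeric
#'   vector of folds.
#' @param threshold Positive fold cutoff, default 2.
#' @return Character vector of protein ids passing the filter, with
#'   attribute `n` (the count).
#' @export
dep_filter <- function(folds, threshold = 2) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  if (is.data.frame(folds)) {
    ids <- as.character(folds$protein_id)
    f <- folds$fold
  } else {
    ids <- names(folds) %||% as.character(seq_along(folds))
    f <- as.numeric(folds)
  }
  keep <- ids[f >= threshold]
  attr(keep, "n") <- length(keep)
  keep
}

#' Per-protein ratio of fold enrichments across two conditions
#'
#' For proteins quantified in both conditions (e.g. intact microtubules at
#' 25 C vs depolymerized at 4 C), the ratio `fold_A / fold_B`; proteins
#' seen in only one condition are reported separately, not ratioed.
#'
#' @param table_a,table_b Data frames from [fold_enrichment()] (or raw
#'   intensity tables, which are passed through it with `pseudo`).
#' @param pseudo Pseudo-count forwarded when raw tables are given.
#' @return List with `ratios` (data frame: protein_id, fold_a, fold_b,
#'   ratio) and `only_a`, `only_b` (ids absent from the other condition).
#' @export
condition_enrichment_ratio <- function(table_a, table_b, pseudo = "auto") {
  fa <- if ("fold" %in% names(table_a)) as.data.frame(table_a) else
    fold_enrichment(table_a, pseudo)
  fb <- if ("fold" %in% names(table_b)) as.data.frame(table_b) else
    fold_enrichment(table_b, pseudo)
  shared <- intersect(fa$protein_id, fb$protein_id)
  if (length(shared) == 0) stop("conditions share no protein ids")
  ia <- match(shared, fa$protein_id); ib <- match(shared, fb$protein_id)
  ratios <- data.frame(protein_id = shared,
                       fold_a = fa$fold[ia],
                       fold_b = fb$fold[ib],
                       ratio = fa$fold[ia] / fb$fold[ib])
  list(ratios = ratios,
       only_a = setdiff(fa$protein_id, shared),
       only_b = setdiff(fb$protein_id, shared))
}

#' Category fractions of a protein set
#'
#' Fraction of each annotation category (tubulin isotypes, MT-associated
#' proteins, motors, ...) among the labelled proteins; fractions sum to 1.
#'
#' @param categories Character vector of category labels, one per protein
#'   (NA or empty labels are rejected).
#' @return Named numeric vector of fractions.
#' @export
category_fractions <- function(categories) {
  categories <- as.character(categories)
  if (length(categories) == 0) stop("empty protein set")
  if (any(is.na(categories) | categories == ""))
    stop("every protein must carry a category label")
  tab <- table(categories)
  out <- as.numeric(tab) / length(categories)
  names(out) <- names(tab)
  out
}
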