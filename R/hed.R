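# HLA evolutionary divergence: per-site mean Grantham distance between the
# two peptide-binding-domain sequences carried at a locus, aggregated per
# class and globally, then dichotomized against healthy-control medians.

HED_SLOTS <- c("A", "B", "C", "DRB1", "DQB1", "DPB1", "class1", "class2", "global")

hed_col <- function(slot) paste0("HED_", slot)

#' Per-site mean Grantham divergence between two aligned sequences
#'
#' The divergence of a sequence pair is the mean Grantham distance over
#' aligned positions. Positions where either sequence carries the unknown
#' residue `X` are excluded and the denominator is the number of retained
#' positions, so unknowns neither inflate nor dilute the score.
#'
#' @param seq_a,seq_b Equal-length amino-acid strings (single-letter code).
#' @param matrix Grantham distance table.
#' @return A single non-negative number; 0 for identical sequences.
#' @examples
#' sequence_divergence("AAAA", "AAAS")  # = grantham A-S distance / 4
#' @export
sequence_divergence <- function(seq_a, seq_b, matrix = grantham_matrix()) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(a) != length(b)) {
    stop("sequence length mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  keep <- a != "X" & b != "X"
  if (!any(keep)) {
    stop("no comparable positions (all masked by 'X')", call. = FALSE)
  }
  mean(grantham_distance(a[keep], b[keep], matrix))
}

# Divergence for allele-name pairs with memoisation across a cohort: cohorts
# reuse a small allele pool, so each unordered pair is computed once.
pair_divergence_cache <- function(genotypes, locus, dict, matrix) {
  a1 <- genotypes[[paste0(locus, "_1")]]
  a2 <- genotypes[[paste0(locus, "_2")]]
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  key <- paste(lo, hi, sep = "|")
  uk <- !duplicated(key)
  vals <- mapply(function(x, y) {
    if (x == y) 0 else
      sequence_divergence(dict_lookup(dict, x), dict_lookup(dict, y), matrix)
  }, lo[uk], hi[uk])
  unname(vals[match(key, key[uk])])
}

#' Compute HED profiles for a genotype table
#'
#' Per-locus HED is the [sequence_divergence()] of the two allele sequences
#' at each of the six HED loci; `HED_class1` is the mean over A/B/C,
#' `HED_class2` the mean over DRB1/DQB1/DPB1, and `HED_global` the
#' unweighted mean of all six locus scores. A homozygous locus scores
#' exactly 0.
#'
#' @param genotypes An `hla_genotypes` data frame (see
#'   [read_hla_genotypes()]); all six HED loci must be typed.
#' @param dict An `allele_dict` covering every allele present.
#' @param matrix Grantham distance table.
#' @return Data frame `hed_table`: `subject_id`, `HED_A` .. `HED_DPB1`,
#'   `HED_class1`, `HED_class2`, `HED_global`.
#' @export
hed_table <- function(genotypes, dict, matrix = grantham_matrix()) {
  missing_loci <- setdiff(hed_loci(), genotype_loci(genotypes))
  if (length(missing_loci)) {
    stop("genotypes lack HED locus/loci: ", paste(missing_loci, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(subject_id = genotypes$subject_id, stringsAsFactors = FALSE)
  for (locus in hed_loci()) {
    out[[hed_col(locus)]] <-
      pair_divergence_cache(genotypes, locus, dict, matrix)
  }
  out$HED_class1 <- rowMeans(out[hed_col(class1_loci())])
  out$HED_class2 <- rowMeans(out[hed_col(class2_loci())])
  out$HED_global <- rowMeans(out[hed_col(hed_loci())])
  class(out) <- c("hed_table", "data.frame")
  out
}

#' Single-subject HED profile
#'
#' Convenience wrapper around [hed_table()] for one genotype row.
#'
#' @inheritParams hed_table
#' @return One-row `hed_table` data frame.
#' @export
hed_profile <- function(genotypes, dict, matrix = grantham_matrix()) {
  stopifnot(nrow(genotypes) == 1L)
  hed_table(genotypes, dict, matrix)
}

#' Healthy-control 50th-percentile HED cutoffs
#'
#' For every score slot (six loci, two class means, global) the cutoff is
#' the median of the control cohort values, computed with the
#' linear-interpolation quantile convention (`stats::quantile` type 7).
#'
#' @param control_hed An `hed_table` of reference (healthy-control)
#'   profiles; at least 2 rows.
#' @param source Label recording where the cutoffs came from.
#' @return A `hed_cutoffs` object: named numeric vector over the nine score
#'   slots with a `source` attribute.
#' @export
hed_cutoffs <- function(control_hed, source = "healthy-controls") {
  if (nrow(control_hed) < 2L) {
    stop("need at least 2 control profiles to define cutoffs", call. = FALSE)
  }
  cuts <- vapply(HED_SLOTS, function(s)
    unname(stats::quantile(control_hed[[hed_col(s)]], 0.5, type = 7)), 0)
  structure(cuts, source = source, class = "hed_cutoffs")
}

#' Dichotomize HED profiles against reference cutoffs
#'
#' A slot is `"high"` iff its score strictly exceeds the cutoff; a score
#' equal to the cutoff is `"low"` ("high divergence" means strictly above
#' the reference median).
#'
#' @param hed An `hed_table`.
#' @param cutoffs A `hed_cutoffs` object (or named numeric covering the
#'   nine score slots).
#' @return Data frame: `subject_id` plus `HED_<slot>_cat` factor columns
#'   with levels `low`, `high`.
#' @export
hed_dichotomize <- function(hed, cutoffs) {
  missing_keys <- setdiff(HED_SLOTS, names(cutoffs))
  if (length(missing_keys)) {
    stop("cutoffs missing slot(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(subject_id = hed$subject_id, stringsAsFactors = FALSE)
  for (s in HED_SLOTS) {
    out[[paste0(hed_col(s), "_cat")]] <-
      factor(ifelse(hed[[hed_col(s)]] > cutoffs[[s]], "high", "low"),
             levels = c("low", "high"))
  }
  out
}

#' @export
print.hed_cutoffs <- function(x, ...) {
  cat("HED 50th-percentile cutoffs (source: ", attr(x, "source"), ")\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
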