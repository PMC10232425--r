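# Somatic HLA lesion landscape: lesion taxonomy, patient-level frequency
# tabulation by timepoint / donor type / relapse timing, and myeloid
# co-mutation enrichment. Lesion calls are consumed pre-called; the variant
# calling itself is out of scope.

#' Lesion category and timepoint vocabularies
#' @return Character vectors of the closed category / timepoint lists.
#' @export
lesion_categories <- function() {
  c("missense", "nonsense", "frameshift", "splicing", "UTR", "intronic", "loss")
}

#' @rdname lesion_categories
#' @export
lesion_timepoints <- function() {
  c("diagnosis", "post_chemo_relapse", "post_hct_relapse")
}

#' Read a somatic HLA lesion table
#'
#' TSV with columns `patient_id`, `timepoint`, `allele`, `category` and an
#' optional `vaf` (variant allele fraction in `[0, 1]`). Categories and
#' timepoints are validated against the closed vocabularies; allele names
#' must parse and fall within the eleven typed loci.
#'
#' @param path File path or a data frame in the same layout.
#' @return Validated data frame of lesion calls.
#' @export
read_lesion_table <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, colClasses = "character", strip.white = TRUE)
  need <- c("patient_id", "timepoint", "allele", "category")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("lesion table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_tp <- !(df$timepoint %in% lesion_timepoints())
  if (any(bad_tp)) {
    stop("unknown timepoint in row(s) ",
         paste(which(bad_tp), collapse = ", "), ": ",
         paste(unique(df$timepoint[bad_tp]), collapse = ", "), call. = FALSE)
  }
  bad_cat <- !(df$category %in% lesion_categories())
  if (any(bad_cat)) {
    stop("unknown lesion category in row(s) ",
         paste(which(bad_cat), collapse = ", "), ": ",
         paste(unique(df$category[bad_cat]), collapse = ", "), call. = FALSE)
  }
  df$allele <- normalize_hla_allele(df$allele)
  if ("vaf" %in% names(df)) {
    df$vaf <- as.numeric(df$vaf)
    if (any(!is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1))) {
      stop("vaf outside [0, 1]", call. = FALSE)
    }
  }
  df
}

# nearest integer, half away from zero (round() is banker's)
percent_half_up <- function(num, den) {
  ifelse(den == 0, NA_real_, floor(100 * num / den + 0.5))
}

#' Tabulate lesion frequencies over an assayed-patient table
#'
#' Frequencies are patient-level: a patient with one or more lesions at an
#' assayed (patient, timepoint) counts once in the numerator. The
#' mutation-vs-loss breakdown instead counts lesions (`loss` vs any
#' mutation category). Percentages are rounded to the nearest integer,
#' half away from zero.
#'
#' @param lesions Lesion table (see [read_lesion_table()]).
#' @param patients Assayed-patient table: one row per assayed (patient,
#'   timepoint), columns `patient_id`, `timepoint`, plus grouping
#'   covariates such as `donor_type`. Every lesion must match an assayed
#'   row.
#' @param group_by Grouping column of `patients` (default `"timepoint"`).
#' @return Data frame: `group`, `n_lesioned`, `n_assayed`, `percent`,
#'   `n_mutation_lesions`, `n_loss_lesions`, `empty` (TRUE when no patient
#'   was assayed in the group).
#' @export
lesion_tabulate <- function(lesions, patients, group_by = "timepoint") {
  if (!group_by %in% names(patients)) {
    stop("grouping column ", sQuote(group_by), " absent from patient table",
         call. = FALSE)
  }
  pkey <- paste(patients$patient_id, patients$timepoint)
  lkey <- paste(lesions$patient_id, lesions$timepoint)
  orphan <- !(lkey %in% pkey)
  if (any(orphan)) {
    stop("lesion(s) for unassayed patient/timepoint: ",
         paste(unique(lkey[orphan]), collapse = "; "), call. = FALSE)
  }
  grp <- patients[[group_by]]
  lesions <- unique(lesions[c("patient_id", "timepoint", "allele", "category")])
  lgrp <- grp[match(paste(lesions$patient_id, lesions$timepoint), pkey)]
  levels_ <- if (is.factor(grp)) levels(grp) else unique(as.character(grp))
  rows <- lapply(levels_, function(g) {
    in_g <- as.character(grp) == g
    les_g <- lesions[as.character(lgrp) == g, , drop = FALSE]
    n_assayed <- sum(in_g)
    n_lesioned <- length(unique(paste(les_g$patient_id, les_g$timepoint)))
    data.frame(group = g, n_lesioned = n_lesioned, n_assayed = n_assayed,
               percent = percent_half_up(n_lesioned, n_assayed),
               n_mutation_lesions = sum(les_g$category != "loss"),
               n_loss_lesions = sum(les_g$category == "loss"),
               empty = n_assayed == 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Early versus late relapse lesion frequencies
#'
#' Splits post-transplant-relapse patients at a relapse-time threshold:
#' late iff time strictly greater than `threshold` months (a relapse at
#' exactly the threshold is early).
#'
#' @param lesions Lesion table.
#' @param patients Assayed-patient table; post-HCT-relapse rows must carry
#'   a numeric `relapse_time_months` column.
#' @param threshold Months; default 6.
#' @return Two-row tabulation (groups `early`, `late`) as from
#'   [lesion_tabulate()].
#' @export
lesion_early_late <- function(lesions, patients, threshold = 6) {
  post <- patients[patients$timepoint == "post_hct_relapse", , drop = FALSE]
  if (anyNA(post$relapse_time_months)) {
    stop("relapse_time_months missing for patient(s): ",
         paste(post$patient_id[is.na(post$relapse_time_months)],
               collapse = ", "), call. = FALSE)
  }
  post$.phase <- factor(ifelse(post$relapse_time_months > threshold,
                               "late", "early"), levels = c("early", "late"))
  les <- lesions[lesions$timepoint == "post_hct_relapse", , drop = FALSE]
  lesion_tabulate(les, post, group_by = ".phase")
}

#' Myeloid co-mutation enrichment in HLA-altered relapses
#'
#' For each myeloid gene, patients at the chosen timepoint are cross
#' classified as HLA-altered (any lesion) versus HLA wild type, and
#' gene-mutated versus not; the 2x2 table is tested with a two-sided
#' Fisher exact test and p-values are Benjamini-Hochberg adjusted across
#' genes. The displayed odds ratio uses the Haldane-Anscombe 0.5
#' continuity correction (the p-value comes from the uncorrected table).
#' A gene mutated in nobody (or everybody) is degenerate: reported with
#' `odds_ratio = 1`, `p_value = 1` and flagged, with a warning.
#'
#' @param lesions Lesion table.
#' @param myeloid Myeloid mutation table: `patient_id`, `timepoint`,
#'   `gene` (plus anything else, ignored).
#' @param patients Assayed-patient table.
#' @param timepoint Timepoint analyzed (default `"post_hct_relapse"`).
#' @param genes Genes to test; defaults to all genes observed in `myeloid`.
#' @return Data frame: `gene`, `n_alt_mut`, `n_alt_wt`, `n_wt_mut`,
#'   `n_wt_wt`, `odds_ratio`, `p_value`, `q_value`, `degenerate`.
#' @export
comutation_enrichment <- function(lesions, myeloid, patients,
                                  timepoint = "post_hct_relapse",
                                  genes = NULL) {
  pats <- patients$patient_id[patients$timepoint == timepoint]
  altered <- pats %in% lesions$patient_id[lesions$timepoint == timepoint]
  if (!any(altered) || all(altered)) {
    stop("need at least one HLA-altered and one wild-type patient at ",
         timepoint, call. = FALSE)
  }
  my <- myeloid[myeloid$timepoint == timepoint &
                  myeloid$patient_id %in% pats, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(my$gene))
  rows <- lapply(genes, function(g) {
    mut <- pats %in% my$patient_id[my$gene == g]
    a <- sum(altered & mut);  b <- sum(altered & !mut)
    c_ <- sum(!altered & mut); d <- sum(!altered & !mut)
    degenerate <- (a + c_ == 0L) || (b + d == 0L)
    if (degenerate) {
      warning("degenerate 2x2 stratum for gene ", g,
              " (mutated in nobody or everybody)", call. = FALSE)
      or <- 1; p <- 1
    } else {
      p <- stats::fisher.test(matrix(c(a, c_, b, d), 2), alternative = "two.sided")$p.value
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    }
    data.frame(gene = g, n_alt_mut = a, n_alt_wt = b, n_wt_mut = c_,
               n_wt_wt = d, odds_ratio = or, p_value = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[c("gene", "n_alt_mut", "n_alt_wt", "n_wt_mut", "n_wt_wt",
        "odds_ratio", "p_value", "q_value", "degenerate")]
}

#' Descriptive DLI response cross-tabulation
#'
#' Cross-tabulates donor-lymphocyte-infusion recipients by complete
#' response and by the class of HLA aberration they carried (exonic
#' mutation or loss, versus UTR/intronic only, versus none). Descriptive
#' only; sample sizes are too small for testing.
#'
#' @param patients Assayed-patient table with logical `dli` and `dli_cr`
#'   columns on post-HCT-relapse rows.
#' @param lesions Lesion table.
#' @return Contingency table (lesion class x response).
#' @export
dli_response_table <- function(patients, lesions) {
  post <- patients[patients$timepoint == "post_hct_relapse" &
                     patients$dli %in% TRUE, , drop = FALSE]
  les <- lesions[lesions$timepoint == "post_hct_relapse", , drop = FALSE]
  cls <- vapply(post$patient_id, function(p) {
    cats <- les$category[les$patient_id == p]
    if (!length(cats)) "none"
    else if (any(!cats %in% c("UTR", "intronic"))) "exonic_or_loss"
    else "UTR_or_intronic"
  }, "")
  table(lesion_class = factor(cls, c("none", "exonic_or_loss", "UTR_or_intronic")),
        complete_response = factor(post$dli_cr %in% TRUE, c(FALSE, TRUE)))
}
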