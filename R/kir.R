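# KIR-ligand grouping of HLA-C alleles. C alleles partition into C1 (Asp80)
# and C2 (Lys80) ligand groups; membership here follows the allele-group
# (first-field) supertype rule, the convention used for clinical KIR-ligand
# stratification.

C1_SUPERTYPES <- c("01", "03", "07", "08", "09", "10", "12", "14", "16", "17")
C2_SUPERTYPES <- c("02", "04", "05", "06", "15")

#' C1/C2 supertype membership lists
#' @return Named list with character vectors `C1` and `C2` of HLA-C
#'   allele-group fields.
#' @export
kir_supertypes <- function() list(C1 = C1_SUPERTYPES, C2 = C2_SUPERTYPES)

#' KIR-ligand group of an HLA-C allele
#'
#' Membership is determined solely by the allele-group (first) field:
#' C*01/03/07/08/09/10/12/14/16/17 are C1; C*02/04/05/06/15 are C2. An
#' allele group outside both lists raises a classed error
#' (`hedscape_unclassified_allele`) rather than defaulting, so unclassified
#' alleles surface as missing status instead of corrupting stratification.
#'
#' @param allele Character vector of HLA-C allele names.
#' @return Factor vector with levels `C1`, `C2`.
#' @examples
#' kir_c_group(c("C*07:01", "C*04:01"))
#' @export
kir_c_group <- function(allele) {
  parsed <- parse_hla_allele(allele)
  if (any(parsed$locus != "C")) {
    stop("KIR-ligand groups are defined for locus C only; got: ",
         paste(unique(parsed$allele[parsed$locus != "C"]), collapse = ", "),
         call. = FALSE)
  }
  grp <- ifelse(parsed$field1 %in% C1_SUPERTYPES, "C1",
         ifelse(parsed$field1 %in% C2_SUPERTYPES, "C2", NA))
  if (anyNA(grp)) {
    stop(structure(
      class = c("hedscape_unclassified_allele", "error", "condition"),
      list(message = paste0("HLA-C allele group(s) outside the C1/C2 lists: ",
                            paste(unique(parsed$allele[is.na(grp)]),
                                  collapse = ", ")),
           call = sys.call())))
  }
  factor(grp, levels = c("C1", "C2"))
}

#' KIR-ligand status of subjects from their HLA-C genotype
#'
#' Homozygous carriage of C1-group (resp. C2-group) alleles gives status
#' `C1/C1` (`C2/C2`); one of each gives `C1/C2`. Order of the two alleles
#' is immaterial. Unclassifiable alleles propagate the classed error from
#' [kir_c_group()].
#'
#' @param genotypes An `hla_genotypes` data frame with `C_1`/`C_2` columns.
#' @return Data frame: `subject_id`, `c_status` factor with levels
#'   `C1/C1`, `C1/C2`, `C2/C2`.
#' @export
kir_c_status <- function(genotypes) {
  if (!all(c("C_1", "C_2") %in% names(genotypes))) {
    stop("genotypes lack C locus columns", call. = FALSE)
  }
  g1 <- kir_c_group(genotypes$C_1)
  g2 <- kir_c_group(genotypes$C_2)
  status <- ifelse(g1 == "C1" & g2 == "C1", "C1/C1",
            ifelse(g1 == "C2" & g2 == "C2", "C2/C2", "C1/C2"))
  data.frame(subject_id = genotypes$subject_id,
             c_status = factor(status, levels = c("C1/C1", "C1/C2", "C2/C2")),
             stringsAsFactors = FALSE)
}
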