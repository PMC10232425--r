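# HLA nomenclature parsing, genotype table I/O, allele-sequence dictionaries.

#' Recognized HLA loci
#'
#' The eleven classical loci typed by standard clinical panels. HED is
#' computed on the six loci in [hed_loci()]; the remainder (DRB3/4/5, DQA1,
#' DPA1) are accepted on input but carry no divergence score.
#'
#' @return Character vector of locus names.
#' @export
hla_loci <- function() {
  c("A", "B", "C", "DRB1", "DRB3", "DRB4", "DRB5", "DQA1", "DQB1", "DPA1", "DPB1")
}

#' The six loci entering HED computation
#'
#' Class I: A, B, C (peptide-binding domain = exons 2+3). Class II: DRB1,
#' DQB1, DPB1 (exon 2).
#'
#' @return Character vector of six locus names.
#' @export
hed_loci <- function() c("A", "B", "C", "DRB1", "DQB1", "DPB1")

#' @rdname hed_loci
#' @export
class1_loci <- function() c("A", "B", "C")

#' @rdname hed_loci
#' @export
class2_loci <- function() c("DRB1", "DQB1", "DPB1")

#' Parse HLA allele names in standard nomenclature
#'
#' Accepts strings of the form `LOCUS*gg:pp`, optionally with 3rd/4th fields
#' and an expression suffix (N/L/S/Q/C/A), e.g. `"A*02:01:01:01"`. Extra
#' fields and suffixes are truncated: all downstream divergence work is done
#' at 2-field (protein) resolution. Legacy forms without the `*` separator
#' or with fewer than two fields are rejected.
#'
#' @param text Character vector of allele names.
#' @return A data frame with one row per input: `raw`, `locus`, `field1`,
#'   `field2`, and `allele` (the normalized 2-field rendering
#'   `"LOCUS*gg:pp"`).
#' @examples
#' parse_hla_allele(c("C*07:01", "A*02:01:01:01"))
#' @export
parse_hla_allele <- function(text) {
  text <- as.character(text)
  m <- regmatches(text, regexec(
    "^([A-Z][A-Z0-9]*)\\*([0-9]+):([0-9]+)(:[0-9]+)*([NLSQCA])?$", text))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed HLA allele name(s): ",
         paste(sQuote(text[bad][seq_len(min(5, sum(bad)))]), collapse = ", "),
         call. = FALSE)
  }
  locus <- vapply(m, `[`, "", 2L)
  unknown <- !(locus %in% hla_loci())
  if (any(unknown)) {
    stop("unsupported HLA locus in: ",
         paste(sQuote(text[unknown][seq_len(min(5, sum(unknown)))]), collapse = ", "),
         call. = FALSE)
  }
  field1 <- vapply(m, `[`, "", 3L)
  field2 <- vapply(m, `[`, "", 4L)
  data.frame(
    raw = text, locus = locus, field1 = field1, field2 = field2,
    allele = paste0(locus, "*", field1, ":", field2),
    stringsAsFactors = FALSE)
}

#' Normalize allele names to 2-field resolution
#'
#' @param text Character vector of allele names.
#' @return Character vector of normalized `"LOCUS*gg:pp"` strings.
#' @export
normalize_hla_allele <- function(text) parse_hla_allele(text)$allele

#' Read a wide HLA genotype table
#'
#' Expects a delimited file with a `subject_id` column and two columns per
#' locus named `<LOCUS>_1` and `<LOCUS>_2` (e.g. `A_1`, `A_2`). The six HED
#' loci must be fully typed for every subject; other loci may be blank (a
#' legal absence, e.g. haplotypes lacking DRB3/4/5). Allele names are
#' normalized to 2-field resolution and checked against their column's
#' locus.
#'
#' @param path Path to the table, or a data frame already in the wide layout.
#' @param delim Field delimiter, `"\t"` by default; use `","` for CSV.
#' @return A data frame of class `hla_genotypes`: `subject_id` plus
#'   `<LOCUS>_1`/`<LOCUS>_2` character columns (NA where untyped).
#' @export
read_hla_genotypes <- function(path, delim = "\t") {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, sep = delim, colClasses = "character",
                      check.names = FALSE, strip.white = TRUE)
  if (!"subject_id" %in% names(df)) {
    stop("genotype table must have a 'subject_id' column", call. = FALSE)
  }
  dup <- duplicated(df$subject_id)
  if (any(dup)) {
    stop("duplicate subject id(s): ",
         paste(unique(df$subject_id[dup]), collapse = ", "), call. = FALSE)
  }
  present <- hla_loci()[vapply(hla_loci(), function(l)
    all(paste0(l, c("_1", "_2")) %in% names(df)), TRUE)]
  missing_hed <- setdiff(hed_loci(), present)
  if (length(missing_hed)) {
    stop("missing column pair(s) for HED locus/loci: ",
         paste(missing_hed, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(subject_id = as.character(df$subject_id),
                    stringsAsFactors = FALSE)
  for (locus in present) {
    for (k in c("_1", "_2")) {
      v <- as.character(df[[paste0(locus, k)]])
      v[!nzchar(trimws(ifelse(is.na(v), "", v)))] <- NA_character_
      out[[paste0(locus, k)]] <- v
    }
    a1 <- out[[paste0(locus, "_1")]]
    a2 <- out[[paste0(locus, "_2")]]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      stop("one of two alleles blank at locus ", locus, " for subject(s): ",
           paste(out$subject_id[half], collapse = ", "), call. = FALSE)
    }
    if (locus %in% hed_loci() && anyNA(a1)) {
      stop("HED locus ", locus, " untyped for subject(s): ",
           paste(out$subject_id[is.na(a1)], collapse = ", "), call. = FALSE)
    }
    for (k in c("_1", "_2")) {
      col <- paste0(locus, k)
      idx <- !is.na(out[[col]])
      if (any(idx)) {
        parsed <- parse_hla_allele(out[[col]][idx])
        off <- parsed$locus != locus
        if (any(off)) {
          stop("allele ", parsed$raw[off][1], " found in column ", col,
               " (locus mismatch)", call. = FALSE)
        }
        out[[col]][idx] <- parsed$allele
      }
    }
  }
  class(out) <- c("hla_genotypes", "data.frame")
  out
}

#' Loci present in a genotype table
#' @param genotypes An `hla_genotypes` data frame.
#' @return Character vector of locus names with both columns present.
#' @export
genotype_loci <- function(genotypes) {
  hla_loci()[vapply(hla_loci(), function(l)
    all(paste0(l, c("_1", "_2")) %in% names(genotypes)), TRUE)]
}

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Read an allele-to-sequence dictionary from FASTA
#'
#' Headers must contain an allele name in standard nomenclature; IMGT/HLA
#' style headers (`>HLA:HLA00001 A*01:01:01:01 365 bp`) and bare-name
#' headers (`>A*01:01`) are both accepted. Entries are keyed at 2-field
#' resolution; when several full-resolution alleles reduce to the same
#' 2-field key, the sequence of the lexicographically smallest full name is
#' kept, so the reduction is deterministic and order-independent. Sequences
#' are the peptide-binding domain: exons 2+3 concatenated for class I loci,
#' exon 2 for class II. Within a locus all sequences must have equal length;
#' only the 20 standard residues plus `X` (unknown) are allowed.
#'
#' @param path FASTA file path.
#' @param version Version tag stored on the dictionary (e.g. `"IMGT-3.41"`
#'   or `"fixture-1"`).
#' @return An `allele_dict`: list with `version`, `entries` (named character
#'   vector, 2-field allele -> sequence), and `lengths` (named per-locus
#'   sequence length).
#' @export
read_allele_sequences <- function(path, version = "unversioned") {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  tokens <- strsplit(headers, "[[:space:]]+")
  full <- vapply(tokens, function(tk) {
    hit <- grep("^[A-Z][A-Z0-9]*\\*[0-9]+:", tk, value = TRUE)
    if (!length(hit)) NA_character_ else hit[1]
  }, "")
  if (anyNA(full)) {
    stop("FASTA header(s) without a parseable allele name: ",
         paste(sQuote(headers[is.na(full)][seq_len(min(3, sum(is.na(full))))]),
               collapse = ", "), call. = FALSE)
  }
  parsed <- parse_hla_allele(full)
  seq_chr <- as.character(seqs)
  bad_chr <- grepl(paste0("[^", paste(c(AA_ALPHABET, "X"), collapse = ""), "]"),
                   seq_chr)
  if (any(bad_chr)) {
    stop("non-amino-acid characters in sequence(s) for: ",
         paste(full[bad_chr][seq_len(min(3, sum(bad_chr)))], collapse = ", "),
         call. = FALSE)
  }
  # deterministic reduction: keep lexicographically smallest full name per key
  ord <- order(parsed$allele, full, method = "radix")
  keep <- ord[!duplicated(parsed$allele[ord])]
  entries <- stats::setNames(seq_chr[keep], parsed$allele[keep])
  locus_of <- parsed$locus[keep]
  lengths <- tapply(nchar(entries), locus_of, unique, simplify = FALSE)
  multi <- names(lengths)[vapply(lengths, length, 1L) > 1L]
  if (length(multi)) {
    l <- multi[1]
    at <- locus_of == l
    stop("unequal sequence lengths within locus ", l, ": ",
         paste(paste0(names(entries)[at], "=", nchar(entries)[at]),
               collapse = ", "), call. = FALSE)
  }
  structure(
    list(version = version,
         entries = entries,
         lengths = vapply(lengths, `[`, 1L, 1L)),
    class = "allele_dict")
}

#' Build an allele dictionary from a named vector of sequences
#'
#' Programmatic counterpart of [read_allele_sequences()]; applies the same
#' validation (2-field keys, per-locus equal lengths, residue alphabet).
#'
#' @param sequences Named character vector, allele name -> sequence.
#' @param version Version tag.
#' @return An `allele_dict`.
#' @export
allele_dict <- function(sequences, version = "unversioned") {
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)), tf)
  read_allele_sequences(tf, version = version)
}

#' Look up peptide-binding-domain sequences
#'
#' @param dict An `allele_dict`.
#' @param allele Character vector of allele names (any resolution; truncated
#'   to 2 fields).
#' @return Character vector of sequences.
#' @export
dict_lookup <- function(dict, allele) {
  key <- normalize_hla_allele(allele)
  hit <- dict$entries[key]
  if (anyNA(hit)) {
    stop("allele(s) absent from sequence dictionary (", dict$version, "): ",
         paste(key[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  unname(hit)
}

#' Write an allele dictionary to FASTA
#'
#' @param dict An `allele_dict`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(dict, path) {
  x <- Biostrings::AAStringSet(dict$entries)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @export
print.allele_dict <- function(x, ...) {
  tab <- table(parse_hla_allele(names(x$entries))$locus)
  cat("Allele sequence dictionary [", x$version, "]: ",
      length(x$entries), " alleles\n", sep = "")
  for (l in names(tab)) {
    cat("  ", l, ": ", tab[[l]], " alleles, length ", x$lengths[[l]], "\n",
        sep = "")
  }
  invisible(x)
}
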