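# Grantham physicochemical amino-acid distance model.
#
# The distance between residues a and b combines differences in side-chain
# composition (c), polarity (p) and volume (v):
#   D(a,b) = rho * sqrt(alpha (c_a-c_b)^2 + beta (p_a-p_b)^2 + gamma (v_a-v_b)^2)
# with alpha/beta/gamma the inverse squared mean pairwise property
# differences and rho fixed so the mean distance over the 190 unordered
# residue pairs is 100. The package carries the integer distance table
# (rounded, half away from zero); the continuous from-properties
# recomputation is exposed so the two can be checked against each other.

#' Physicochemical side-chain properties of the 20 standard residues
#'
#' Composition (atomic weight ratio of non-carbon elements in side chain),
#' polarity, and molecular volume, in the original units.
#'
#' @return Data frame with columns `c`, `p`, `v`; row names are one-letter
#'   residue codes.
#' @export
grantham_properties <- function() {
  x <- rbind(
    A = c(0.00,  8.1,  31.0), C = c(2.75,  5.5,  55.0), D = c(1.38, 13.0,  54.0),
    E = c(0.92, 12.3,  83.0), F = c(0.00,  5.2, 132.0), G = c(0.74,  9.0,   3.0),
    H = c(0.58, 10.4,  96.0), I = c(0.00,  5.2, 111.0), K = c(0.33, 11.3, 119.0),
    L = c(0.00,  4.9, 111.0), M = c(0.00,  5.7, 105.0), N = c(1.33, 11.6,  56.0),
    P = c(0.39,  8.0,  32.5), Q = c(0.89, 10.5,  85.0), R = c(0.65, 10.5, 124.0),
    S = c(1.42,  9.2,  32.0), T = c(0.71,  8.6,  61.0), V = c(0.00,  5.9,  84.0),
    W = c(0.13,  5.4, 170.0), Y = c(0.20,  6.2, 136.0))
  out <- as.data.frame(x)
  names(out) <- c("c", "p", "v")
  out
}

# Frozen integer distance table (zero diagonal, symmetric); derived once by
# rounding the continuous model of grantham_model_from_properties().
GRANTHAM_INT <- local({
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  m <- rbind(
  A = c(0, 195, 126, 107, 113, 60, 86, 94, 106, 96, 85, 111, 27, 91, 111, 99, 58, 65, 148, 112),
  C = c(195, 0, 154, 170, 205, 158, 174, 197, 202, 198, 196, 139, 169, 154, 180, 112, 149, 191, 215, 194),
  D = c(126, 154, 0, 45, 177, 94, 81, 168, 102, 172, 160, 23, 108, 61, 96, 66, 85, 152, 191, 160),
  E = c(107, 170, 45, 0, 140, 98, 41, 134, 57, 139, 126, 41, 94, 29, 54, 80, 66, 121, 152, 123),
  F = c(113, 205, 177, 140, 0, 153, 100, 21, 102, 22, 29, 158, 114, 116, 97, 155, 103, 50, 40, 22),
  G = c(60, 158, 94, 98, 153, 0, 98, 136, 127, 138, 127, 79, 42, 87, 125, 55, 59, 109, 184, 147),
  H = c(86, 174, 81, 41, 100, 98, 0, 94, 32, 99, 86, 68, 76, 24, 29, 89, 47, 84, 115, 83),
  I = c(94, 197, 168, 134, 21, 136, 94, 0, 102, 5, 10, 149, 96, 109, 98, 142, 89, 30, 61, 33),
  K = c(106, 202, 102, 57, 102, 127, 32, 102, 0, 107, 95, 94, 103, 53, 26, 121, 78, 97, 110, 85),
  L = c(96, 198, 172, 139, 22, 138, 99, 5, 107, 0, 14, 153, 98, 113, 102, 144, 92, 32, 61, 36),
  M = c(85, 196, 160, 126, 29, 127, 86, 10, 95, 14, 0, 141, 87, 101, 92, 135, 81, 22, 67, 35),
  N = c(111, 139, 23, 41, 158, 79, 68, 149, 94, 153, 141, 0, 90, 46, 85, 46, 65, 133, 174, 142),
  P = c(27, 169, 108, 94, 114, 42, 76, 96, 103, 98, 87, 90, 0, 75, 103, 73, 38, 68, 147, 110),
  Q = c(91, 154, 61, 29, 116, 87, 24, 109, 53, 113, 101, 46, 75, 0, 43, 68, 41, 96, 130, 99),
  R = c(111, 180, 96, 54, 97, 125, 29, 98, 26, 102, 92, 85, 103, 43, 0, 109, 71, 96, 101, 77),
  S = c(99, 112, 66, 80, 155, 55, 89, 142, 121, 144, 135, 46, 73, 68, 109, 0, 58, 123, 177, 143),
  T = c(58, 149, 85, 66, 103, 59, 47, 89, 78, 92, 81, 65, 38, 41, 71, 58, 0, 70, 129, 92),
  V = c(65, 191, 152, 121, 50, 109, 84, 30, 97, 32, 22, 133, 68, 96, 96, 123, 70, 0, 88, 55),
  W = c(148, 215, 191, 152, 40, 184, 115, 61, 110, 61, 67, 174, 147, 130, 101, 177, 129, 88, 0, 37),
  Y = c(112, 194, 160, 123, 22, 147, 83, 33, 85, 36, 35, 142, 110, 99, 77, 143, 92, 55, 37, 0))
  dimnames(m) <- list(aa, aa)
  m
})

#' The packaged integer Grantham distance matrix
#'
#' Symmetric 20x20 table with zero diagonal; mean of the 190 unordered
#' pairwise distances is 100 to within rounding. This is the table used for
#' all divergence computation.
#'
#' @return Numeric 20x20 matrix with residue dimnames.
#' @export
grantham_matrix <- function() GRANTHAM_INT

#' Recompute the Grantham distance matrix from first principles
#'
#' Builds the continuous distance table from the residue property triples:
#' weights are the inverse squared mean pairwise differences of each
#' property, and the global scale is set so the mean unordered pairwise
#' distance equals exactly 100. Rounding this matrix reproduces
#' [grantham_matrix()]; it exists so the packaged table can be audited.
#'
#' @param properties Property table as from [grantham_properties()].
#' @return List with `matrix` (continuous 20x20), `weights`
#'   (`alpha`, `beta`, `gamma`), and `scale`.
#' @export
grantham_model_from_properties <- function(properties = grantham_properties()) {
  dc <- abs(outer(properties$c, properties$c, "-"))
  dp <- abs(outer(properties$p, properties$p, "-"))
  dv <- abs(outer(properties$v, properties$v, "-"))
  ut <- upper.tri(dc)
  w <- c(alpha = 1 / mean(dc[ut])^2,
         beta  = 1 / mean(dp[ut])^2,
         gamma = 1 / mean(dv[ut])^2)
  m <- sqrt(w[["alpha"]] * dc^2 + w[["beta"]] * dp^2 + w[["gamma"]] * dv^2)
  rho <- 100 / mean(m[ut])
  m <- m * rho
  dimnames(m) <- list(rownames(properties), rownames(properties))
  list(matrix = m, weights = w, scale = rho)
}

#' Grantham distance between residues
#'
#' Vectorized over pairs of one-letter residue codes. Unknown residues
#' (`X` or anything outside the 20 standard letters) raise a classed error
#' (`hedscape_undefined_residue`); position-exclusion policy belongs to the
#' caller (see [sequence_divergence()]).
#'
#' @param a,b Character vectors of single-letter residue codes.
#' @param matrix Distance table, by default the packaged integer table.
#' @return Numeric vector of distances.
#' @export
grantham_distance <- function(a, b, matrix = grantham_matrix()) {
  known <- rownames(matrix)
  bad <- !(a %in% known) | !(b %in% known)
  if (any(bad)) {
    stop(structure(
      class = c("hedscape_undefined_residue", "error", "condition"),
      list(message = paste0("undefined residue(s): ",
                            paste(unique(c(a[bad], b[bad])), collapse = ", ")),
           call = sys.call())))
  }
  matrix[cbind(a, b)]
}
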