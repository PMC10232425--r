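# Shared in-code fixtures and independent oracles.

# Tiny hand-checkable dictionary: 4-residue "binding domains", two alleles
# per HED locus, plus a third A allele carrying an unknown residue.
toy_dict <- function() {
  allele_dict(c(
    "A*01:01" = "AAAA", "A*02:01" = "AAAS", "A*03:01" = "AXAA",
    "B*01:01" = "GGGG", "B*02:01" = "GGGW",
    "C*01:01" = "CCCC", "C*02:01" = "CCCY",
    "DRB1*01:01" = "DDDD", "DRB1*02:01" = "DDDE",
    "DQB1*01:01" = "KKKK", "DQB1*02:01" = "KKKR",
    "DPB1*01:01" = "MMMM", "DPB1*02:01" = "MMMV"),
    version = "toy-1")
}

toy_genotype <- function(subject_id = "T1",
                         alleles = list(A = c("A*01:01", "A*02:01"),
                                        B = c("B*01:01", "B*02:01"),
                                        C = c("C*01:01", "C*02:01"),
                                        DRB1 = c("DRB1*01:01", "DRB1*02:01"),
                                        DQB1 = c("DQB1*01:01", "DQB1*02:01"),
                                        DPB1 = c("DPB1*01:01", "DPB1*02:01"))) {
  out <- data.frame(subject_id = subject_id, stringsAsFactors = FALSE)
  for (locus in names(alleles)) {
    out[[paste0(locus, "_1")]] <- alleles[[locus]][1]
    out[[paste0(locus, "_2")]] <- alleles[[locus]][2]
  }
  class(out) <- c("hla_genotypes", "data.frame")
  out
}

write_genotype_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent product-limit oracle: explicit loop over distinct event times.
oracle_km <- function(time, status) {
  tt <- sort(unique(time[status == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & status == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = tt, surv = out)
}

# Independent log-rank oracle: observed-minus-expected summation over risk
# sets, two groups.
oracle_logrank <- function(time, status, group) {
  g <- as.integer(factor(group)) - 1L   # 0/1
  tt <- sort(unique(time[status == 1]))
  o_minus_e <- 0; v <- 0
  for (t in tt) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Independent Aalen-Johansen oracle: CIF(t) = sum over cause events of
# S(t-) * d_cause/n, with S the all-cause product-limit estimate.
oracle_cif <- function(time, event, cause) {
  tt <- sort(unique(time[event != "censored"]))
  s_prev <- 1; cif <- 0
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n_risk <- sum(time >= tt[i])
    d_all <- sum(time == tt[i] & event != "censored")
    d_cause <- sum(time == tt[i] & event == cause)
    cif <- cif + s_prev * d_cause / n_risk
    s_prev <- s_prev * (1 - d_all / n_risk)
    out[i] <- cif
  }
  data.frame(time = tt, cif = out)
}

# Cox partial log-likelihood for a single binary covariate, no ties
# (Breslow = Efron in that case); used for brute-force grid maximization.
oracle_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    at <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at])))
  }
  ll
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value.
oracle_fisher <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
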