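# Synthetic cohort generator. Emits genotype tables, an allele-sequence
# dictionary, covariates, competing-risk outcomes and lesion tables with
# the statistical structure the analysis assumes, so the full pipeline can
# run and be validated without protected clinical data.

# run expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 777771 * k) %% .Machine$integer.max)
}

#' Synthetic allele-sequence pool
#'
#' Builds a deterministic pool of synthetic alleles per HED locus: one base
#' peptide-binding-domain sequence per locus (length 182 for class I,
#' emulating concatenated exons 2+3; 94 for class II, emulating exon 2)
#' with each further allele substituted at ~12% of positions, so every
#' distinct allele pair has strictly positive divergence. HLA-C allele
#' groups are drawn from the C1/C2-classifiable range so KIR-ligand
#' assignment always succeeds. The pool is a fixture: its generating seed
#' is a fixed constant, not a tunable.
#'
#' @param n_alleles Alleles per locus (default 8).
#' @return An `allele_dict` with version `"fixture-1"`.
#' @export
synthetic_allele_pool <- function(n_alleles = 8) {
  stopifnot(n_alleles >= 2, n_alleles <= 17)
  lens <- c(A = 182, B = 182, C = 182, DRB1 = 94, DQB1 = 94, DPB1 = 94)
  with_seed(20230531 %% 1e6, {
    seqs <- character(0)
    for (locus in names(lens)) {
      L <- lens[[locus]]
      base <- sample(AA_ALPHABET, L, replace = TRUE)
      for (i in seq_len(n_alleles)) {
        s <- base
        if (i > 1) {
          at <- sample.int(L, max(2L, round(0.12 * L)))
          s[at] <- vapply(s[at], function(r)
            sample(setdiff(AA_ALPHABET, r), 1L), "")
        }
        seqs[[paste0(locus, "*", sprintf("%02d", i), ":01")]] <-
          paste(s, collapse = "")
      }
    }
    allele_dict(seqs, version = "fixture-1")
  })
}

#' Configuration of the synthetic transplant cohort
#'
#' Bundles everything the generator needs: the synthetic allele pool and
#' per-locus allele frequencies, cause-specific exponential baseline
#' hazards (per month), log hazard-ratio effects on each cause,
#' administrative censoring, and covariate generators. Three scenarios
#' preset the class II HED effect at the magnitudes reported for allo-HCT
#' cohorts: `"multivariable"` (relapse HR 0.54 for high class II HED,
#' alongside non-null adjustment covariates), `"univariable"` (relapse HR
#' 0.65, all other effects null), and `"overall_survival"` (death-only
#' hazard carrying HR 0.63).
#'
#' @param scenario Effect-structure preset.
#' @param n_subjects Cohort size (default 4000).
#' @param n_controls Healthy-control cohort size used for cutoffs
#'   (default 200).
#' @param seed Seed governing every draw made under this config.
#' @param allele_freqs Optional per-locus named frequency vectors
#'   (must each sum to 1); defaults to a common skewed spectrum over the
#'   8-allele pool.
#' @param hazards Named baseline rates `c(relapse=, death=)` per month.
#' @param censor_months Administrative censoring time (months).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(scenario = c("multivariable", "univariable",
                                       "overall_survival"),
                          n_subjects = 4000, n_controls = 200, seed = 1,
                          allele_freqs = NULL,
                          hazards = NULL, censor_months = 48) {
  scenario <- match.arg(scenario)
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  pool <- synthetic_allele_pool()
  if (is.null(allele_freqs)) {
    base_freq <- c(0.30, 0.20, 0.15, 0.10, 0.10, 0.06, 0.05, 0.04)
    allele_freqs <- lapply(hed_loci(), function(locus) {
      alleles <- grep(paste0("^", locus, "\\*"), names(pool$entries),
                      value = TRUE)
      stats::setNames(base_freq[seq_along(alleles)], sort(alleles))
    })
    names(allele_freqs) <- hed_loci()
  }
  for (locus in names(allele_freqs)) {
    if (abs(sum(allele_freqs[[locus]]) - 1) > 1e-8) {
      stop("allele frequencies at locus ", locus, " do not sum to 1",
           call. = FALSE)
    }
  }
  effects <- switch(scenario,
    multivariable = list(
      relapse = c(hed_class2_high = log(0.54), hed_class1_high = log(0.95),
                  age10 = 0.10, donor_MUD = 0.10, donor_Haplo = 0.25,
                  cond_MAC = -0.15, disease_MDS = -0.10, disease_MPN = -0.30,
                  graft_PBSC = 0.05, hct_ci = 0.05, risk_2 = 0.30,
                  risk_3 = 0.60, year_c = -0.02),
      death = c(hed_class2_high = log(0.85), age10 = 0.25,
                donor_Haplo = 0.15, cond_MAC = 0.10, hct_ci = 0.15,
                risk_3 = 0.20)),
    univariable = list(
      relapse = c(hed_class2_high = log(0.65)),
      death = c()),
    overall_survival = list(
      relapse = c(),
      death = c(hed_class2_high = log(0.63), age10 = 0.20, hct_ci = 0.10)))
  if (is.null(hazards)) {
    hazards <- switch(scenario,
      overall_survival = c(relapse = 0, death = 0.018),
      c(relapse = 0.012, death = 0.010))
  }
  if (any(hazards < 0) || all(hazards == 0)) {
    stop("baseline hazards must be non-negative with at least one positive",
         call. = FALSE)
  }
  adjustment <- switch(scenario,
    multivariable = c("hed_class2", "hed_class1", "age10", "donor_type",
                      "conditioning", "disease", "graft", "hct_ci",
                      "disease_risk", "year_c"),
    univariable = "hed_class2",
    overall_survival = c("hed_class2", "age10", "hct_ci"))
  structure(
    list(scenario = scenario, n_subjects = n_subjects,
         n_controls = n_controls, seed = as.integer(seed),
         sequences = pool, allele_freqs = allele_freqs,
         hazards = hazards, effects = effects,
         censor_months = censor_months,
         adjustment_covariates = adjustment),
    class = "cohort_config")
}

#' Sample genotypes under Hardy-Weinberg equilibrium
#'
#' Each chromosome's allele at each locus is drawn independently from the
#' configured frequency spectrum (no linkage disequilibrium).
#'
#' @param config A `cohort_config`.
#' @param n Number of subjects (default `config$n_subjects`).
#' @param seed Seed (default `config$seed`).
#' @param prefix Subject-id prefix.
#' @return An `hla_genotypes` data frame.
#' @export
sample_genotypes <- function(config, n = config$n_subjects,
                             seed = config$seed, prefix = "S") {
  with_seed(derive_seed(seed, 1), {
    out <- data.frame(
      subject_id = sprintf("%s%05d", prefix, seq_len(n)),
      stringsAsFactors = FALSE)
    for (locus in hed_loci()) {
      fr <- config$allele_freqs[[locus]]
      for (k in c("_1", "_2")) {
        out[[paste0(locus, k)]] <-
          sample(names(fr), n, replace = TRUE, prob = fr)
      }
    }
    class(out) <- c("hla_genotypes", "data.frame")
    out
  })
}

# transplant covariates with realistic marginal mixes
simulate_covariates <- function(n, seed) {
  with_seed(derive_seed(seed, 2), {
    age <- pmin(pmax(round(stats::rnorm(n, 59, 8)), 18), 75)
    data.frame(
      age = age,
      age10 = (age - 60) / 10,
      donor_type = factor(sample(c("MRD", "MUD", "Haplo"), n, TRUE,
                                 prob = c(0.27, 0.53, 0.20)),
                          levels = c("MRD", "MUD", "Haplo")),
      conditioning = factor(sample(c("RIC", "MAC"), n, TRUE,
                                   prob = c(0.64, 0.36)),
                            levels = c("RIC", "MAC")),
      disease = factor(sample(c("AML", "MDS", "MPN"), n, TRUE,
                              prob = c(0.59, 0.26, 0.15)),
                       levels = c("AML", "MDS", "MPN")),
      graft = factor(sample(c("BM", "PBSC"), n, TRUE, prob = c(0.31, 0.69)),
                     levels = c("BM", "PBSC")),
      hct_ci = sample(0:5, n, TRUE, prob = c(0.30, 0.25, 0.18, 0.12, 0.10, 0.05)),
      disease_risk = factor(sample(c("1", "2", "3"), n, TRUE,
                                   prob = c(0.25, 0.50, 0.25)),
                            levels = c("1", "2", "3")),
      year_c = sample(2010:2020, n, TRUE) - 2015,
      stringsAsFactors = FALSE)
  })
}

# linear predictor from named effects over the generator's design terms
linear_predictor <- function(effects, covars, cats) {
  e <- function(nm) if (nm %in% names(effects)) effects[[nm]] else 0
  e("hed_class2_high") * (cats$HED_class2_cat == "high") +
    e("hed_class1_high") * (cats$HED_class1_cat == "high") +
    e("age10") * covars$age10 +
    e("donor_MUD") * (covars$donor_type == "MUD") +
    e("donor_Haplo") * (covars$donor_type == "Haplo") +
    e("cond_MAC") * (covars$conditioning == "MAC") +
    e("disease_MDS") * (covars$disease == "MDS") +
    e("disease_MPN") * (covars$disease == "MPN") +
    e("graft_PBSC") * (covars$graft == "PBSC") +
    e("hct_ci") * covars$hct_ci +
    e("risk_2") * (covars$disease_risk == "2") +
    e("risk_3") * (covars$disease_risk == "3") +
    e("year_c") * covars$year_c
}

#' Simulate competing-risk outcomes under proportional hazards
#'
#' Latent exponential event times for relapse and death are drawn with
#' subject-specific rates `lambda_cause * exp(x' beta_cause)`; the earlier
#' latent time is observed, administratively censored at
#' `config$censor_months`. With all effects zero and no censoring, the
#' relapse share of events is `lambda_relapse / (lambda_relapse +
#' lambda_death)` in expectation.
#'
#' @param config A `cohort_config`.
#' @param categories HED category table from [hed_dichotomize()]
#'   (columns `HED_class1_cat`, `HED_class2_cat`), one row per subject.
#' @param seed Seed (default `config$seed`).
#' @return Outcomes data frame: `subject_id`, `time`, `event`, the HED
#'   category factors (`hed_class1`, `hed_class2`, levels low/high) and the
#'   transplant covariates.
#' @export
simulate_outcomes <- function(config, categories, seed = config$seed) {
  n <- nrow(categories)
  covars <- simulate_covariates(n, seed)
  lp_r <- linear_predictor(config$effects$relapse, covars, categories)
  lp_d <- linear_predictor(config$effects$death, covars, categories)
  with_seed(derive_seed(seed, 3), {
    draw <- function(rate, lp) {
      if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate * exp(lp))
    }
    t_r <- draw(config$hazards[["relapse"]], lp_r)
    t_d <- draw(config$hazards[["death"]], lp_d)
    t_event <- pmin(t_r, t_d)
    cens <- config$censor_months
    time <- pmin(t_event, cens)
    event <- ifelse(t_event > cens, "censored",
                    ifelse(t_r <= t_d, "relapse", "death"))
    # guard against zero observed time under pathological censoring
    time <- pmax(time, .Machine$double.eps)
    out <- data.frame(subject_id = categories$subject_id,
                      time = time, event = event,
                      hed_class1 = factor(
                        as.character(categories$HED_class1_cat),
                        levels = c("low", "high")),
                      hed_class2 = factor(
                        as.character(categories$HED_class2_cat),
                        levels = c("low", "high")),
                      stringsAsFactors = FALSE)
    as_outcomes(cbind(out, covars))
  })
}

#' Run the whole synthetic pipeline for one configuration
#'
#' Samples subject and healthy-control genotypes, computes HED, derives
#' control-median cutoffs, dichotomizes, simulates outcomes, and assigns
#' KIR-ligand status. This is the canonical path from a `cohort_config` to
#' an analyzable cohort.
#'
#' @param config A `cohort_config`.
#' @param seed Seed (default `config$seed`).
#' @return List: `genotypes`, `controls`, `hed`, `cutoffs`, `categories`,
#'   `c_status`, `outcomes`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  genotypes <- sample_genotypes(config, n = config$n_subjects, seed = seed,
                                prefix = "S")
  controls <- sample_genotypes(config, n = config$n_controls,
                               seed = derive_seed(seed, 11), prefix = "HC")
  hed <- hed_table(genotypes, config$sequences)
  cutoffs <- hed_cutoffs(hed_table(controls, config$sequences),
                         source = "synthetic-healthy-controls")
  categories <- hed_dichotomize(hed, cutoffs)
  outcomes <- simulate_outcomes(config, categories, seed = seed)
  list(genotypes = genotypes, controls = controls, hed = hed,
       cutoffs = cutoffs, categories = categories,
       c_status = kir_c_status(genotypes), outcomes = outcomes)
}

#' Simulate somatic HLA lesion tables
#'
#' Bernoulli lesion indicators per assayed patient-timepoint at the
#' configured rates, with lesion categories drawn from a multinomial over
#' the category vocabulary. `fixture = TRUE` instead returns the
#' deterministic landscape fixture of [fixture_f3()] exactly.
#'
#' @param n Named integer vector of assayed patients per timepoint.
#' @param rates Named lesion probabilities per timepoint, each in `[0,1]`.
#' @param seed Seed.
#' @param fixture If TRUE, emit the deterministic fixture.
#' @return List with `lesions` and `patients` data frames.
#' @export
simulate_lesions <- function(n = c(diagnosis = 40, post_chemo_relapse = 9,
                                   post_hct_relapse = 45),
                             rates = c(diagnosis = 0.22,
                                       post_chemo_relapse = 0,
                                       post_hct_relapse = 0.38),
                             seed = 1, fixture = FALSE) {
  if (fixture) return(fixture_f3())
  if (any(rates < 0 | rates > 1)) {
    stop("lesion rates must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(identical(sort(names(n)), sort(names(rates))))
  pool <- c("A*02:01", "B*07:02", "C*07:01", "DRB1*15:01", "DQB1*06:02",
            "DPB1*04:01", "DPA1*01:03")
  cat_probs <- c(missense = 0.42, nonsense = 0.08, frameshift = 0.10,
                 splicing = 0.05, UTR = 0.07, intronic = 0.03, loss = 0.25)
  with_seed(derive_seed(seed, 5), {
    patients <- do.call(rbind, lapply(names(n), function(tp) {
      data.frame(patient_id = sprintf("%s_P%03d", toupper(substr(tp, 1, 3)),
                                      seq_len(n[[tp]])),
                 timepoint = tp, stringsAsFactors = FALSE)
    }))
    hit <- stats::rbinom(nrow(patients), 1L,
                         rates[patients$timepoint]) == 1L
    les <- lapply(which(hit), function(i) {
      k <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
      data.frame(patient_id = patients$patient_id[i],
                 timepoint = patients$timepoint[i],
                 allele = sample(pool, k, replace = TRUE),
                 category = sample(names(cat_probs), k, TRUE, cat_probs),
                 stringsAsFactors = FALSE)
    })
    lesions <- if (length(les)) do.call(rbind, les) else
      data.frame(patient_id = character(), timepoint = character(),
                 allele = character(), category = character(),
                 stringsAsFactors = FALSE)
    list(lesions = lesions, patients = patients)
  })
}

#' Deterministic somatic HLA lesion landscape fixture
#'
#' A synthetic, fully deterministic lesion and assayed-patient table whose
#' marginals reproduce the published landscape of a longitudinally
#' genotyped post-transplant relapse cohort: 9/40 lesioned at diagnosis,
#' 0/9 at post-chemotherapy relapse, and at post-transplant relapse 10/20
#' in matched-related, 2/8 in haploidentical and 5/17 in unrelated
#' transplants (17 lesioned overall), with 25 DLI recipients of whom 5
#' achieved complete response, and late (>6 months) relapses more often
#' lesioned than early ones. Patient identities and per-lesion details are
#' synthetic.
#'
#' @return List with `lesions` and `patients` data frames; `patients`
#'   carries `donor_type`, `relapse_time_months`, `dli`, `dli_cr` on
#'   post-HCT rows.
#' @export
fixture_f3 <- function() {
  pid <- function(i) sprintf("P%02d", i)
  # diagnosis: 40 assayed, lesioned P01-P09
  diag_pat <- data.frame(patient_id = pid(1:40), timepoint = "diagnosis",
                         donor_type = NA_character_,
                         relapse_time_months = NA_real_,
                         dli = NA, dli_cr = NA, stringsAsFactors = FALSE)
  # post-chemotherapy relapse: 9 assayed, none lesioned
  chemo_pat <- data.frame(patient_id = pid(40:48),
                          timepoint = "post_chemo_relapse",
                          donor_type = NA_character_,
                          relapse_time_months = NA_real_,
                          dli = NA, dli_cr = NA, stringsAsFactors = FALSE)
  # post-HCT relapse: 45 assayed; MRD P01-P20 (10 lesioned), Haplo P21-P28
  # (2 lesioned), MUD P29-P45 (5 lesioned)
  hct_pat <- data.frame(
    patient_id = pid(1:45), timepoint = "post_hct_relapse",
    donor_type = rep(c("MRD", "Haplo", "MUD"), c(20, 8, 17)),
    stringsAsFactors = FALSE)
  lesioned_hct <- pid(c(1:10, 21:22, 29:33))
  # relapse timing: 10 lesioned late / 7 early; 24 early, 21 late overall
  late_ids <- pid(c(1:6, 21, 29:31, 11:16, 23:25, 34:38))   # 21 late
  hct_pat$relapse_time_months <-
    ifelse(hct_pat$patient_id %in% late_ids,
           8 + 2 * (seq_len(45) %% 7), 1 + 0.5 * (seq_len(45) %% 9))
  # DLI: 25 recipients (9 lesioned: 6 exonic/loss without CR, 3 UTR-only),
  # complete response in 5 (all HLA wild type here)
  dli_ids <- pid(c(1:6, 29:31, 11:20, 23:28))
  hct_pat$dli <- hct_pat$patient_id %in% dli_ids
  hct_pat$dli_cr <- hct_pat$patient_id %in% pid(11:15)
  lesion_row <- function(p, tp, allele, category)
    data.frame(patient_id = p, timepoint = tp, allele = allele,
               category = category, stringsAsFactors = FALSE)
  diag_les <- do.call(rbind, list(
    lesion_row(pid(1), "diagnosis", "A*02:01", "missense"),
    lesion_row(pid(2), "diagnosis", "DRB1*15:01", "loss"),
    lesion_row(pid(3), "diagnosis", "C*07:01", "nonsense"),
    lesion_row(pid(4), "diagnosis", "DQB1*06:02", "loss"),
    lesion_row(pid(4), "diagnosis", "B*07:02", "frameshift"),
    lesion_row(pid(5), "diagnosis", "DQB1*03:01", "missense"),
    lesion_row(pid(6), "diagnosis", "A*01:01", "splicing"),
    lesion_row(pid(7), "diagnosis", "DPB1*04:01", "missense"),
    lesion_row(pid(8), "diagnosis", "C*04:01", "missense"),
    lesion_row(pid(9), "diagnosis", "DRB1*07:01", "loss")))
  hct_cat <- c("missense", "loss", "missense", "loss", "nonsense",
               "frameshift", "loss", "missense", "splicing", "loss",
               "missense", "loss", "UTR", "UTR", "UTR", "missense", "loss")
  hct_allele <- c("A*02:01", "DRB1*15:01", "C*07:01", "DQB1*06:02",
                  "B*07:02", "A*01:01", "DQB1*03:01", "C*04:01",
                  "DRB1*07:01", "DQB1*05:01", "B*08:01", "DRB1*03:01",
                  "DPA1*01:03", "DPB1*04:01", "A*03:01", "C*12:03",
                  "DQB1*02:01")
  hct_les <- lesion_row(lesioned_hct, "post_hct_relapse", hct_allele, hct_cat)
  list(lesions = rbind(diag_les, hct_les),
       patients = rbind(diag_pat, chemo_pat,
                        cbind(hct_pat[c("patient_id", "timepoint",
                                        "donor_type", "relapse_time_months",
                                        "dli", "dli_cr")])))
}

#' Write a simulated cohort to disk in the pipeline's file dialects
#'
#' @param cohort List from [simulate_cohort()].
#' @param config The `cohort_config` used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; writes `genotypes.tsv`, `controls.tsv`,
#'   `sequences.fasta`, `outcomes.tsv`.
#' @export
write_cohort <- function(cohort, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$genotypes, "genotypes.tsv")
  wt(cohort$controls, "controls.tsv")
  write_allele_fasta(config$sequences, file.path(dir, "sequences.fasta"))
  wt(cohort$outcomes, "outcomes.tsv")
  invisible(dir)
}
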