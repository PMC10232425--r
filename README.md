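# hedscape

Immunogenetic analysis of leukemia relapse after allogeneic hematopoietic
cell transplantation (allo-HCT), for transplant immunogenetics and
hematology researchers. The package covers both sides of HLA heterogeneity
dysfunction:

- **germline** — HLA evolutionary divergence (HED) scoring of recipient
  genotypes, dichotomized against healthy-control medians and related to
  relapse and survival in a competing-risk framework;
- **somatic** — tabulation of acquired HLA lesions (mutations and allelic
  losses) at diagnosis and relapse, by donor type and relapse timing, with
  myeloid co-mutation enrichment.

Because the clinical cohorts such analyses run on are access-controlled,
the package includes a first-class synthetic-cohort generator so every
stage can be exercised, tested, and calibrated end to end.

## The score

For a locus with alleles *i* and *j* whose peptide-binding-domain protein
sequences are s<sup>i</sup> and s<sup>j</sup> (exons 2+3 for HLA class I,
exon 2 for class II), the HED score is the per-site mean Grantham distance

> HED(i, j) = (1/L) Σ<sub>k=1..L</sub> D(s<sup>i</sup><sub>k</sub>, s<sup>j</sup><sub>k</sub>)

where D is the Grantham physicochemical amino-acid distance,
D(a, b) = ρ·[α(c<sub>a</sub>−c<sub>b</sub>)² + β(p<sub>a</sub>−p<sub>b</sub>)² +
γ(v<sub>a</sub>−v<sub>b</sub>)²]<sup>1/2</sup>, built from side-chain
composition, polarity and volume and scaled so the mean over the 190
residue pairs is 100. Per-class scores are the means over A/B/C
(class I) and DRB1/DQB1/DPB1 (class II); the global score is the mean of
all six loci. Scores are dichotomized high/low at the 50th percentile of a
healthy-control cohort. HLA-C alleles are additionally assigned to the
KIR-ligand groups C1/C2 by allele-group supertype.

Relapse is modeled cause-specifically: cumulative incidence by
Aalen–Johansen with death as the competing event, and Cox regression on
the cause-specific hazard (competing events censored, Efron ties).

## Worked example

```r
library(hedscape)

cfg <- cohort_config("univariable", n_subjects = 400, n_controls = 150, seed = 42)
co  <- simulate_cohort(cfg)   # genotypes -> HED -> cutoffs -> categories -> outcomes

head(co$hed[c("subject_id", "HED_A", "HED_DRB1",
              "HED_class1", "HED_class2", "HED_global")], 3)
#>   subject_id HED_A HED_DRB1 HED_class1 HED_class2 HED_global
#> 1     S00001 19.96    21.48      18.71      14.88      16.79
#> 2     S00002 24.27     0.00      20.03       3.61      11.82
#> 3     S00003 19.96    12.39      14.25      15.12      14.69

co$cutoffs
#> HED 50th-percentile cutoffs (source: synthetic-healthy-controls)
#>        A        B        C     DRB1     DQB1     DPB1   class1   class2   global
#> 12.60440 12.71429 12.42308 11.63830 13.22340 11.94681 15.00000 13.77482 14.09553

cox_cause_specific(co$outcomes, cause = "relapse", covariates = "hed_class2")
#> Cause-specific Cox fit (cause: relapse, ties: efron, n = 400, events = 130)
#>             term    coef     se     hr ci_lower ci_upper p_value
#> 1 hed_class2high -0.5394 0.1804 0.5831   0.4095   0.8304 0.00278

logrank_test(co$outcomes, "hed_class2", event_def = "relapse")
#> log-rank: chi2 = 9.16, p = 0.0025
```

The cohort was generated with a true relapse hazard ratio of 0.65 for high
class II HED; the single-seed fit above estimates HR 0.58 (95% CI
0.41–0.83), and averaging over many seeds recovers the configured value
(see below). Subjects above the control median of class II divergence
relapse less — the protective effect the score is designed to capture.

Somatic landscape tabulation on the packaged deterministic fixture:

```r
f3   <- fixture_f3()
post <- f3$patients[f3$patients$timepoint == "post_hct_relapse", ]
lesion_tabulate(f3$lesions[f3$lesions$timepoint == "post_hct_relapse", ],
                post, group_by = "donor_type")
#>   group n_lesioned n_assayed percent n_mutation_lesions n_loss_lesions empty
#> 1   MRD         10        20      50                  6              4 FALSE
#> 2 Haplo          2         8      25                  1              1 FALSE
#> 3   MUD          5        17      29                  4              1 FALSE
```

Half of matched-related-donor relapses carry a somatic HLA hit, a quarter
of haploidentical and 29% of unrelated-donor relapses — immune escape is
not confined to the mismatched setting.

## Package tour

| area | functions |
|---|---|
| HLA core | `parse_hla_allele`, `read_hla_genotypes`, `read_allele_sequences`, `allele_dict` |
| Grantham / HED | `grantham_matrix`, `grantham_model_from_properties`, `sequence_divergence`, `hed_table`, `hed_cutoffs`, `hed_dichotomize` |
| KIR ligand | `kir_c_group`, `kir_c_status` |
| Outcomes | `km_estimate`, `logrank_test`, `cif_estimate`, `cox_cause_specific` |
| Lesions | `read_lesion_table`, `lesion_tabulate`, `lesion_early_late`, `comutation_enrichment`, `fixture_f3` |
| Synthetic cohorts | `cohort_config`, `synthetic_allele_pool`, `sample_genotypes`, `simulate_outcomes`, `simulate_cohort`, `simulate_lesions` |
| Pipeline | `run_pipeline` |

The methods vignette (`vignettes/hed-methods.Rmd`) documents the model,
the generator's assumptions, and every numerical convention.
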