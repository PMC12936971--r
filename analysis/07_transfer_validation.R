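#!/usr/bin/env Rscript
# Stage 7: out-of-sample validation. A same-process validation cohort
# (single new site, its own subjects) is processed identically; the
# pretrained normative models are recalibrated on the validation controls;
# validation cases are assigned to biotypes by maximum expression score
# against the pretrained polytope; clinical contrasts and between-cohort
# biotype profile correlations are reported.

source(file.path("analysis", "00_config.R"))

res <- run_stages(c("simulate", "msn", "topology", "normative", "deviations",
                    "fuse", "cluster"))
st <- res$state
cfg <- demo_config()

spec_v <- cohort_spec(n_controls = 123L, n_cases = 554L,
                      n_regions = cfg$spec$n_regions, n_sites = 1L,
                      n_samples_per_region = cfg$spec$n_samples_per_region,
                      k_true = cfg$spec$k_true, effect_size = 3,
                      seed = derive_seed(MASTER_SEED, "validation"))
vsim <- generate_cohort(spec_v, template = st$sim$ground_truth)

is_case <- st$sim$cohort$group == "case"
pre <- list(hydra = st$hydra, models = st$models, partition = st$partition,
            sparsity = cfg$sparsity, n_bins = cfg$n_bins,
            density_method = cfg$density_method,
            train = list(X = msnbiotypes:::flatten_deviations(st$devs)[is_case, ],
                         labels = st$hydra$case_labels))
tv <- transfer_validate(pre, vsim)

cat(sprintf("validation biotype sizes: %s\n",
            paste(tv$biotype_sizes, collapse = ", ")))
cat(sprintf("between-cohort biotype profile correlations: %s\n",
            paste(sprintf("%.2f", tv$profile_cor), collapse = ", ")))
vtruth <- vsim$cohort$true_biotype[vsim$cohort$group == "case"]
cat(sprintf("agreement with planted validation biotypes: ARI = %.2f\n",
            adjusted_rand_index(tv$assignment, vtruth)))
for (sc in names(tv$clinical))
  cat(sprintf("%s: H = %.2f, p = %.3g\n", sc, tv$clinical[[sc]]$H,
              tv$clinical[[sc]]$p))

out <- file.path("results", "transfer")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(subject_id = vsim$cohort$subject_id[vsim$cohort$group == "case"],
                       biotype = tv$assignment),
            file.path(out, "validation_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(biotype_sizes = tv$biotype_sizes,
                          profile_cor = tv$profile_cor,
                          clinical = tv$clinical),
                     file.path(out, "transfer_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("validation outputs written under results/transfer/\n")
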