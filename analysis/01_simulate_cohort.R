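#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 25 glaucoma patients and 18
# glaucoma suspects, each with a monocular field pair (suspects normal,
# patients drawn from a defect-archetype mixture), clinical covariates,
# and two drives' worth of vehicle-control outcomes generated from the
# planted multivariable model.

suppressPackageStartupMessages(library(oudrive))

dir.create("results", showWarnings = FALSE)
cfg <- pipeline_config(seed = 20201020)

cohort <- simulate_cohort(cfg$cohort)
subj <- cohort[!duplicated(cohort$subject_id), ]

cat(sprintf("Simulated %d subjects (%d glaucoma, %d suspect), %d drives\n",
            nrow(subj), sum(subj$group == "glaucoma"),
            sum(subj$group == "suspect"), nrow(cohort)))
cat(sprintf("OU-VFI: suspects %.1f +- %.1f%%, glaucoma %.1f +- %.1f%% (range %.0f-%.0f)\n",
            mean(subj$ou_vfi[subj$group == "suspect"]),
            sd(subj$ou_vfi[subj$group == "suspect"]),
            mean(subj$ou_vfi[subj$group == "glaucoma"]),
            sd(subj$ou_vfi[subj$group == "glaucoma"]),
            min(subj$ou_vfi[subj$group == "glaucoma"]),
            max(subj$ou_vfi[subj$group == "glaucoma"])))

d <- as.data.frame(cohort)
num <- vapply(d, is.double, logical(1))
d[num] <- lapply(d[num], function(x) formatC(x, format = "g", digits = 6))
write.csv(d, "results/cohort.csv", row.names = FALSE, quote = FALSE)

# one example field pair for the integration walk-through (02)
pair <- simulate_monocular_pair("moderate_diffuse", asymmetry = 2,
                                noise_sd = 1.5, seed = 20201020)
write_monocular_field(pair$left, "results/example_field_os.csv")
write_monocular_field(pair$right, "results/example_field_od.csv")
write_pipeline_config(cfg, "results/config.yaml")
cat("Wrote results/cohort.csv and an example monocular field pair\n")
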