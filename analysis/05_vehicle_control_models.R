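#!/usr/bin/env Rscript
# Multivariable mixed models of vehicle control: log(outcome) ~ age +
# worst-eye acuity + disease burden + MoCA total + VFQ driving, with a
# per-subject random intercept over the repeated drives and
# Kenward-Roger degrees of freedom. Disease burden enters either as the
# logit of OU-VFI or as glaucoma group.

suppressPackageStartupMessages(library(oudrive))

cohort <- read.csv("results/cohort.csv", stringsAsFactors = FALSE)

for (outc in c("steering_sd", "lat_accel_sd")) {
  for (expo in c("logit_ou", "group")) {
    res <- fit_vehicle_control_model(cohort, outcome = outc,
                                     exposure = expo)
    cat(sprintf("\n== log(%s) ~ ... + %s ==\n", outc, expo))
    print(as.data.frame(res[, c("term", "estimate", "se", "df",
                                "f_value", "p_value")]), digits = 3)
    tab <- data.frame(
      Effect = res$term,
      Estimate = formatC(res$estimate, format = "g", digits = 6),
      SE = formatC(res$se, format = "g", digits = 6),
      DF = formatC(res$df, format = "g", digits = 6),
      F = formatC(res$f_value, format = "g", digits = 6),
      p = formatC(res$p_value, format = "g", digits = 6)
    )
    write.csv(tab, sprintf("results/model_%s_%s.csv", outc, expo),
              row.names = FALSE, quote = FALSE)
  }
}
cat("\nWrote results/model_<outcome>_<exposure>.csv (4 tables)\n")
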