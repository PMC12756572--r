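#!/usr/bin/env Rscript
# Clinical associations: descriptive table by endotype, the adjusted linear
# model for VFD-30 (endotype and BASICq as exposure), and the adjusted Cox
# model for the composite outcome (death or ventilation >= 30 days).

library(endokit)

clinical <- read_clinical("results/cohort/clinical.csv")
labels <- utils::read.csv("results/endotype/labels.csv")
lab <- setNames(labels$endotype, labels$sample_id)[clinical$sample_id]
bq <- utils::read.csv("results/basicq/basicq.csv")
basicq <- setNames(bq$basicq, bq$sample_id)[clinical$sample_id]

t1 <- endotype_table1(clinical, lab)
print(t1$continuous)

vfd_endo <- fit_vfd_regression(clinical, endotype = lab)
row <- vfd_endo[vfd_endo$term == "endotype1", ]
message(sprintf("adjusted VFD-30 effect of endotype 1: %.2f days (95%% CI %.2f to %.2f, p = %.3g)",
                row$estimate, row$ci_lo, row$ci_hi, row$p))

vfd_q <- fit_vfd_regression(clinical, basicq = basicq)
rq <- vfd_q[vfd_q$term == "basicq", ]
message(sprintf("adjusted VFD-30 effect of BASICq (0 -> 1): %.2f days (p = %.3g)",
                rq$estimate, rq$p))

oc <- outcome_records(clinical)
cox <- fit_cox_model(ifelse(oc$event_composite, 30L, oc$time_to_extubation),
                     oc$event_composite, clinical, endotype = lab)
rc <- cox[cox$term == "endotype1", ]
message(sprintf("composite-outcome HR for endotype 1: %.2f (95%% CI %.2f-%.2f)",
                rc$hr, rc$ci_lo, rc$ci_hi))

manifest <- write_results(
  list(table1_continuous = t1$continuous, vfd_model_endotype = vfd_endo,
       vfd_model_basicq = vfd_q, cox_model_composite = cox),
  "results/clinical")
message("wrote ", length(manifest), " tables under results/clinical/")
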