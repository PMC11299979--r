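#!/usr/bin/env Rscript
# Backbone dynamics and conformational entropy from 15N relaxation.
#
# R1/R2/NOE data are simulated at 600 MHz for a rigid reference
# protein and a query whose helix alpha1 has lowered order parameters
# (more fast internal motion). Lipari-Szabo model-free fits recover
# S2/tau_e/Rex and the global tumbling time; the entropy meter converts
# the order-parameter difference into segment-averaged -T dS.

suppressPackageStartupMessages(library(tagfold))
dir.create("results", showWarnings = FALSE)

set.seed(501)
residues <- 1:71
s2_ref <- runif(71, 0.86, 0.92)
s2_query <- s2_ref
in_a1 <- residues %in% 23:34
s2_query[in_a1] <- s2_query[in_a1] - 0.12

fit_protein <- function(s2, seed) {
  ds <- gen_relaxation(relax_spec(s2, tau_m = 5, tau_e = 30, rex = 0,
                                  field_mhz = 600, noise_frac = 0.02,
                                  residues = residues, seed = seed))
  fit_model_free(ds)
}

mf_ref <- fit_protein(s2_ref, 502)
mf_query <- fit_protein(s2_query, 503)

cmp <- segment_entropy_compare(mf_ref, mf_query, temperature_k = 298)
write.table(cmp, "results/entropy_segments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Tumbling times: reference %.2f ns, query %.2f ns\n",
            mf_ref$tau_m_ns, mf_query$tau_m_ns))
cat(sprintf("Mean S2: reference %.3f, query %.3f\n\n",
            mean(mf_ref$data$s2), mean(mf_query$data$s2)))
cat("Segment-averaged -T dS (kcal/mol; positive = query more flexible):\n")
print(cmp, row.names = FALSE)
cat("\nOnly the helix with deliberately lowered order parameters\n")
cat("crosses the mean + error threshold.\n")
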