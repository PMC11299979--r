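#!/usr/bin/env Rscript
# Amide temperature coefficients: which parts of the tag have weak
# hydrogen bonds?
#
# Shift-vs-temperature tables are simulated for a ubiquitin-like
# reference (uniform, well-bonded Tc around -5 ppb/K) and a
# Fat10-domain-like query whose beta1/beta2 hairpin carries markedly
# more negative coefficients (weak or absent hydrogen bonds). The
# per-residue regression, disorder flagging and segment-level
# comparison are run end to end.

suppressPackageStartupMessages(library(tagfold))
dir.create("results", showWarnings = FALSE)

set.seed(401)
residues <- 1:71
tc_ref <- rnorm(71, -5, 0.5)
tc_query <- tc_ref
weak <- residues %in% c(2:7, 11:17)           # beta1 + beta2
tc_query[weak] <- tc_query[weak] - 3.5

tabs <- lapply(list(ref = tc_ref, query = tc_query), function(tc) {
  gen_shift_table(tempco_spec(residues, tc, noise_sd = 0.003, seed = 402))
})
fits <- lapply(tabs, fit_temp_coefficients)

flagged <- flag_disordered(fits$query)
seg <- lapply(fits, segment_average)
cmp <- compare_proteins(seg$ref, seg$query)

write.table(cmp, "results/tempco_segments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Disorder-prone residues in the query (Tc < mean - SD):\n")
cat(" ", paste(flagged, collapse = " "), "\n\n")
cat("Segment comparison, delta = Tc(ref) - Tc(query) in ppb/K:\n")
print(cmp, row.names = FALSE)
cat("\nFlagged segments carry weaker hydrogen bonding in the query;\n")
cat("by construction these are the beta1/beta2 strands.\n")
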