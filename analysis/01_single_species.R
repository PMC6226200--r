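#!/usr/bin/env Rscript
# Stage 1: metabolic capabilities of each species on its own.
#
# Every species of the eight-member toy community is run as a
# single-member community on the toy western diet; its maximal growth rate
# and the net secretion rates of the crossfed byproducts and SCFA analogs
# are tabulated.  This is the baseline against which community effects
# (crossfeeding-enabled growth of otherwise non-growing species) are read.

suppressPackageStartupMessages(library(commfba))
dir.create("results", showWarnings = FALSE)

fx <- toy8_fixture()
cm <- build_community(fx$models, fx$diet, fx$policy)

prof <- single_species_profile(cm)
write.table(format(prof, digits = 12), "results/single_species_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Single-species growth rates (1/h):")
print(prof[, c("species", "growth")], row.names = FALSE)
zero <- prof$species[!is.na(prof$growth) & prof$growth < 1e-9]
message("Species unable to grow alone (obligate crossfeeders or ",
        "maintenance-limited): ", paste(zero, collapse = ", "))
message("Wrote results/single_species_profile.tsv")
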