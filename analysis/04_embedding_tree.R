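#!/usr/bin/env Rscript
# Evolutionary relationships: classical MDS of individual- and population-
# level allele-sharing distances, a neighbor-joining population tree, and
# the placement of the hypothetical insertion-free ancestor.

library(polyTE)

sim <- simulate_polyte(serial_founder_preset(seed = 42))
m <- add_ancestor(sim$matrix)
panel <- rbind(sim$panel,
               data.frame(sample = "ANCESTOR", population = "ANCESTOR",
                          group = "ANCESTOR"))
dir.create("results", showWarnings = FALSE)

d <- allele_sharing_distance(m)
pa <- population_average_distances(d, panel)

emb <- classical_mds(pa$between, k = 2, orient_negative = "AFR1")
write_embedding(emb, "results/population_mds.tsv")
cat("Population MDS (axis 1 oriented with the African pole negative):\n")
print(round(emb$points, 1))

tree <- neighbor_joining(pa$between)
write_newick(tree, "results/population_nj.nwk")
cat("NJ tree: ", write_newick(tree), "\n")

rep <- attach_ancestor_and_report(pa$between)
cat("Ancestor nearest population:", rep$nearest,
    sprintf("(mean distance %.1f)\n", rep$nearest_distance))
cat("Ancestor attachment splits the tree into:\n")
for (s in rep$split) cat("  {", paste(s, collapse = ", "), "}\n")
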