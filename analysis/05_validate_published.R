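#!/usr/bin/env Rscript
# Validation against deposited crystal structures (requires local files;
# nothing is fetched). Supply the two CpxA sensor-domain entries as
#
#   Rscript analysis/05_validate_published.R path/to/8uk7.pdb path/to/3v67.pdb
#
# and this script reproduces the three published comparisons:
#   * Calpha superposition of the E. coli domain (chain B) onto the
#     V. parahaemolyticus homolog (chain A): expect roughly 2.9 A over
#     ~108 aligned atoms;
#   * pairwise sequence identity over E. coli residues 35-150: expect
#     about 20%;
#   * crystal-contact burial of the alpha2-alpha3 spans (E. coli M33-A79,
#     V. parahaemolyticus D71-I123): expect about 48.5% and 57.1%.

suppressMessages(library(pascreen))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 2) {
  stop("usage: Rscript analysis/05_validate_published.R <8uk7.pdb> <3v67.pdb>")
}
ec <- read_structure(args[1])
vib <- read_structure(args[2])

chain_ec <- if ("B" %in% structure_chains(ec)) "B" else structure_chains(ec)[1]
chain_vib <- structure_chains(vib)[1]

cmp <- run_compare(ec, chain_ec, vib, chain_vib, window = c(35, 150))
cat(sprintf("superposition: %.2f A over %d CA atoms\n",
            cmp$superposition$rmsd, cmp$superposition$n_aligned))
cat(sprintf("sequence identity (residues 35-150): %.1f%%\n", cmp$identity))

bur_ec <- crystal_contact_burial(ec, chain_ec, resno_range = c(33, 79))
cat(sprintf("crystal-contact burial, E. coli M33-A79: %.1f%% of range (%.1f%% of chain)\n",
            100 * bur_ec$range_fraction, 100 * bur_ec$chain_fraction))
bur_vib <- crystal_contact_burial(vib, chain_vib, resno_range = c(71, 123))
cat(sprintf("crystal-contact burial, V. para D71-I123: %.1f%% of range (%.1f%% of chain)\n",
            100 * bur_vib$range_fraction, 100 * bur_vib$chain_fraction))
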