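#!/usr/bin/env Rscript
# Generate the synthetic study set: PAS monomers, dimers of both interface
# elements and both orientations, a four-strand control, and the homolog
# alignment with the planted N-cap motif frequencies. Everything downstream
# (02-04) reads from results/fixtures/.

suppressMessages(library(pascreen))

out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("monomers ...")
mono <- build_pas_monomer()
write_structure(pascreen:::.new_structure(mono$atoms, id = "pas_monomer"),
                file.path(out, "pas_monomer.pdb"))
m4 <- build_pas_monomer(fixture_spec("pas_monomer", n_strands = 4))
write_structure(pascreen:::.new_structure(m4$atoms, id = "four_strand"),
                file.path(out, "four_strand_control.pdb"))

message("dimers ...")
for (iface in c("alpha1", "alpha3")) {
  for (par in c(TRUE, FALSE)) {
    d <- build_pas_dimer(fixture_spec("pas_dimer", interface_element = iface,
                                      parallel = par, separation = 3.8))
    nm <- sprintf("dimer_%s_%s.pdb", sub("alpha", "a", iface),
                  if (par) "parallel" else "antiparallel")
    write_structure(d$structure, file.path(out, nm))
    jsonlite::write_json(d$truth, file.path(out, sub("\\.pdb$", ".json", nm)),
                         auto_unbox = TRUE)
  }
}

message("alignment ...")
built <- build_msa(fixture_spec("msa", n = 321, identity = 60, rng_seed = 1,
                                freq = c(capping_box = 0.922,
                                         non_traditional = 0.078,
                                         pre_LI = 0.894, pre_MV = 0.084)))
write_msa(built$msa, file.path(out, "homologs.fasta"))
jsonlite::write_json(built$truth, file.path(out, "homologs_truth.json"),
                     auto_unbox = TRUE)

message("wrote ", length(list.files(out)), " files under ", out)
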