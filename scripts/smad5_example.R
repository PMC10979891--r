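#!/usr/bin/env Rscript
# Full-scale worked example: zebrafish Smad5 (UniProt Q9W7E7).
#
# This run needs real inputs that must be assembled once, with network access
# and external tools, and staged under tests/testthat/fixtures/smad5/:
#
#   query.fasta  UniProt sequence:
#                  Rscript -e 'tagsite::fetch_uniprot_sequence("Q9W7E7",
#                               cache_dir = "tests/testthat/fixtures/smad5",
#                               online = TRUE)'
#                  then rename uniprot_Q9W7E7.fasta -> query.fasta
#   msa.fasta    aligned FASTA of the query plus its best BLAST hit (lowest
#                E-value) from each of: Bos taurus, Canis lupus, Gallus
#                gallus, Homo sapiens, Mus musculus, Takifugu rubripes,
#                Xenopus tropicalis; align with any standard aligner, e.g.
#                  tagsite::run_external("aligner", "mafft",
#                    args = c("--auto", "homologs.fasta"), stdout = "msa.fasta")
#   query.dssp   DSSP output for the AlphaFold model
#                (fetch_alphafold_structure("Q9W7E7", online = TRUE), then
#                 run_external("dssp", "mkdssp", ...)); alternatively stage
#                the model as model.pdb and pass `structure` below
#   anchor.txt   IUPred2A (long) + ANCHOR2 per-residue output for Q9W7E7
#
# With defaults (entropy weight 1.5, window 7) the two top-ranked sites are
# expected at positions 181 and 247, at the edges of the disordered linker
# between the MH1 and MH2 domains.

suppressMessages(library(tagsite))

dir <- "tests/testthat/fixtures/smad5"
q <- read_query_fasta(file.path(dir, "query.fasta"))
msa <- read_alignment(file.path(dir, "msa.fasta"), query_id = q$id, query = q)
d <- parse_dssp(file.path(dir, "query.dssp"))
a <- parse_iupred2a(file.path(dir, "anchor.txt"), query = q)
res <- predict_tag_sites(q, msa, dssp = d, anchor = a, top_k = 5)
print(res$sites)
write_report(res$profile, res$sites, "smad5_out")
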