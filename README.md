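# tagsite

Predicts where an epitope tag (V5, ALFA, FLAG, ...) can be inserted into a
protein with minimal risk of disrupting its function. Terminal fusions often
fail when a protein's ends are structured or mediate interactions; `tagsite`
instead screens every internal position, keeping only spots where four
independent per-residue signals *all* favour insertion.

## The score

For each 1-based query position *i*, four feature tracks are normalized to
[0, 1] (high = tag-friendly):

- **conservation** — Shannon entropy of the position's column in a multiple
  sequence alignment with vertebrate homologs,
  `H_i = -Σ_a p(x_a) log2 p(x_a)`, normalized by the maximum possible
  entropy over the 20 amino acids, `log2(20) ≈ 4.32` bits;
- **secondary structure** — the DSSP code binned by expected sensitivity to
  insertion: coil `C → 1`; helix/strand `G,H,I,E → 0`; anything else → 0.5;
- **relative solvent accessibility** — `RSA_i = SASA_i / SA_max`, the DSSP
  accessibility estimate over the residue's theoretical maximum
  (Tien et al. 2013), clamped to [0, 1];
- **disordered binding regions** — the complement `1 − BR_i` of the ANCHOR2
  probability that the residue takes part in a disordered protein-binding
  segment.

Two per-position summaries follow:

    S_i = w1·H_i/log2(20) + w2·SS_i + w3·RSA_i + w4·(1 − BR_i)     (sum score)
    E_i = min(H_i/log2(20), SS_i, RSA_i, 1 − BR_i)                 (min score)

with default weights `w = (1.5, 1, 1, 1)`. Candidate insertion sites are the
highest peaks of `E_i` after smoothing with a centred 7-residue window —
a position is only as good as its *worst* feature. A reported site at
position *i* means "tag inserted immediately after residue *i*".

## Worked example

Everything runs offline from files. The built-in fixture generator writes a
complete, internally consistent input bundle (query FASTA, 8-species
alignment, classic DSSP file, ANCHOR track, toy PDB) with one planted
7-residue window where all four features are simultaneously high:

```r
library(tagsite)

fx  <- make_fixture(length = 60, peak_position = 30, seed = 1)
q   <- read_query_fasta(fx$paths["query_fasta"])
msa <- read_alignment(fx$paths["msa"], query_id = fx$query_id, query = q)
d   <- parse_dssp(fx$paths["dssp"])
a   <- parse_iupred2a(fx$paths["anchor"], query = q)

res <- predict_tag_sites(q, msa, dssp = d, anchor = a, top_k = 3)
res$sites
#> # A tibble: 3 × 8
#>    rank position residue score entropy_norm ss_score   rsa dbr_complement
#>   <int>    <int> <chr>   <dbl>        <dbl>    <dbl> <dbl>          <dbl>
#> 1     1       30 L       0.694        0.694        1 1              0.960
#> 2     2        1 E       0            0            0 0.152          0.103
#> 3     3       10 L       0            0            0 0.294          0.1
```

The rank-1 site recovers the planted peak at position 30 with the analytic
score `3/log2(20) = 0.694`: every window column of the fixture alignment
holds 8 distinct residues (`log2(8) = 3` bits of entropy), the window is
coil, fully exposed, and outside any predicted binding region, and the
minimum of the four normalized features is the entropy term. Away from the
window the alignment is perfectly conserved, so entropy — and hence the min
score — is 0. `tidy(res$profile)` returns the full per-residue score table,
`glance(res$profile)` a one-row summary, and
`autoplot(res$profile, sites = res$sites)` draws the feature tracks with the
selected sites marked.

For a real protein, supply your own files: the query FASTA, an aligned
FASTA of the query with homologs (e.g. best BLAST hits from *Bos taurus*,
*Canis lupus*, *Gallus gallus*, *Homo sapiens*, *Mus musculus*,
*Takifugu rubripes*, *Xenopus tropicalis*), DSSP output for the AlphaFold
model (or the model itself: an internal Shrake–Rupley accessibility and a
coarse secondary-structure fallback then apply, labelled non-reference),
and IUPred2A/ANCHOR2 output. `scripts/smad5_example.R` walks through the
full-scale zebrafish Smad5 (UniProt Q9W7E7) example, whose two top-ranked
sites fall at S181 and S247, flanking the disordered MH1–MH2 linker.

There is also a command line:

```sh
Rscript inst/scripts/tagsite.R --query q.fasta --msa msa.fasta \
  --dssp q.dssp --anchor anchor.txt --out-dir out --bed
```

which writes `residue_scores.tsv` (one row per residue, all raw and
normalized tracks plus `S_i`, `E_i` and smoothed `E_i`), `ranked_sites.tsv`,
a run manifest with input checksums, and optionally a protein-coordinate
BED file of the sites.

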