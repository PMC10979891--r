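---
title: "Scoring protein positions for non-disruptive epitope tag insertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein positions for non-disruptive epitope tag insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Inserting a short epitope tag (V5, ALFA, FLAG, ...) into a protein gives you a
reliable antibody handle where none exists, but a badly placed insertion
destroys function. N- and C-terminal fusions often fail precisely for the
proteins where tagging matters most, because the termini are structured or
mediate interactions. `tagsite` scores every internal position of a query
protein for how safely a tag could be inserted there, by demanding that four
independent per-residue signals *all* favour insertion at once.

## The model

Four feature tracks are computed on the query sequence, each normalized to
$[0, 1]$ with high values meaning "tag-friendly":

1. **Conservation.** For each query position $i$, the Shannon entropy of its
   column in a multiple sequence alignment with vertebrate homologs,
   $H_i = -\sum_a p(x_a)\log_2 p(x_a)$, divided by the maximum possible
   entropy over the 20 amino acids, $\log_2(20) \approx 4.32$ bits. Variable
   (high-entropy) positions tolerate change; conserved ones likely do not.
2. **Secondary structure.** The DSSP code at each position, binned by
   expected sensitivity to an insertion: coil `C` $\to 1$; helix or strand
   `G,H,I,E` $\to 0$; everything else (`B,T,S,P`) $\to 0.5$.
3. **Relative solvent accessibility.** $RSA_i = SASA_i / SA_{max}$, the DSSP
   accessibility estimate over the residue's theoretical maximum (Tien et
   al. 2013, Gly-X-Gly values). Exposed residues accommodate an inserted
   loop; buried ones do not.
4. **Disordered binding regions.** The ANCHOR2 probability $BR_i$ that the
   residue takes part in a disordered-region protein interaction, used as
   its complement $1 - BR_i$ so predicted interaction segments are avoided.

Two per-position summaries are computed:

$$S_i = w_1\frac{H_i}{\log_2 20} + w_2\,SS_i + w_3\,RSA_i + w_4(1-BR_i)$$

$$E_i = \min\!\left(\frac{H_i}{\log_2 20},\; SS_i,\; RSA_i,\; 1-BR_i\right)$$

The sum score $S_i$ (default weights $w = (1.5, 1, 1, 1)$, up-weighting
conservation) is reported for inspection. Ranking uses the *minimum* score
$E_i$: a position is only as good as its worst feature, which is exactly the
logic of looking for a spot where *nothing* argues against insertion. $E_i$
is deliberately unweighted. After smoothing $E_i$ with a centred
7-residue sliding window, the highest peaks are reported as candidate
insertion sites.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| weights $w_1..w_4$ | 1.5, 1, 1, 1 | – | conservation is the strongest single predictor of mutational tolerance, so it is up-weighted in $S_i$; weights do not affect $E_i$ |
| `window` | 7 | residues | a tag insertion perturbs a neighbourhood, not a point; 7 residues is roughly two helical turns and matches the smoothing used for the suitability curve |
| `top_k` | 5 | sites | number of distinct peaks reported |
| `min_separation` | 8 | residues | about one window; prevents the top-$k$ list collapsing onto a single broad peak. Reported sites are distinct candidate regions |
| `probe` | 1.4 | Å | water-probe radius for the internal Shrake–Rupley accessibility fallback |
| `n_points` | 960 | – | sphere test points per atom; doubling changes per-residue SASA by under 2 % |

A reported site at position $i$ is interpreted as "tag inserted immediately
after residue $i$"; the report headers state this convention, since
1-based residue labels alone do not define insertion semantics.

## Design decisions

Several choices were genuinely open; the package resolves them as follows.

* **Gaps in entropy columns** are excluded and the probabilities
  renormalized over the residues actually present. Treating the gap as a
  21st symbol would change the normalization ceiling away from
  $\log_2(20)$; with exclusion, a fully conserved column scores 0 and a
  uniform 20-residue column scores exactly 1 after normalization. An
  all-gap column yields a missing value. The query itself is counted as a
  member of its alignment column (configurable via `include_query`).
* **RSA above 1** (possible with empirical accessibility estimates and
  theoretical maxima) is clamped to 1, preserving the $[0,1]$ contract all
  downstream scores rely on.
* **Smoothing is applied to the minimum track**, not to the features before
  the minimum, reproducing a single smoothed suitability curve; smoothing
  features first is available behind `smooth_features = TRUE` and changes
  little on smooth inputs.
* **Window edges shrink** rather than pad: zero-padding would artificially
  depress terminal scores, and termini are exactly the regions users want
  scored honestly (if usually poorly).
* **Ties** in ranking break toward the N-terminus, and best-BLAST-hit
  selection breaks E-value ties by higher bit score then lexicographic
  accession, so every run is deterministic.
* **Unknown residues (`X`)** are allowed in the query; they have no maximum
  accessibility, receive missing RSA, and are thereby excluded from
  ranking. Missing data is always an explicit `NA`, never a silent zero,
  and any position missing any feature is never reported as a site.
* **DSSP output is the reference structural path.** When only a structure
  file is supplied, a deterministic golden-angle Shrake–Rupley SASA and a
  coarse dihedral-based secondary-structure assignment stand in; both are
  labelled non-reference in the run manifest, and the internal SASA agrees
  with an independent implementation to a few Å² per residue on a real
  protein (asserted in the test suite). The dihedral fallback is
  deliberately simple and is *not* a Kabsch–Sander reimplementation.
* **External tools are wrapped, never reimplemented.** BLAST, the aligner
  and DSSP run behind a single orchestration boundary (`run_external`) and
  every stage can be bypassed with a file, so a fully offline, zero-binary
  run is always possible (and is what the test suite exercises). Network
  fetchers (UniProt sequence, AlphaFold model) are opt-in, cache to plain
  files, and validate accessions before any connection is attempted.

## What the synthetic generator emulates

`make_fixture()` writes an internally consistent toy input set — query
FASTA, 8-sequence alignment, classic-format DSSP file, CA-trace PDB and a
4-column ANCHOR track — in which one 7-residue window is, by construction,
the only region where all four features are simultaneously high. Inside the
window each homolog carries a fixed residue rotation, so every window
column holds 8 distinct residues and its entropy is exactly
$\log_2 8 = 3$ bits; outside the window the alignment is identical to the
query and entropy is exactly 0, which pins the minimum score to 0 there.
The expected peak score is therefore analytic:
$3/\log_2 20 \approx 0.694$. The seed controls the random query sequence
and cosmetic jitter of out-of-window values, none of which can move the
planted peak.

This makes the generator a sharp end-to-end oracle: recovery of the planted
site is exact for interior peaks, across seeds. It is *not* evidence about
real proteins — the fixtures have block-structured features with a single
dominant region, a CA-only pseudo-structure, and none of the correlated,
noisy tracks real data show. Passing the recovery tests demonstrates that
the plumbing, parsers, scoring and peak selection compose correctly, not
that the biological weighting is optimal.

## Numerical choices

* Entropy uses base-2 logarithms with $0\log 0 \equiv 0$; equality checks
  against closed forms are tested to $10^{-12}$.
* The Shrake–Rupley lattice is a fixed golden-angle spiral — no random
  number generation — so accessibility is bit-reproducible for a given
  `n_points`.
* Reports print scores at 6 decimals; re-reading a report reproduces the
  score vectors at that precision exactly.
* Test problem sizes: random profiles of length 50 (100 replicates) for
  the brute-force oracle comparisons, 60-residue fixtures across 20 seeds
  and three peak positions for end-to-end recovery, and a 129-residue
  lysozyme structure for the accessibility and DSSP-consistency checks.

## Known limitations

* The score is a heuristic screen, not a stability predictor: it flags
  positions where nothing obvious argues against insertion; it does not
  model the tag sequence, linker chemistry or expression context.
* Entropy from a 7-species panel is coarse; columns with few non-gap
  residues are noisy, and paralog contamination in homolog selection is not
  detected.
* The geometric secondary-structure fallback misassigns isolated strands
  and bridge residues; supply DSSP output for reference-quality tracks.
* ANCHOR2 probabilities are consumed as given; no disorder prediction is
  performed internally.

## A worked run

```{r, eval = FALSE}
library(tagsite)

fx <- make_fixture(length = 60, peak_position = 30, seed = 1)
q   <- read_query_fasta(fx$paths["query_fasta"])
msa <- read_alignment(fx$paths["msa"], query_id = fx$query_id, query = q)
d   <- parse_dssp(fx$paths["dssp"])
a   <- parse_iupred2a(fx$paths["anchor"], query = q)

res <- predict_tag_sites(q, msa, dssp = d, anchor = a)
res$sites
autoplot(res$profile, sites = res$sites)
```
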