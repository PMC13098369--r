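# File formats

TSV dialect everywhere: tab-separated, UTF-8, header row, `#` comment lines
ignored, no quoting. Missing values are format errors, not `NA`.

## Expression matrix (`read_expression` / `write_expression`)

First column `gene` (unique ids); remaining columns one per sample, header
`genotype_condition_rep` (e.g. `OE_drought_3`, replicate numeric); cells
numeric (log-scale expression).

## Gene annotation (`read_annotation` / `write_annotation`)

Columns `gene`, `class` with `class` ∈ {`TF`, `structural`}.

## DE result table (`test_differential` output, `filter_degs` input)

Columns `gene`, `log2fc`, `pvalue`, `fdr` (BH-adjusted). The DEG output adds
`direction` ∈ {`up`, `down`}.

## Coexpressed pair list (`coexpressed_pairs`)

Columns `gene_x`, `gene_y` (`gene_x < gene_y` lexicographically), `r`, `p`,
`n`.

## Network files (`write_network` / `read_network`)

Prefix-based trio:

* `<prefix>_edges.tsv` — `regulator`, `target`, `regulator_layer`,
  `target_layer`, `min_pcc`;
* `<prefix>_summary.json` — `layer_sizes` (length 4), `edge_counts`
  (length 3, root→2, 2→3, 3→4), `total`, `layers` (gene → layer map);
* `<prefix>_orphans.tsv` — template-violating edges plus a `reason` column
  (written only when orphans exist).

Planted ground truth (`write_planted_network`): `<prefix>_truth_edges.tsv`
(`regulator`, `target`) and `<prefix>_truth.json` (layer membership, seed).

## Promoter FASTA (`write_promoters` / `read_promoters`)

Record id = gene id. The description carries the ground-truth insertion log
as space-separated `element:strand:core_start` tokens (1-based plus-strand
coordinate of the core). Upstream coordinates for a promoter of length L run
`-L .. -1`; converters `upstream_to_index` / `index_to_upstream`.

## Verification table (`write_verification` / `read_verification`)

Columns `regulator`, `target`, `layer_pair` (`1-2` / `2-3` / `3-4`),
`chip_fragments` (comma-separated ChIP-positive fragment indices, or `-` for
none), `qpcr_fold`, `qpcr_p`; simulated tables add the generating `truth`
label. Summary JSON fields per layer pair: `n`, `n_direct`, `n_indirect`,
`n_unconfirmed`, `pct_direct`, `pct_indirect`, `pct_overall`.

## Motif hits (`scan_sequence`, `elements_in_fragments`)

Hit tables: `element`, `strand` (`+`/`-`), `offset` (1-based start on the +
strand), `matched` (strand-resolved bases), plus `fragment_index` for
per-fragment scans. Presence tables: `fragment_index`, `element`, `present`,
`label` (`p+`/`p-`), `n_hits`.
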