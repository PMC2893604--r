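# Bundled example data

Both files are SYNTHETIC, produced by `generate_synthetic_corpus()`
(30 proteins, planting rate 1.5, seed 20100615). They are a stand-in for a
curated caspase cleavage-site training set in the package's on-disk
training-set format, used by examples and tests of the loader/evaluation
pipeline:

- `synthetic_training_proteins.fasta` — protein sequences.
- `synthetic_training_sites.tsv` — positive P1 positions per protein
  (tab-separated; comma-joined 1-based positions).

They are NOT curated biological annotations and carry no experimentally
verified cleavage site.
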