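Synthetic toy map fixtures for examples and tests.

These tables are small, hand-constructed illustrations of the map formats
the package consumes (ICD-to-phecode, disease-to-phecode, diagnostic-ICD,
HPO annotation and HPO-to-phecode link tables). They are NOT curated
clinical maps: codes, term ids, and disease groupings are plausible-looking
but synthetic, chosen only so every pipeline stage can run without any
ontology download. Supply real map releases for any scientific use.
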