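Synthetic demonstration dataset (generated by the package's own simulator,
seed 42): 30 samples, 20 leaf taxa on a depth-3 taxonomy, 5 responses.
counts.tsv  sample x taxon integer counts
tree.nwk    taxonomy (Newick)
Y.tsv       sample x response continuous outcomes
Z.tsv       covariates (intercept + one standard-normal covariate)
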