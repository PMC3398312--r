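Place the PDB entries `1jnr.pdb` and `1kth.pdb` (downloadable from the
Protein Data Bank) in this directory to enable the published cross-fold
superposition check (1jnrA:614-629 vs 1kthA:16-31, C-alpha RMSD 2.49 A)
in the test suite. These third-party coordinate files are not
redistributed with the package.
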