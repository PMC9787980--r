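Fixture provenance: `make_ref_carbonate_grid.py` generates
`tests/testthat/ref_carbonate_grid.csv`, the frozen 125-point reference
grid for the carbonate solver, using an independently written
Python/scipy speciation solver (run from the package root:
`python data-raw/make_ref_carbonate_grid.py`).
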