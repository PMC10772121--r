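# Integration inputs (optional)

The integration tests in `test-acceptance.R` compare the package's output
against published interface measurements on deposited crystal structures.
Coordinate files are not distributed with the package; to enable those
tests, download the entries from the PDB and place them here as:

- `8tui.pdb` — Fab:KIR2DL3 complex
- `1im9.pdb` — KIR2DL1:HLA-Cw4 complex
- `1b6u.pdb` — unbound KIR2DL3

e.g. `curl -O https://files.rcsb.org/download/8TUI.pdb` (rename to
lowercase). When the files are absent the tests are skipped; everything
else in the suite runs fully offline on synthetic fixtures.
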