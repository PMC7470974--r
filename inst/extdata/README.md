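# extdata

- `synthetic_pfms.txt` — synthetic position frequency matrices
  (TATA-, CCAAT-, Sp1-, INR- and YY1-like; consensus-dominated columns,
  counts out of 100).  Constructed for the simulation module and the test
  suite; **not** derived from or redistributing any motif database.
  Users analysing real data should supply their own PFM files in the same
  JASPAR text dialect via `read_jaspar()`.
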