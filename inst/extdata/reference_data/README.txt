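Public reference data (not redistributed with the package)
===========================================================

The published-number reproduction checks in the test suite compare this
package's computations against values reported for real structures and
sequences. Those inputs are public but are not bundled here; retrieving
them requires network access. To enable the checks, place the following
files in this directory and reinstall the package:

  8JBS.pdb                      dark-state CtMerR cobalamin-binding
                                domain (https://files.rcsb.org/download/8JBS.pdb)
  8JBT.pdb                      anaerobic light-exposed CtMerR CBD
                                (https://files.rcsb.org/download/8JBT.pdb)
  TtCarH.fasta                  full-length Thermus thermophilus CarH
                                protein sequence (UniProt/NCBI)
  TaCarH_WP_053768024.fasta     full-length TaCarH (NCBI WP_053768024)
  CtMerR_WP_157850694.fasta     full-length CtMerR (NCBI WP_157850694)

Without these files the corresponding three test blocks fail with a
message pointing here; every other test is self-contained and runs on
synthetic fixtures generated in code.
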