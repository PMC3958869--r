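# Shared fixtures: molecules used across test files, built fresh each run.

mol_benzene <- function() parse_smiles("c1ccccc1", "benzene")
mol_toluene <- function() parse_smiles("Cc1ccccc1", "toluene")
mol_phenol <- function() parse_smiles("Oc1ccccc1", "phenol")
mol_cyclopentane <- function() parse_smiles("C1CCCC1", "cyclopentane")

# independent closed form for the connectivity index of an unbranched
# n-alkane with k >= 3 carbons: two terminal bonds of (1*2)^-0.5 each and
# k - 3 internal (2*2)^-0.5 bonds
chi_nalkane_closed_form <- function(k) 0.5 * (k - 3) + 2 * 2^-0.5

n_alkane_smiles <- function(k) paste(rep("C", k), collapse = "")
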