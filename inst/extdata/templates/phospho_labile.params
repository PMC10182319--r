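# Fully labile phosphopeptide search: phosphates as mass offsets on S/T/Y,
# neutral loss of phosphoric acid leaves a -18.01056 fragment remainder at
# the modified residue. Up to three phosphates per peptide.
mode = labile
precursor_tol_ppm = 20
fragment_tol_ppm = 10
series = b,y
enzyme = stricttrypsin
missed_cleavages = 2
min_len = 7
max_len = 50
clip_met = true
max_var = 3
total_mod_cap = 3
min_matched = 4
isotope_errors = 0,1,2
decoy_prefix = rev_
n_max_peaks = 150
min_peaks = 5
norm_ceiling = 100
remove_neutral_losses = true
neutral_losses = 18.01056,17.02655,97.9769
deisotope = false
assumed_charges = 2,3
fdr_threshold = 0.01
fdr_level = psm

[labile_mod]
label = phospho
offset = 79.96633
residues = STY
max_per_peptide = 3
diagnostic_mz =
diagnostic_min_intensity = 0
peptide_remainders =
fragment_remainders = -18.01056
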