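# RNA-crosslink (4-thiouridine) search: the crosslinked nucleoside
# (+226.0594) and its base after ribose loss (+94.0168) as labile offsets
# on any residue; fragments retaining the base (+94.0168 remainder) localize
# the crosslink site.
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
neutral_losses = 18.01056,17.02655
deisotope = false
assumed_charges = 2,3
fdr_threshold = 0.01
fdr_level = psm

[labile_mod]
label = 4SU_nucleoside
offset = 226.0594
residues = *
max_per_peptide = 1
diagnostic_mz =
diagnostic_min_intensity = 0
peptide_remainders =
fragment_remainders = 94.0168

[labile_mod]
label = 4SU_base
offset = 94.0168
residues = *
max_per_peptide = 1
diagnostic_mz =
diagnostic_min_intensity = 0
peptide_remainders =
fragment_remainders = 94.0168
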