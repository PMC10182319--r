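# ADP-ribosylation HCD search: ADP-ribose (+541.06111) as a labile mass
# offset on S/R/K/D/E, gated on adenine-derived diagnostic ions, with the
# ribose/phosphoribose peptide-remainder ladder. The -42.0205 fragment
# remainder (partial Arg side-chain loss) localizes Arg-linked sites.
mode = labile
precursor_tol_ppm = 20
fragment_tol_ppm = 10
series = b,y
enzyme = stricttrypsin
missed_cleavages = 3
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
label = ADPr
offset = 541.06111
residues = SRKDE
max_per_peptide = 1
diagnostic_mz = 136.06232,250.09401,348.07036,428.03669
diagnostic_min_intensity = 20
peptide_remainders = 114.03169,193.99802,291.97492,406.00661
fragment_remainders = -42.0205
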