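# UK FSA/Ofcom nutrient profiling model, 2004-05 point thresholds.
# All thresholds are per 100 g of food; a food earns k component points
# when its value is strictly greater than the k-th listed threshold.
version = fsa-ofcom-2004-05

# A-components (unfavourable), 0-10 points each
energy_kj = 335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350
satfat_g  = 1, 2, 3, 4, 5, 6, 7, 8, 9, 10
sugars_g  = 4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45
sodium_mg = 90, 180, 270, 360, 450, 540, 630, 720, 810, 900

# C-components (favourable)
# fibre: two published threshold sets, by analytical fibre definition
fibre_aoac_g = 0.9, 1.9, 2.8, 3.7, 4.7
fibre_nsp_g  = 0.7, 1.4, 2.1, 2.8, 3.5
protein_g    = 1.6, 3.2, 4.8, 6.4, 8.0

# fruit/vegetable/nut points by content band (>40%, >60%, >80%)
fvn_mid_low_points  = 1
fvn_mid_high_points = 2
fvn_max_points      = 5

# protein points are withheld when A-points reach this cap,
# unless FVN points are at the maximum level
cap_a_points = 11

# energy unit conversion applied before the kJ lookup
kcal_to_kj = 4.184

# which fibre threshold set to use by default
fibre_basis = aoac
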