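# Isotope registry for the Cerenkov simulator. Users can append entries.
# half_life_min: minutes; endpoint_keV: beta endpoint kinetic energy;
# mean_positron_range_mm: mean (not maximum) range in soft tissue;
# branching_beta: fraction of decays through the beta channel;
# daughter_Z: atomic number of the daughter nucleus (Fermi correction);
# particle: beta+ or beta-.
#
# The Ga-68 half-life is kept at the rounded clinical figure of 68 min.
isotopes:
  - name: Ga-68
    half_life_min: 68
    endpoint_keV: 1899.1
    mean_positron_range_mm: 2.8
    branching_beta: 0.889
    daughter_Z: 30
    particle: beta+
  - name: F-18
    half_life_min: 109.77
    endpoint_keV: 633.5
    mean_positron_range_mm: 0.6
    branching_beta: 0.967
    daughter_Z: 8
    particle: beta+
  - name: Zr-89
    half_life_min: 4704
    endpoint_keV: 902.0
    mean_positron_range_mm: 1.2
    branching_beta: 0.227
    daughter_Z: 39
    particle: beta+
  - name: Y-90
    half_life_min: 3847
    endpoint_keV: 2280.0
    mean_positron_range_mm: 3.6
    branching_beta: 1.0
    daughter_Z: 40
    particle: beta-
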