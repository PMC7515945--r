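# Default synthetic study configuration: one surface lesion (positive
# margin) on the anterior view, imaged on all six sides with the favoured
# clinical protocol (150 s, 8x8 binning, with and without the 550 nm
# shortpass filter). Acquisition starts 73 min after injection.
patient_id: synthetic-psm
isotope: Ga-68
injected_activity_MBq: 100
injection_time: "2020-01-01T09:00:00Z"
benign_radiance: 500
reference_activity_MBq: 100
acquisition_delay_min: 73
lesions:
  - view: anterior
    depth_mm: 0
    ratio: 8
    lateral_sigma_mm: 2
    center: [128, 128]
protocol:
  - exposure_s: 150
    binning: 8
    filter: none
  - exposure_s: 150
    binning: 8
    filter: shortpass_550
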