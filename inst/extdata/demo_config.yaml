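# Demonstration pipeline configuration: two imaging conditions on synthetic
# phantoms, two motility conditions, and a linearly closing scratch wound.
pixel_size_um: 0.25
seed: 11
out_dir: cellquant_demo
stages: [synth, quantify, motility, wound, report]
phantoms:
  n_per_condition: 3
  noise_sd_frac: 0.05
  conditions:
    control:
      enrichment_fold: 1.0
      nc_ratio: 1.0
    stimulated:
      enrichment_fold: 2.0
      nc_ratio: 0.65
segmentation:
  offset: 0.05
  ring_thickness_um: 2
  box_size_um: 3.88
  nucleus_dilation_um: 2
tracks:
  conditions:
    control:
      model: random_walk
      D_um2_h: 20
      n_tracks: 10
    stimulated:
      model: random_walk
      D_um2_h: 60
      n_tracks: 10
wound:
  width_um: 150
  closure_rate_um_per_h: 6.25
  timepoints_h: [0, 6, 12, 18, 24]
report:
  control: control
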