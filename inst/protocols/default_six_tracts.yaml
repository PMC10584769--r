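# Shipped tract protocols for the six clinically relevant tracts.
# Label names use {h}/{ch} for the ipsilateral/contralateral hemisphere
# suffix and {hside}/{chside} for side arguments; resolve with a hemisphere
# before building ROIs. Streamline counts and fODF amplitude cutoffs are the
# per-tract production settings; tests and phantom runs override the counts.
tracts:
  - name: CST
    n_streamlines: 7500
    max_length_mm: 150
    amplitude_cutoff_fraction: 0.07
    rfbc_threshold: 1.0e-3
    seed:
      op: axial_slab
      thickness_mm: 4
      reference: {op: select, labels: [fourth_ventricle]}
      of:
        op: split_axis
        axis: AP
        side: anterior
        fraction: 0.5
        of:
          op: split_axis
          axis: LR
          side: "{hside}"
          fraction: 0.5
          of: {op: select, labels: [brainstem]}
    targets:
      - {op: select, labels: ["precentral_gyrus_{h}"]}
    excludes:
      - op: split_axis
        axis: LR
        side: "{chside}"
        fraction: 0.5
        of: {op: select, labels: [brainstem]}
      - {op: select, labels: ["thalamus_{h}", "thalamus_{ch}"]}

  - name: IFOF
    n_streamlines: 15000
    max_length_mm: 150
    amplitude_cutoff_fraction: 0.07
    rfbc_threshold: 1.0e-3
    seed:
      op: select
      labels: ["pars_triangularis_{h}", "pars_opercularis_{h}",
               "pars_orbitalis_{h}", "anterior_orbital_gyrus_{h}",
               "posterior_orbital_gyrus_{h}", "frontal_pole_{h}"]
    targets:
      - op: select
        labels: ["inferior_occipital_gyrus_{h}", "middle_occipital_gyrus_{h}",
                 "superior_occipital_gyrus_{h}"]
    includes:
      - op: sphere_between
        volume_mm3: 24
        a: {op: select, labels: ["posterior_insula_{h}"]}
        b: {op: select, labels: ["putamen_{h}"]}
        within: {op: select, labels: [white_matter]}

  - name: OR
    n_streamlines: 7500
    max_length_mm: 150
    amplitude_cutoff_fraction: 0.10
    rfbc_threshold: 1.0e-3
    seed_cone: {axis: lateral, half_angle_deg: 45}
    seed:
      op: dilate
      sigma_mm: 1.5
      of: {op: select, labels: ["lgn_{h}"]}
    targets:
      - {op: select, labels: ["calcarine_cortex_{h}"]}
    excludes:
      - {op: select, labels: ["precuneus_{h}"]}
      - {op: select, labels: [basal_forebrain]}
      - {op: select, labels: ["lingual_gyrus_{h}"]}

  - name: AF
    n_streamlines: 7500
    max_length_mm: 150
    amplitude_cutoff_fraction: 0.075
    rfbc_threshold: 1.0e-3
    seed:
      op: union
      of:
        - {op: select, labels: ["pars_triangularis_{h}", "pars_opercularis_{h}"]}
        - op: split_axis
          axis: IS
          side: inferior
          fraction: 0.5
          of: {op: select, labels: ["precentral_gyrus_{h}"]}
    targets:
      - op: split_axis
        axis: AP
        side: posterior
        fraction: 0.3333333333
        of:
          op: select
          labels: ["superior_temporal_gyrus_{h}", "middle_temporal_gyrus_{h}"]
    excludes:
      - {op: select, labels: ["putamen_{h}"]}
      - {op: select, labels: ["anterior_insula_{h}"]}
      - {op: select, labels: ["thalamus_{h}"]}

  - name: FAT
    n_streamlines: 5000
    max_length_mm: 150
    amplitude_cutoff_fraction: 0.09
    rfbc_threshold: 1.0e-3
    seed:
      op: plane_split
      keep: posterior
      landmark: {op: select, labels: [corpus_callosum_genu]}
      of: {op: select, labels: ["sma_{h}", "pre_sma_{h}"]}
    targets:
      - {op: select, labels: ["pars_opercularis_{h}", "pars_triangularis_{h}"]}

  - name: SLF3
    n_streamlines: 7000
    max_length_mm: 150
    amplitude_cutoff_fraction: 0.08
    rfbc_threshold: 1.0e-3
    seed:
      op: union
      of:
        - {op: select, labels: ["pars_triangularis_{h}", "pars_opercularis_{h}"]}
        - op: split_axis
          axis: IS
          side: inferior
          fraction: 0.5
          of: {op: select, labels: ["precentral_gyrus_{h}"]}
    targets:
      - {op: select, labels: ["supramarginal_gyrus_{h}"]}
    excludes:
      - {op: select, labels: ["angular_gyrus_{h}"]}
      - {op: select, labels: ["thalamus_{h}"]}
      - op: dilate
        sigma_mm: 3.0
        of: {op: select, labels: ["superior_temporal_gyrus_{h}"]}
        constraint:
          op: select
          labels: ["superior_temporal_gyrus_{h}", "middle_temporal_gyrus_{h}",
                   "angular_gyrus_{h}"]
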