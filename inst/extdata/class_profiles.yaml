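# Synthetic cohort class profiles. mean_abundance is the per-pixel
# component abundance in canonical order
# (protein, nucleic_acid, unsaturated_lipid, saturated_lipid), in a.u.
# on the unit-norm reference scale. Magnitudes are simulator plumbing
# chosen to encode the qualitative biology (AML lipid-elevated vs normal
# counterparts, M3 most unsaturated / M5 most saturated among AML, ALL
# lipid-poor vs AML, Ph+ >= Ph- in unsaturated lipid); edit freely.
classes:
  - class_label: AML-M2
    mean_abundance: [0.80, 0.32, 0.40, 0.25]
    cv_abundance: 0.10
    mean_radius_px: 11
    cv_radius: 0.06
  - class_label: AML-M3
    mean_abundance: [0.90, 0.28, 0.72, 0.33]
    cv_abundance: 0.10
    mean_radius_px: 12
    cv_radius: 0.06
  - class_label: AML-M4
    mean_abundance: [0.72, 0.46, 0.50, 0.46]
    cv_abundance: 0.10
    mean_radius_px: 13.5
    cv_radius: 0.06
  - class_label: AML-M5
    mean_abundance: [1.00, 0.60, 0.54, 0.66]
    cv_abundance: 0.10
    mean_radius_px: 15
    cv_radius: 0.06
  - class_label: ALL-Ph-
    mean_abundance: [0.56, 0.66, 0.13, 0.11]
    cv_abundance: 0.10
    mean_radius_px: 8
    cv_radius: 0.06
  - class_label: ALL-Ph+
    mean_abundance: [0.68, 0.54, 0.32, 0.15]
    cv_abundance: 0.10
    mean_radius_px: 10
    cv_radius: 0.06
  - class_label: HSPC
    mean_abundance: [0.50, 0.45, 0.12, 0.10]
    cv_abundance: 0.10
    mean_radius_px: 9
    cv_radius: 0.06
  - class_label: granulocyte
    mean_abundance: [0.55, 0.50, 0.18, 0.16]
    cv_abundance: 0.10
    mean_radius_px: 10
    cv_radius: 0.06
  - class_label: monocyte
    mean_abundance: [0.60, 0.45, 0.20, 0.18]
    cv_abundance: 0.10
    mean_radius_px: 11
    cv_radius: 0.06
  - class_label: B_cell
    mean_abundance: [0.45, 0.50, 0.10, 0.09]
    cv_abundance: 0.10
    mean_radius_px: 8
    cv_radius: 0.06
  - class_label: T_cell
    mean_abundance: [0.42, 0.48, 0.09, 0.08]
    cv_abundance: 0.10
    mean_radius_px: 8
    cv_radius: 0.06
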