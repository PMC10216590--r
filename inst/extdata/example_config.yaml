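# Example run configuration for the omlit CLI / run_*() functions.
materials: bundled        # or a path to a material CSV/JSON
contrast_mode: ratio      # or michelson
stack:
  section_thickness_nm: 60
  coating: none           # or {material: silver, thickness_nm: 70}
  tape_material: polycarbonate_tape
  tape_thickness_nm: 50000
  carbon_tape_thickness_nm: 100000
  substrate: silicon
  cell_material: stained_cell
  surround_material: stained_tissue
illumination:
  wavelength_nm: 470
  angle_deg: 0
  polarization: unpolarized
  fwhm_nm: 0
  na: 0
sweep:
  wavelengths_nm: [390, 470, 555, 630]
  # section_nm / coating_nm default to 10-300 / 10-400 nm in 5 nm steps
  fraction: 0.95
  materials: [silver, chromium, copper]
phantom:
  dim_vox: [192, 192, 24]
  voxel_size_nm: 500
  n_somata: 25
  n_vessels: 2
  processes_per_cell: 2
  n_sections: 3
rois:
  n_pairs: 50
  roi_size: 11
noise:
  gaussian_sd: 0
  poisson_scale: 0
defects:
  n_scratches: 0
  n_cracks: 0
  n_specks: 0
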