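material_id,wavelength_nm,n,k
air,340,1,0
air,390,1,0
air,470,1,0
air,555,1,0
air,630,1,0
air,680,1,0
silicon,340,5.1,2.9
silicon,390,5.8,0.37
silicon,470,4.49,0.1
silicon,555,4.07,0.028
silicon,630,3.88,0.016
silicon,680,3.81,0.011
polycarbonate_tape,340,1.639,0.001
polycarbonate_tape,390,1.613,0
polycarbonate_tape,470,1.599,0
polycarbonate_tape,555,1.589,0
polycarbonate_tape,630,1.583,0
polycarbonate_tape,680,1.579,0
carbon_tape,340,2.05,0.68
carbon_tape,390,2.1,0.7
carbon_tape,470,2.15,0.72
carbon_tape,555,2.2,0.75
carbon_tape,630,2.25,0.78
carbon_tape,680,2.28,0.8
silver,340,0.18,1.25
silver,390,0.05,1.96
silver,470,0.046,2.79
silver,555,0.055,3.48
silver,630,0.053,4.15
silver,680,0.046,4.6
chromium,340,2.0,2.95
chromium,390,2.35,3.12
chromium,470,2.82,3.28
chromium,555,3.12,3.32
chromium,630,3.16,3.3
chromium,680,3.1,3.3
copper,340,1.3,1.95
copper,390,1.22,2.17
copper,470,1.15,2.42
copper,555,1.04,2.59
copper,630,0.42,3.27
copper,680,0.22,4.0
stained_tissue,340,1.56,0.027
stained_tissue,390,1.556,0.025
stained_tissue,470,1.551,0.022
stained_tissue,555,1.547,0.02
stained_tissue,630,1.545,0.018
stained_tissue,680,1.544,0.017
stained_cell,340,1.59,0.102
stained_cell,390,1.585,0.095
stained_cell,470,1.578,0.085
stained_cell,555,1.572,0.078
stained_cell,630,1.568,0.072
stained_cell,680,1.566,0.068
stained_tissue_post,340,1.565,0.043
stained_tissue_post,390,1.561,0.04
stained_tissue_post,470,1.556,0.035
stained_tissue_post,555,1.552,0.032
stained_tissue_post,630,1.55,0.029
stained_tissue_post,680,1.549,0.027
stained_cell_post,340,1.6,0.16
stained_cell_post,390,1.595,0.15
stained_cell_post,470,1.588,0.135
stained_cell_post,555,1.582,0.124
stained_cell_post,630,1.578,0.115
stained_cell_post,680,1.576,0.108
resin,340,1.527,0.004
resin,390,1.522,0.003
resin,470,1.516,0.002
resin,555,1.512,0.002
resin,630,1.51,0.001
resin,680,1.509,0.001
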