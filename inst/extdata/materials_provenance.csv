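material_id,provenance
air,"Unity index, non-absorbing by definition."
silicon,"Crystalline Si, Aspnes & Studna (1983) ellipsometric tabulation, interpolated to the LED lines."
polycarbonate_tape,"Polycarbonate (Panlite-type film), Sellmeier fit of Sultanova et al. (2009); visible-range absorption neglected."
carbon_tape,"Synthetic placeholder: representative amorphous-carbon constants standing in for conductive adhesive carbon tape."
silver,"Johnson & Christy (1972) noble-metal tabulation, interpolated to the LED lines."
chromium,"Johnson & Christy (1974) transition-metal tabulation, interpolated to the LED lines."
copper,"Johnson & Christy (1972) noble-metal tabulation, interpolated to the LED lines."
stained_tissue,"Synthetic placeholder: resin-embedded osmium-stained neuropil modelled as a weakly absorbing dielectric."
stained_cell,"Synthetic placeholder: cell body/nucleus with heavier heavy-metal deposition, hence higher n and k than stained_tissue."
stained_tissue_post,"Synthetic placeholder: stained_tissue after uranyl acetate/lead citrate poststaining (increased k)."
stained_cell_post,"Synthetic placeholder: stained_cell after uranyl acetate/lead citrate poststaining (increased k)."
resin,"Synthetic placeholder: bare embedding epoxy (Epon-type), nearly lossless; used for vessel lumina."
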