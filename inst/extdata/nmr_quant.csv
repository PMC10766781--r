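sample_id,aldehyde_mol_per_kg,epoxide_mol_per_kg,hydroperoxide_mol_per_kg,mean_tag_mass
oxidized_rapeseed_oil,0.022,0.167,0.236,885
fresh_rapeseed_oil,0,0,0.009,885
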