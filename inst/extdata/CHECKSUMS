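76262df974c38074080b85f94e92a0f2  cie_daylight_components_10nm.tsv
811c402f4abc29a8f1b6dcda67ec8a0b  cie_xyz_cmf_2deg_10nm.tsv
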