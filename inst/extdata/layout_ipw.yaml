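name: IPW
rows: [115, 117, 119]
panels: [1, 3, 5, 7, 9, 11]
row_width: 2.5
panel_width: 9.0
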