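name: BD
rows: [1, 4, 7, 10, 13, 16, 19]
panels: [3, 7, 11]
row_width: 2.5
panel_width: 9.0
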