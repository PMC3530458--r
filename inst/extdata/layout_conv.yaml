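name: CONV
rows: [9, 11, 13, 15, 17, 19]
panels: [3, 7, 11]
row_width: 2.5
panel_width: 9.0
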