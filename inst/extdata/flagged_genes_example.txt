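MUC16
MUC4
TTN
HLA-A
HLA-B
HLA-DRB1
PDE4DIP
HYDIN
AHNAK2
FLG
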