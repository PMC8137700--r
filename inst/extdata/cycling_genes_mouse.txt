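# Mouse cell cycle genes excluded from variable-gene selection by default.
# Editable: one symbol per line, '#' comments.
Mki67
Top2a
Ccnb1
Ccnb2
Ccna2
Ccne1
Cdk1
Cdc20
Cdc6
Cdca3
Cdca8
Birc5
Bub1
Bub1b
Plk1
Aurka
Aurkb
Mcm2
Mcm3
Mcm4
Mcm5
Mcm6
Mcm7
Pcna
Tyms
Rrm1
Rrm2
Dut
Hells
Ung
Tipin
Gins2
Cenpa
Cenpe
Cenpf
Hmgb2
Tubb5
Stmn1
Hist1h1b
Hist1h2ap
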