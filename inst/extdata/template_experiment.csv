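# class: Cer
# mode: gradient
# flow_rate: 0.2 mL/min
# column: Agilent XDB-C8 3x150 mm
lipid_name,precursor_mz,product_mz,role,rt
Cer (d18:2/16:1),534.5,262.3,Test,
Cer (d18:2/16:0),536.5,262.3,Test,
Cer (d18:1/16:1),536.5,264.3,Test,
Cer (d18:1/16:0),538.6,264.3,Train,15.05
Cer (d18:0/16:0),540.5,266.3,Train,15.27
Cer (d18:1/17:0),552.7,264.3,Train,15.33
Cer (d18:2/18:1),562.5,262.3,Test,
Cer (d18:2/18:0),564.5,262.3,Test,
Cer (d18:1/18:1),564.5,264.3,Train,15.05
Cer (d18:1/18:0),566.6,264.3,Train,15.7
Cer (d18:0/18:0),568.6,266.3,Train,15.91
Cer (d18:2/20:0),592.6,262.3,Test,
Cer (d18:1/20:1),592.6,264.3,Test,
Cer (d18:1/20:0),594.6,264.3,Train,16.28
Cer (d18:0/20:0),596.6,266.3,Test,
Cer (d18:2/22:0),620.6,262.3,Test,
Cer (d18:1/22:1),620.6,264.3,Test,
Cer (d18:1/22:0),622.6,264.3,Train,16.94
Cer (d18:0/22:0),624.6,266.3,Test,
Cer (d18:2/24:1),646.6,262.3,Test,
Cer (d18:2/24:0),648.6,262.3,Test,
Cer (d18:1/24:1),648.6,264.3,Train,17.08
Cer (d18:1/24:0),650.7,264.3,Train,17.68
Cer (d18:0/24:0),652.9,266.3,Train,17.95
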