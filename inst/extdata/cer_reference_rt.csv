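lipid_name,precursor_mz,product_mz,is_reference,serum_pred,serum_user,serum_err,csf_pred,csf_user,csf_err,liver_pred,liver_user,liver_err,brain_pred,brain_user,brain_err
Cer (d18:2/16:1),534.5,262.3,0,14.20,13.9,2.16,14.19,14.05,1.00,6.9,ND,,2.49,ND,
Cer (d18:2/16:0),536.5,262.3,0,14.78,14.55,1.58,14.66,14.58,0.55,7.54,7.62,1.05,3.24,3.61,0.00
Cer (d18:1/16:1),536.5,264.3,0,14.45,14.31,0.98,14.40,14.48,0.55,7.38,7.4,0.27,3.19,3.45,7.54
Cer (d18:1/16:0),538.6,264.3,1,15.03,15.05,0.13,14.88,14.86,0.13,8.02,8.04,0.25,3.94,4.1,3.90
Cer (d18:0/16:0),540.5,266.3,1,15.29,15.27,0.13,15.10,15.08,0.13,8.5,8.52,0.23,4.64,4.7,1.28
Cer (d18:1/17:0),552.7,264.3,1,15.34,15.33,0.07,15.19,15.20,0.07,8.4,8.40,0.00,4.7,4.8,2.08
Cer (d18:2/18:1),562.5,262.3,0,14.82,14.57,1.72,14.81,14.68,0.89,7.66,7.64,0.26,4.06,4.1,0.98
Cer (d18:2/18:0),564.5,262.3,0,15.40,15.27,0.85,15.29,15.18,0.72,8.3,8.27,0.36,4.83,4.99,3.21
Cer (d18:1/18:1),564.5,264.3,1,15.07,15.05,0.13,15.03,15.11,0.53,8.14,8.10,0.49,4.78,4.77,0.21
Cer (d18:1/18:0),566.6,264.3,1,15.66,15.70,0.25,15.51,15.50,0.06,8.78,8.72,0.69,5.55,5.5,0.91
Cer (d18:0/18:0),568.6,266.3,1,15.91,15.91,0.00,15.72,15.72,0.00,9.25,9.24,0.11,6.27,6.1,2.79
Cer (d18:2/20:1),590.6,262.3,0,15.46,NA,,15.43,NA,,8.42,ND,,5.95,5.95,0.00
Cer (d18:2/20:0),592.6,262.3,0,16.05,15.95,0.63,15.91,15.73,1.14,9.07,9.07,0.00,6.74,6.75,0.15
Cer (d18:1/20:1),592.6,264.3,0,15.72,15.7,0.13,15.65,15.62,0.19,8.9,8.9,0.00,6.69,6.35,5.35
Cer (d18:1/20:0),594.6,264.3,1,16.31,16.28,0.18,16.13,16.11,0.12,9.54,9.59,0.52,7.49,7.28,2.88
Cer (d18:0/20:0),596.6,266.3,0,16.56,16.51,0.30,16.35,16.3,0.31,10.02,10.08,0.60,8.24,ND,
Cer (d18:2/22:1),618.6,262.3,0,16.13,NA,,16.05,NA,,9.2,ND,,8.16,8,2.00
Cer (d18:2/22:0),620.6,262.3,0,16.72,16.52,1.21,16.53,16.32,1.29,9.84,9.78,0.61,8.97,9.12,1.64
Cer (d18:1/22:1),620.6,264.3,0,16.39,16.28,0.68,16.27,16.27,0.00,9.68,9.68,0.00,8.92,8.88,0.45
Cer (d18:1/22:0),622.6,264.3,1,16.98,16.94,0.24,16.75,16.72,0.18,10.32,10.3,0.19,9.74,9.63,1.14
Cer (d18:0/22:0),624.6,266.3,0,17.24,17.15,0.52,16.97,16.93,0.24,10.8,10.77,0.28,10.51,10.47,0.38
Cer (d18:2/24:1),646.6,262.3,0,16.82,16.64,1.08,16.67,16.45,1.34,9.98,9.94,0.40,10.66,10.5,1.52
Cer (d18:2/24:0),648.6,262.3,0,17.41,17.27,0.81,17.15,16.95,1.18,10.62,10.62,0.00,11.5,11.9,3.36
Cer (d18:1/24:1),648.6,264.3,1,17.08,17.08,0.00,16.89,16.81,0.48,10.46,10.46,0.00,11.45,11.46,0.09
Cer (d18:1/24:0),650.7,264.3,1,17.67,17.68,0.06,17.37,17.41,0.23,11.1,11.12,0.18,12.29,12.4,0.89
Cer (d18:0/24:0),652.9,266.3,1,17.93,17.95,0.11,17.59,17.67,0.45,11.58,11.58,0.00,13.09,13.2,0.83
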