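lipid_name,precursor_mz,product_mz,product_mz2,is_reference,serum_pred,serum_user,serum_err,csf_pred,csf_user,csf_err,liver_pred,liver_user,liver_err,brain_pred,brain_user,brain_err
SM (d18:1/12:0),647.5,184,264.3,1,13.31,13.3,0.08,13.13,13.12,0.08,6.06,6.00,1.00,2.69,2.73,1.47
SM (d18:2/16:1),699.6,184,262.3,0,13.73,13.66,0.51,13.54,13.61,0.51,6.40,ND,,2.50,2.58,3.10
SM (d18:2/16:0),701.6,184,262.3,0,14.37,14.20,1.20,14.08,14.1,0.14,6.79,6.72,1.04,3.29,3.26,0.92
SM (d18:1/16:1),701.6,184,264.3,1,14.05,14.15,0.71,13.92,14.05,0.93,6.53,6.60,1.06,2.98,3.04,1.97
SM (d18:1/16:0),703.5,184,264.3,1,14.69,14.69,0.00,14.47,14.5,0.21,6.91,6.96,0.72,3.77,3.9,3.33
SM (d18:0/16:0),705.6,184,266.3,0,15.00,14.99,0.07,14.86,14.81,0.34,7.04,7.18,1.95,4.25,4.3,1.16
SM (d18:2/18:1),727.6,184,262.3,0,14.40,14.37,0.21,14.20,14.24,0.28,6.94,ND,,3.62,3.53,2.55
SM (d18:2/18:0),729.6,184,262.3,0,15.04,14.94,0.67,14.74,14.80,0.41,7.33,7.24,1.24,4.43,4.25,4.24
SM (d18:1/18:1),729.6,184,264.3,0,14.72,14.86,0.94,14.58,ND,,7.06,7.14,1.12,4.12,3.98,3.52
SM (d18:1/18:0),731.6,184,264.3,1,15.35,15.39,0.26,15.13,15.11,0.13,7.45,7.44,0.13,4.94,4.96,0.40
SM (d18:0/18:0),733.6,184,266.3,1,15.67,15.64,0.19,15.51,15.51,0.00,7.58,7.63,0.66,5.45,5.58,2.33
SM (d18:2/20:1),755.6,184,262.2,0,15.06,15.19,0.86,14.85,14.94,0.60,7.54,ND,,5.13,4.95,3.64
SM (d18:2/20:0),757.6,184,262.3,0,15.70,15.61,0.58,15.39,15.42,0.19,7.94,7.71,2.98,5.97,5.64,5.85
SM (d18:1/20:1),757.6,184,264.3,0,15.38,15.58,1.28,15.23,ND,,7.68,7.61,0.92,5.66,5.32,6.39
SM (d18:1/20:0),759.6,184,264.3,0,16.01,16.15,0.87,15.78,15.74,0.25,8.07,7.98,1.13,6.51,6.4,1.72
SM (d18:0/20:0),761.6,184,266.3,0,16.32,16.31,0.06,16.16,16.16,0.00,8.21,8.20,0.12,7.05,ND,
SM (d18:2/22:1),783.7,184,262.3,0,15.71,15.68,0.19,15.49,15.62,0.83,8.22,ND,,7.03,6.95,1.15
SM (d18:2/22:0),785.7,184,262.3,0,16.34,16.23,0.68,16.04,16.04,0.00,8.62,8.46,1.89,7.90,7.65,3.27
SM (d18:1/22:1),785.7,184,264.3,0,16.02,16.01,0.06,15.88,15.90,0.13,8.36,8.36,0.00,7.59,7.40,2.57
SM (d18:1/22:0),787.7,184,264.3,0,16.65,16.61,0.24,16.42,16.34,0.49,8.76,8.82,0.68,8.46,8.30,1.93
SM (d18:0/22:0),789.7,184,266.3,0,16.97,16.86,0.65,16.81,16.79,0.12,8.90,9.05,1.66,9.03,9.10,0.77
SM (d18:2/24:1),811.7,184,262.3,0,16.34,16.31,0.18,16.13,16.13,0.00,8.97,ND,,9.30,9.20,1.09
SM (d18:2/24:0),813.7,184,262.3,0,16.97,16.83,0.83,16.68,16.61,0.42,9.38,9.24,1.52,10.20,10.07,1.29
SM (d18:1/24:1),813.7,184,264.3,1,16.65,16.68,0.18,16.52,16.52,0.00,9.11,9.04,0.77,9.89,9.83,0.61
SM (d18:1/24:0),815.7,184,264.3,1,17.28,17.28,0.00,17.06,17.06,0.00,9.52,9.60,0.83,10.79,11.10,2.79
SM (d18:0/24:0),817.7,184,266.3,0,17.60,17.50,0.57,17.45,17.43,0.11,9.66,9.81,1.53,11.38,11.69,2.65
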