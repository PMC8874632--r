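solvent_name,inv_dielectric,LC-BLYP,LC-PBE,MN12SX,CAM-B3LYP,LC-wHPBE,wB97XD,M11,RSX-PBE,RSX-PBE0,RSX-PBE0-1/3
NMF,0.0055,4.17,4.16,0.02,2.15,3.88,2.91,3.54,4.06,4.24,4.32
Formamide,0.0092,4.18,4.17,0.02,2.16,3.89,2.92,3.55,4.08,4.25,4.33
H2O,0.0128,4.16,4.16,0.01,2.15,3.87,2.90,3.53,4.06,4.23,4.32
Methanol,0.0307,4.09,4.08,0.05,2.08,3.80,2.84,3.46,3.99,4.16,4.24
Ethanol,0.0402,4.00,3.99,0.11,2.00,3.81,2.76,3.38,3.38,4.07,4.16
Acetone,0.0488,3.73,3.72,0.27,1.77,3.45,2.53,3.12,3.01,3.80,3.88
DCE,0.0988,3.62,3.61,0.37,1.65,3.33,2.42,3.01,2.89,3.68,3.77
THF,0.1347,3.45,3.44,0.48,1.50,3.16,2.26,2.84,2.72,3.51,3.59
DBE,0.3282,2.95,2.94,0.85,1.03,2.67,1.80,2.36,2.60,3.02,3.10
Cyclohexane,0.4959,2.56,2.55,1.14,0.66,2.29,1.43,1.98,2.47,2.63,2.71
n-Hexane,0.5314,2.48,2.47,2.03,0.58,2.21,1.35,1.90,2.39,2.55,2.63
Gas,1.0000,1.36,1.35,2.08,0.48,1.09,0.28,0.79,1.26,1.42,1.50
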