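locus,A,Ho,He,Fis,hwe_p,f_null,PIC,PI,PI_sibs,NE_1P,NE_2P,NE_PP,NE_I,NE_SI
ER24,16,0.594,0.696,0.154,0.0104,0.079,0.675,0.11,0.43,0.678,0.489,0.272,0.114,0.430
ER40,10,0.696,0.799,0.136,0.4742,0.071,0.773,0.066,0.37,0.560,0.383,0.196,0.066,0.367
ER28,14,0.826,0.864,0.052,0.1114,0.021,0.850,0.032,0.33,0.426,0.269,0.107,0.032,0.326
ER21,13,0.913,0.889,-0.020,0.4540,-0.013,0.879,0.022,0.31,0.367,0.223,0.078,0.022,0.311
ER38,12,0.797,0.799,0.010,0.3520,0.003,0.772,0.068,0.37,0.563,0.387,0.202,0.068,0.367
ER15,21,0.913,0.908,0.002,0.7325,-0.002,0.901,0.016,0.30,0.313,0.185,0.055,0.016,0.300
ER32,9,0.638,0.730,0.133,0.4697,0.066,0.695,0.11,0.41,0.663,0.482,0.287,0.107,0.412
ER7,10,0.899,0.851,-0.048,0.7983,-0.028,0.834,0.040,0.33,0.463,0.299,0.131,0.040,0.334
ER4,17,0.696,0.850,0.188,0.0675,0.102,0.834,0.039,0.33,0.456,0.294,0.124,0.039,0.335
ER5,14,0.826,0.842,0.026,0.7992,0.009,0.823,0.045,0.34,0.484,0.316,0.146,0.045,0.340
ER39,22,0.913,0.923,0.018,0.5100,0.004,0.918,0.011,0.29,0.269,0.156,0.040,0.011,0.291
ER13,19,0.913,0.885,-0.025,0.2387,-0.017,0.874,0.023,0.31,0.373,0.229,0.080,0.023,0.314
ER25,19,0.896,0.914,0.028,0.3522,0.010,0.908,0.014,0.30,0.295,0.173,0.049,0.014,0.296
ER31,26,0.754,0.935,0.201,0.0000,0.106,0.931,0.0079,0.28,0.231,0.131,0.029,0.008,0.285
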