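locus,mix,dye,motif_length,size_min,size_max
ER24,1,TAM,3,128,185
ER40,1,FAM,3,190,217
ER28,1,HEX,3,214,283
ER21,1,ROX,4,225,273
ER38,1,FAM,3,283,358
ER15,1,HEX,4,299,415
ER32,2,TAM,3,106,139
ER7,2,ROX,4,262,294
ER4,2,FAM,4,204,292
ER5,2,FAM,4,308,428
ER39,3,TAM,3,144,216
ER13,3,ROX,4,180,256
ER25,3,HEX,3,272,332
ER31,3,FAM,3,298,344
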