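id,population,role,ER24_1,ER24_2,ER40_1,ER40_2,ER28_1,ER28_2,ER21_1,ER21_2,ER38_1,ER38_2,ER15_1,ER15_2,ER32_1,ER32_2,ER7_1,ER7_2,ER4_1,ER4_2,ER5_1,ER5_2,ER39_1,ER39_2,ER13_1,ER13_2,ER25_1,ER25_2,ER31_1,ER31_2
MO6-F,Bialowieza,adult,140,155,208,214,220,235,249,265,283,295,311,327,118,127,278,286,224,228,316,332,180,186,192,208,302,311,334,343
MO6-M,Bialowieza,adult,137,137,205,205,217,229,253,257,295,298,303,331,118,121,270,286,216,228,316,328,183,201,196,224,290,305,316,322
MO6-1,Bialowieza,nestling,137,140,205,208,220,229,257,265,295,295,311,331,118,121,270,278,216,224,316,328,183,186,208,228,290,311,316,343
MO6-2,Bialowieza,nestling,137,140,205,208,220,229,249,257,295,298,303,327,121,127,270,286,228,228,316,316,183,186,196,208,302,305,316,334
MO6-3,Bialowieza,nestling,137,140,205,214,217,220,249,257,295,298,303,311,118,118,270,278,216,224,328,332,180,183,208,224,302,305,322,343
MO6-4,Bialowieza,nestling,137,155,205,214,217,235,249,257,283,298,303,311,121,127,270,286,228,228,328,332,186,201,208,224,290,311,316,334
MO6-5,Bialowieza,nestling,137,155,205,208,217,235,249,253,283,295,303,311,118,118,278,286,216,224,316,328,183,186,192,196,305,311,322,334
MO6-6,Bialowieza,nestling,137,155,205,208,217,220,253,265,295,298,303,311,118,121,270,286,216,228,328,332,183,186,196,208,290,311,316,334
MO6-7,Bialowieza,nestling,137,155,205,208,217,220,253,265,295,295,327,331,121,127,286,286,216,228,316,316,186,201,192,224,302,305,322,334
MO6-8,Bialowieza,nestling,137,155,205,208,217,235,249,253,283,295,327,331,118,127,278,286,216,224,328,332,183,186,192,196,290,311,316,334
WA6-F,Bialowieza,adult,140,140,199,211,220,220,241,257,292,295,303,339,118,121,270,290,224,240,328,388,168,183,192,196,302,323,316,319
WA6-M,Bialowieza,adult,140,140,193,205,217,220,261,269,292,292,335,339,112,121,278,282,208,228,328,328,186,210,188,192,308,317,319,328
WA6-1,Bialowieza,nestling,140,140,193,211,217,220,241,269,292,292,335,339,118,121,282,290,208,240,328,328,183,210,188,196,308,323,319,328
WA6-2,Bialowieza,nestling,140,140,193,211,220,220,257,269,292,295,303,335,118,121,270,278,228,240,328,388,183,210,188,196,317,323,319,328
WA6-3,Bialowieza,nestling,140,140,193,211,220,220,241,261,292,295,303,335,121,121,270,278,224,228,328,388,183,210,192,196,302,317,319,319
WA6-4,Bialowieza,nestling,140,140,193,211,217,220,241,261,292,292,335,339,112,118,278,290,224,228,328,328,183,186,188,196,317,323,319,328
WA6-5,Bialowieza,nestling,140,140,193,211,217,220,241,261,292,292,339,339,112,121,270,278,228,240,328,328,168,210,188,196,317,323,316,319
WE8-F,Bialowieza,adult,128,140,199,205,217,232,253,257,289,295,335,339,118,121,274,286,216,224,328,332,147,171,188,248,299,299,325,325
WE8-M,Bialowieza,adult,140,143,214,214,217,232,261,269,286,292,335,343,118,118,266,274,216,216,324,332,159,168,200,208,0,0,313,319
WE8-1,Bialowieza,nestling,128,143,199,199,217,217,257,261,286,289,335,343,118,118,274,286,216,216,324,332,147,168,188,208,299,308,319,325
WE8-2,Bialowieza,nestling,140,140,199,202,217,232,257,257,295,295,315,335,118,121,286,290,204,216,328,332,147,171,188,188,299,302,325,331
WE8-3,Bialowieza,nestling,140,140,199,199,217,232,257,269,286,295,339,343,118,118,274,274,216,216,324,332,147,168,200,248,299,308,313,325
WE8-4,Bialowieza,nestling,140,143,199,214,217,217,257,269,289,292,335,339,118,118,274,286,216,224,324,332,159,171,188,208,299,308,313,325
WE8-5,Bialowieza,nestling,140,140,205,205,217,232,253,261,286,289,335,343,118,118,274,274,216,216,324,332,159,171,188,208,275,299,319,325
WE8-6,Bialowieza,nestling,128,143,199,199,217,217,257,269,286,295,335,343,118,121,274,274,216,224,324,332,159,171,200,248,299,308,319,325
WE8-7,Bialowieza,nestling,128,140,199,202,217,232,253,257,289,295,315,335,118,133,286,290,204,224,324,332,147,171,188,252,299,302,325,331
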