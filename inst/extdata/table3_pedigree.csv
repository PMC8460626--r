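family,mother,father,offspring
MO6,MO6-F,MO6-M,MO6-1
MO6,MO6-F,MO6-M,MO6-2
MO6,MO6-F,MO6-M,MO6-3
MO6,MO6-F,MO6-M,MO6-4
MO6,MO6-F,MO6-M,MO6-5
MO6,MO6-F,MO6-M,MO6-6
MO6,MO6-F,MO6-M,MO6-7
MO6,MO6-F,MO6-M,MO6-8
WA6,WA6-F,WA6-M,WA6-1
WA6,WA6-F,WA6-M,WA6-2
WA6,WA6-F,WA6-M,WA6-3
WA6,WA6-F,WA6-M,WA6-4
WA6,WA6-F,WA6-M,WA6-5
WE8,WE8-F,WE8-M,WE8-1
WE8,WE8-F,WE8-M,WE8-2
WE8,WE8-F,WE8-M,WE8-3
WE8,WE8-F,WE8-M,WE8-4
WE8,WE8-F,WE8-M,WE8-5
WE8,WE8-F,WE8-M,WE8-6
WE8,WE8-F,WE8-M,WE8-7
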