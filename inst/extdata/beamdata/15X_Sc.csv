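abscissa,value
                 4,0.97789120304385968
                 6,0.98767450154959424
                 8,0.99461586230607479
                10,                 1
                15,1.0097832985057347
                20,1.0167246592622152
                25,1.0221087969561404
                30,1.0265079577679497
                35,1.0302273952373009
                40,1.0334493185244302
                45,1.0362912562736843
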