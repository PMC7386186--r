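abscissa,value
                 1,            0.9375
                 2,                 1
                 3,0.95401144935309357
                 4,0.91013784549679033
                 5,0.86828192509349489
                 6,0.82835089780553928
                 8,0.75391350144406544
                10,0.68616520989524299
                12,0.62450492578890937
                14,0.56838556765965087
                16,0.5173092159612247
                18,0.4708226952705829
                20,0.42851355348456011
                22,0.39000640233461115
                24,0.35495958675077738
                26,0.32306215352378359
                28,0.29403109236968961
                30,0.26760882491841709
                32,0.24356091934717583
                34,0.22167401038185613
                36,0.20175390621157568
                38,0.18362386551996496
                40,0.16712302934613327
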