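abscissa,value
                 1,0.91000000000000003
                 2,0.98999999999999999
                 3,0.98108030003595814
                 4,0.94430799284597777
                 5,0.90891396486109888
                 6,0.87484655618526441
                 8,0.81049456603937808
                10,0.75087618158292124
                12,0.69564320810160118
                14,0.64447306339873178
                16,0.59706689378886757
                18,0.55314782867523693
                20,0.51245936351702337
                22,0.47476386174238877
                24,0.43984116685782526
                26,0.40748731664801102
                28,0.37751335195659225
                30,0.34974421309070586
                32,0.3240177174038123
                34,0.30018361208552252
                36,0.27810269662633968
                38,0.2576460098321669
                40,0.23869407664042744
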