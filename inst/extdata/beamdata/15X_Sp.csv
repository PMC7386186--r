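abscissa,value
                 4,0.96756664254881153
                 6,0.98191863185504302
                 8,0.99210153032116954
                10,                 1
                15,1.0143519893062314
                20,1.0245348877723581
                25,1.0324333574511886
                30,1.0388868770785895
                35,1.0443432501775023
                40, 1.049069775544716
                45,1.0532388663848209
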