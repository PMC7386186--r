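abscissa,value
                 4,0.96664378823585662
                 6,0.98140414708109347
                 8,0.99187678834618831
                10,                 1
                15,1.0147603588452367
                20,1.0252330001103316
                25,1.0333562117641433
                30,1.0399933589555685
                35, 1.045604986947688
                40,1.0504660002206634
                45,1.0547537178008053
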