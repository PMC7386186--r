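abscissa,value
                 4,0.97645811240407221
                 6,0.98687556362026996
                 8,0.99426686288526511
                10,                 1
                15,1.0104174512161976
                20, 1.017808750481193
                25,1.0235418875959279
                30,1.0282262016973907
                35,1.0321867328378798
                40, 1.035617500962386
                45,1.0386436529135885
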