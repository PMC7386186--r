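abscissa,value
                 4,0.9856616241746764
                 6,0.99200645655360831
                 8,0.99650818676819275
                10,                 1
                15,1.0063448323789319
                20,1.0108465625935164
                25,1.0143383758253235
                30,1.0171913949724483
                35,1.0196035882907977
                40,1.0216931251870327
                45,1.0235362273513802
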