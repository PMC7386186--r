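abscissa,value
                 4,0.97611486256853464
                 6,0.98668420425664582
                 8,0.99418327152651242
                10,                 1
                15,1.0105693416881112
                20,1.0180684089579779
                25,1.0238851374314655
                30,1.0286377506460891
                35,1.0326560278639509
                40,1.0361368179159556
                45,1.0392070923342003
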