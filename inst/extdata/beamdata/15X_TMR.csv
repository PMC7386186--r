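abscissa,value
                 1,0.88888888888888884
                 2,0.97222222222222221
                 3,                 1
                 4,0.96810960867425677
                 5,0.93723621440742255
                 6,0.90734738476531174
                 8,0.85039882804991584
                10,0.79702457833801177
                12,0.74700029859119044
                14,0.70011573201282162
                16,0.65617381831877852
                18,0.61498986547435586
                20,0.57639077341611533
                22,0.54021430649588642
                24,0.50630841158893569
                26,0.47453057900024931
                28,0.44474724348275602
                30,0.41683322284991453
                32,0.39067119182309945
                34,0.36615118890231774
                36,0.3431701541875854
                38,0.32163149620838399
                40,0.30144468594054113
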