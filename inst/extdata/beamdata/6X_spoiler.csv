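abscissa,value
                 0,1.0118236360605806
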