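abscissa,value
                 0,1.0160542470868676
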