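{"COVID-positive":["C1","C2"],"Hospitalized":["C3","C4"],"Deaths":["C5","C6"]}
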