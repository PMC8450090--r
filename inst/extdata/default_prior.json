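{"meth":[{"alpha":24,"beta":1,"weight":0.63},{"alpha":100,"beta":1,"weight":0.27},{"alpha":3,"beta":1,"weight":0.1}],"unmeth":[{"alpha":1,"beta":26,"weight":0.595},{"alpha":1,"beta":100,"weight":0.255},{"alpha":1,"beta":5,"weight":0.15}],"exact":[false]}
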