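{"cornerAS":[0,0],"cornerPS":[0.5,26],"cornerAI":[18,0],"cornerPI":[17.5,26],"concavitySuperior":[1.2],"concavityInferior":[1],"rotation":[0],"spacing":[1,1],"boundaryNoiseSD":[0]}
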