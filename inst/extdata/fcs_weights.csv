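group,weight
staples,2
pulses,3
vegetables,1
fruit,1
meat_fish,4
milk,4
oil_sugar,0.5
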