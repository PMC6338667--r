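genotype,seed,bouts,collisions,steps_S1,steps_S2,steps_S3
{1,0,1;1},3,10,5226,162656,17971,179373
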