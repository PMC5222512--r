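metal,lod
Al,5.147181374166153
Hg,0.29403358710307537
Pb,0.13405757743064375
Sb,0.0631698886599847
Sn,0.19299162750577106
W,0.0318562157853087
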