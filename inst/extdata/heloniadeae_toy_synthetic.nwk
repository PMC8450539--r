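(Helonias_bullata:3.2,((Ypsilandra_thibetica:1.6,Ypsilandra_yunnanensis:1.6):1.2,(((Heloniopsis_umbellata:0.9,Heloniopsis_orientalis:0.9):0.6,Heloniopsis_tubiflora:1.5):0.7,(Heloniopsis_koreana:1.1,Heloniopsis_leucantha:1.1):1.1):0.6):0.4);
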