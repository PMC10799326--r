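((Cornechiniscus|c1|EtAHSa1,Cornechiniscus|c1|EtAHSa2),((Pseudechiniscus|ps1|EtAHSa1,Pseudechiniscus|ps1|EtAHSa2),((Echiniscus|e1|EtAHSa1,(Echiniscus|e1|EtAHSa2,Echiniscus|e1|EtAHSa3)),(Viridiscus|v1|EtAHSa1,(Viridiscus|v1|EtAHSa2,(Viridiscus|v1|EtAHSa3,Viridiscus|v1|EtAHSa4))))));
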