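((Hypsibius|h1|CAHS2a,(Hypsibius|h1|CAHS2b,Hypsibius|h1|CAHS2c)),((Acutuncus|a1|CAHS2a,Acutuncus|a1|CAHS2b),Ramazzottius|r1|CAHS2a));
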