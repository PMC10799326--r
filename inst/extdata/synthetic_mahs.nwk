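((Hypsibius|h1|MAHS1,Acutuncus|a1|MAHS1),Hypsibius|h1|MAHS2);
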