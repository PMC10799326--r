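((Milnesium|m1|SAHSlike,((Macrobiotus|ma1|SAHS1,Paramacrobiotus|p1|SAHS1),(Ramazzottius|r1|SAHS2,(Ramazzottius|r1|SAHS7,(Ramazzottius|r1|SAHS8,(Ramazzottius|r1|SAHS9,(Ramazzottius|r1|SAHS10,(Ramazzottius|r1|SAHS11,Ramazzottius|r1|SAHS12)))))))),(Hypsibius|h1|SAHS3,Acutuncus|a1|SAHS1));
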