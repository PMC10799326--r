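(Nontardigrade|out|MRE11,((Batillipes|b1|MRE11a,Batillipes|b1|MRE11b),((Cornechiniscus|c1|MRE11,(Echiniscus|e1|MRE11,Viridiscus|v1|MRE11)),(Milnesium|m1|MRE11,((((Macrobiotus|ma1|MRE11a,Mesobiotus|me1|MRE11),Paramacrobiotus|p1|MRE11),Dactylobiotus|d1|MRE11),((Hypsibius|h1|MRE11,Acutuncus|a1|MRE11),(Ramazzottius|r1|MRE11a,(Ramazzottius|r1|MRE11b,(Ramazzottius|r1|MRE11c,Ramazzottius|r1|MRE11d)))))))));
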