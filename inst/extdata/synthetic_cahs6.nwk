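(((Hypsibius|h1|CAHS6,Acutuncus|a1|CAHS6),(Ramazzottius|r1|CAHS6a,(Ramazzottius|r1|CAHS6b,(Ramazzottius|r1|CAHS6c,Ramazzottius|r1|CAHS6d)))),((Macrobiotus|ma1|CAHS6,Mesobiotus|me1|CAHS6),(Paramacrobiotus|p1|CAHS6a,(Paramacrobiotus|p1|CAHS6b,(Paramacrobiotus|p1|CAHS6c,Paramacrobiotus|p1|CAHS6d)))));
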