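(((Batillipes,Halechiniscus),(Cornechiniscus,(Echiniscus,Viridiscus))),(Milnesium,((((Macrobiotus,Mesobiotus),Paramacrobiotus),Dactylobiotus),((Hypsibius,Acutuncus),Ramazzottius))));
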