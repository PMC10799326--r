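genus	habitat
Batillipes	marine
Halechiniscus	marine
Echiniscus	limnoterrestrial
Viridiscus	limnoterrestrial
Cornechiniscus	limnoterrestrial
Milnesium	limnoterrestrial
Macrobiotus	limnoterrestrial
Mesobiotus	limnoterrestrial
Paramacrobiotus	limnoterrestrial
Dactylobiotus	freshwater
Ramazzottius	limnoterrestrial
Hypsibius	freshwater
Acutuncus	freshwater
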