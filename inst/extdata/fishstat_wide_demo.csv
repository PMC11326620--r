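Country (Name),ASFIS species (Name),Environment (Name),1950,1951,1952
Italy,European seabass,Marine,10,-,...
France,Rainbow trout,Freshwater,120,135 F,150
Egypt,Nile tilapia,Brackishwater,...,2000,2500 E
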